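# behavkit

High-throughput behavioural analysis for *Drosophila* sleep and circadian
experiments, in R. `behavkit` is aimed at labs that record fly activity
with video-tracking devices (per-frame position and displacement stored in
single-file SQLite databases) or classic infrared beam-break activity
monitors, and at anyone with tabular behavioural data of the form
*animal id x time x variable*.

The package provides, end to end:

* **a metadata-linked behavioural table** (`behav_table`): long
  time-series rows hard-linked to an experimental registry through a
  shared `id` key, with pipeable verbs for metadata filtering, time
  windowing, binning, zeitgeber-time conversion and dead-animal curation;
* **readers and fixture writers** for ethoscope-style SQLite databases,
  DAM-style tab-delimited monitor files, and generic CSV tables;
* **sleep scoring** by the classical inactivity rule — sleep is a run of
  complete immobility lasting at least 5 min — plus bout run-length
  statistics, population sleep profiles with bootstrap confidence bands,
  overview heatmaps, and sleep-rebound quantification after deprivation;
* **circadian analysis**: the chi-squared periodogram
  (Q<sub>P</sub> = K·Σ<sub>h</sub>(M<sub>h</sub>−M̄)²/σ̂², compared to a
  χ²<sub>P−1</sub> null), significance thresholds, peak detection,
  population-averaged curves, and double-plotted actogram matrices;
* **a constrained four-stage hidden Markov model of sleep depth** (deep
  sleep, light sleep, quiet wake, active wake) with structural zeros on
  biologically impossible transitions and emissions, trained by
  constrained Baum–Welch with seeded restarts, decoded by Viterbi or
  posterior marginals, and summarised as stage occupancy over zeitgeber
  time;
* **curated 22-feature time-series phenotyping**: the canonical curated
  feature set computed per specimen, feature standardization, RBF-kernel
  SVM classification with stratified cross-validation, and decision
  surfaces in principal-component space;
* **a ground-truth simulator** of fly populations — circadian-modulated
  four-stage Markov chains with genotype-specific free-running periods,
  displacement traces, mechanical-deprivation windows and a homeostatic
  rebound term — which backs every test in the package.

## Worked example

Simulate a short-period mutant alongside wild-type flies, score sleep,
and recover the free-running periods:

```r
library(behavkit)

cfg <- sim_config(
  genotypes = tibble::tibble(name = c("per-short", "CantonS"),
                             period_h = c(19, 24), n_flies = 4),
  days = 4, bin_s = 60, seed = 7
)
sim <- simulate_population(cfg)
bt <- sim$bt
bt
#> <behav_table> 46080 observations of 8 specimen(s); 8 specimen(s) in metadata

ann <- sleep_annotation(bt$data[, c("id", "t", "moving")],
                        sleep_params(bin_s = 60))
sleep_profile(ann, meta = bt$meta, group_by = "genotype",
              n_boot = 200, seed = 7) |> head(3)
#> # A tibble: 3 × 6
#>   group   zt_bin mean_fraction_asleep ci_low ci_high n_specimens
#>   <chr>    <dbl>                <dbl>  <dbl>   <dbl>       <int>
#> 1 CantonS    0                 0.104  0.0417   0.167           4
#> 2 CantonS    0.5               0.0792 0.0542   0.108           4
#> 3 CantonS    1                 0.123  0.0875   0.159           4

binned <- dplyr::rename(bin_time(bt, "moving", 1800, "sum"), t = t_bin)
pg <- chi_squared_periodogram(binned, c(16, 32), 1800) |>
  periodogram_significance(alpha = 0.01)
peak_periods(pg) |> dplyr::slice_max(Q, n = 1, by = id)
#> # A tibble: 8 × 3
#>   id               period_h     Q
#> 1 sim|CantonS|01       24    139.
#> 2 sim|CantonS|02       23.5  144.
#> 3 sim|CantonS|03       24    135.
#> 4 sim|CantonS|04       24    146.
#> 5 sim|per-short|01     19    142.
#> 6 sim|per-short|02     19    143.
#> 7 sim|per-short|03     19    137.
#> 8 sim|per-short|04     19    153.
```

Every mutant peaks at 19 h and every wild-type fly within half an hour of
24 h, each far above its Bonferroni-corrected χ² significance line (≈ 65
at these degrees of freedom). The mean sleep fraction per half-hour
zeitgeber bin comes with a percentile-bootstrap band over specimens.

Downstream, `train_hmm()` + `decode_states()` + `state_occupancy()` stage
the sleep of the same flies, `extract_curated_features()` +
`classify_phenotypes()` separate the genotypes from their activity
statistics alone, and `plot_sleep_profile()`, `plot_actogram()`,
`autoplot()` (periodograms), `plot_state_occupancy()` and
`plot_decision_surface()` render each result with ggplot2.

## Command line

A thin CLI over the same functions lives at `inst/cli/behavkit.R`
(installed under `system.file("cli", "behavkit.R", package = "behavkit")`):

```sh
Rscript inst/cli/behavkit.R simulate --out-store store --days 4 \
    --genotypes CantonS:24:8,per-short:19:8 --seed 7
Rscript inst/cli/behavkit.R sleep --store store --out profile.csv
Rscript inst/cli/behavkit.R periodogram --store store --out pg.csv
Rscript inst/cli/behavkit.R hmm-train --store store --out model.json
```

A *store* is the package's two-file CSV interchange form (`data.csv` +
`meta.csv`).

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on a freshly
simulated three-genotype population (19 / 24 / 29 h): sleep scoring and
profiling, per-fly periodograms with peak detection, actogram
construction, sleep-stage training and decoding, and cross-validated
feature-based classification, logging each stage's headline numbers. Run
it from the repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/behavkit.Rmd`) describes the models and
their assumptions, every tunable parameter with units and defaults, what
the simulator does and does not emulate, and the numerical design
decisions behind the implementation.
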