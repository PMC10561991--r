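---
title: "Models and methods behind behavkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind behavkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavkit)
```

`behavkit` analyses high-throughput behavioural recordings of *Drosophila*
(and any animal reducible to *id × time × variable* tables): sleep
scoring, circadian rhythm detection, covert sleep-stage modelling and
time-series phenotyping. This vignette is the package's own account of the
science it implements: the models, their assumptions, the parameters that
matter, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## The metadata-linked behavioural table

A `behav_table` pairs a long data tibble (`id`, `t` in seconds, variables)
with a metadata tibble keyed by `id`. The invariant maintained by every
verb is referential integrity: all data ids exist in the metadata, while
the metadata may register specimens with no data (dead on arrival, empty
tracking regions). Metadata is treated as the experimental registry —
data without registration is an error, registration without data is not.

Design choices:

* **Time** is stored in seconds as plain doubles relative to the
  experiment reference. Device readers convert on entry (ethoscope
  databases store milliseconds; monitor files store wall-clock stamps).
* **Windows are half-open** `[t_min, t_max)` and **bins are labelled by
  their left edge** (`t_bin = floor(t / bin) * bin`), so consecutive
  windows and bins partition time without double counting.
* **Dead-animal curation** drops a specimen's trailing immobility run if
  it reaches its last record and spans at least 24 h (configurable).
  24 h of terminal immobility is the standard field heuristic for death;
  the choice is declared, not derived.

## Sleep scoring

Movement is first reduced to a regular binary grid: within each `bin_s`
(default 10 s) bin, a specimen is *moving* if the maximum instantaneous
speed proxy of any frame exceeds `velocity_threshold` (default 1 px/s —
an instrument-scale choice, exposed as a parameter). Max semantics mean a
single fast frame marks the whole bin; bins with no observations are
missing, never silently still.

Sleep is then a maximal run of contiguous still bins spanning at least
`min_sleep_s = 300` s. The threshold is inclusive ("at least 5 min" read
as ≥ 300 s): a run of exactly thirty 10-s bins is sleep, twenty-nine bins
are not. Missing bins terminate runs — no sleep is inferred across gaps
in the record, a deliberately conservative rule.

Bout statistics are an exact run-length encoding; decoding reproduces the
input bin-for-bin, and bout durations tile the covered span.

Population sleep profiles average, per zeitgeber bin, each specimen's
fraction of time asleep, and attach a percentile bootstrap interval
(default 1000 replicates, seeded). Specimens — not time bins — are
resampled, because specimens are the independent experimental units;
time bins within a fly are strongly autocorrelated. Rebound after
deprivation is quantified per specimen as sleep minutes in a clock window
on the post-deprivation day minus the identical window on a baseline day;
minutes were chosen as the reporting unit. Specimens lacking data in
either window are excluded and named.

## The chi-squared periodogram

For a candidate period of $P$ bins the equally binned series is truncated
to $K = \lfloor N/P \rfloor$ complete cycles and folded into $P$ phase
columns with means $M_h$:

$$Q_P \;=\; \frac{K \sum_{h=1}^{P} (M_h - \bar M)^2}{\hat\sigma^2},
\qquad \hat\sigma^2 = \frac{1}{KP}\sum_{i=1}^{KP} (x_i - \bar M)^2 .$$

Under the no-rhythm null each folded mean contributes one standardized
squared deviation (one constraint for the grand mean), so
$Q_P \sim \chi^2_{P-1}$. Numerical notes:

* The candidate grid is every whole-bin multiple inside the requested
  range (default 16–32 h at 30-min bins): folding requires integer bins,
  and finer grids would need resampling, which is out of scope.
* The incomplete final cycle is discarded; keeping it would bias column
  means unevenly and break the null.
* Exactly, $Q_P$ is $N$ times a Beta-distributed variance ratio, which
  has slightly lighter far tails than $\chi^2_{P-1}$; at $\alpha = 0.01$
  the test is therefore mildly conservative (empirical exceedance about
  0.005 in the suite's white-noise calibration). This is a property of
  the classical statistic, not of the implementation.
* The significance line defaults to Bonferroni correction over the
  tested-period grid — conservative, and honest about testing a few dozen
  periods at once. Peaks are local maxima above the line, ranked by $Q$,
  ties broken toward the shorter period.
* Population curves are pointwise arithmetic means of per-specimen $Q$
  ("cumulative" read as population-averaged); the χ² threshold applies to
  individual curves and is carried on the averaged curve for visual
  reference only.

Actograms are laid out one row per day; double plotting concatenates day
$r$ with day $r+1$ so drifting rhythms read as sloping bands, with the
final row's right half missing by construction.

## The four-stage sleep model

Binary activity (0 = inactive, 1 = moving) is modelled as emissions of a
hidden four-state chain: `deep_sleep`, `light_sleep`, `quiet_awake`,
`active_awake`. Biology enters as structural zeros:

* transitions follow the adjacency chain deep ↔ light ↔ quiet ↔ active
  plus self-loops, with one extra arc light → active (abrupt arousal from
  shallow sleep); deep sleep cannot wake directly, active wake cannot
  plunge straight into deep sleep, and the reverse skips (quiet → deep,
  active → light) are likewise forbidden;
* both sleep stages emit movement with structural probability zero;
* active wake emits movement with structural probability one.

The last constraint deserves its own paragraph. With both wake emissions
free, the likelihood cannot distinguish "a quiet state that sometimes
moves" from "an active state that sometimes rests", and — because the
quiet slot enjoys looser transition connectivity — the maximum-likelihood
solution routinely swaps the two roles. Pinning active wake to
always-moving (equivalently: a (0, 1) emission initialization, which
Baum–Welch preserves forever) is what identifies the semantic labels.
Quiet wake keeps the only free emission row, capturing grooming-scale
micro-movement. Every constraint is a mask in `hmm_spec()` and fully
user-overridable.

**Training** is constrained Baum–Welch on the pooled sequences of all
specimens (a shared model; per-group models are obtained by filtering
first). Masked entries stay exactly zero because their expected counts
are zero; rows are renormalized each M-step; the log-likelihood is
monotone within each restart, which the tests assert. Missing bins split
sequences rather than being imputed. Restarts (default 5) draw free
transition rows from a sticky-diagonal Dirichlet (diagonal weight 12):
behavioural stages persist across adjacent bins, so sticky initial
guesses start near the relevant likelihood basin — flat Dirichlet draws
were observed to converge to fast-switching local optima well below it.
Restart 1 is the template itself; the best final log-likelihood wins,
ties toward the lowest restart index. Everything is deterministic given
the seed.

**Decoding** offers the Viterbi path (ties toward the lowest state index)
and forward–backward posterior marginals. `state_occupancy()` summarises
either into stage fractions per zeitgeber bin and exposes the choice as
`weight = "viterbi"` or `"posterior"`. The distinction matters: the MAP
path over-represents dominant stages, and with two structurally silent
sleep states the deep/light split of a silent run is decided by dwell
statistics alone, so Viterbi occupancy can deviate from the true stage
frequencies by several percent even under a perfectly specified model.
Posterior averaging is unbiased for occupancy fractions and is what the
recovery tests use when the fraction itself is the target quantity; the
timing of the deep-sleep peak is robust to the choice and is asserted on
Viterbi output.

Models serialize to JSON (labels, transition, emission, initial, masks).

## Curated time-series features and classification

Each specimen's binned activity series is mapped to the canonical curated
set of 22 time-series features (distribution shape, autocorrelation
timescales, symbolic motif statistics, fluctuation scaling, spectral
summaries, extreme-event timing, periodicity). No implementation of the
set ships with the target environment, so the features are reimplemented
in R from their published definitions, z-scoring the series on entry as
the standard pipeline does. Where the reference leaves implementation
details unstated, deterministic choices are made: histogram modes average
tied bin centres; the two-regime fluctuation fits use 50 log-spaced
scales from 5 to $N/2$; the periodicity detrend uses a cubic polynomial
in place of the reference spline; spectral summaries use the rectangular
window periodogram. Bit-exact agreement with the reference C library is
therefore not claimed; determinism, the count of 22, and discriminative
power are the tested contract. Constant series keep their row with
features flagged `NA`; series under 10 bins are excluded and reported.

Classification uses an RBF-kernel soft-margin SVM, hand-written (a
simplified SMO solver; one-vs-one voting for more than two classes,
vote ties broken by aggregate decision value) because no SVM library is
available in the environment. Defaults are cost 1 and the
$\gamma = 1/p$ heuristic on standardized features. Accuracy is estimated
by stratified k-fold cross-validation with seeded fold assignment.
Features are standardized once on the full matrix before folding — a
simplification that leaks only column means/variances, acceptable at the
package's scale and noted here. The decision surface projects
standardized features onto their first two principal axes and refits the
classifier in that plane; the projection is a declared choice, as is the
single-class degenerate case (a uniform surface).

## The synthetic population generator

The simulator is the package's stated world: a ground-truth fly
population every analysis module is tested against.

Each fly's latent stage follows the four-stage chain with a circadian
mixture of a day matrix and a night matrix,
$A(t) = (1 - w(t))\,A_{day} + w(t)\,A_{night}$, with
$w(t) = \big[\tfrac{1}{2}(1 + \cos 2\pi (h - h_{peak})/T)\big]^s$ where
$T$ is the genotype's free-running period (so mutant rhythms drift
against the 24-h clock), $h_{peak} = 15$ (mid first half of the night,
where deep sleep is expected to peak) and sharpness $s = 3$. The exponent
concentrates night-like dynamics into a single prominent nightly peak
rather than a broad plateau — the phenomenon the model is meant to
emulate. The default night matrix is calibrated so peak deep-sleep
occupancy stays mid-range (≈ 0.5): in a saturated night (occupancy ≈ 0.9)
the occupancy curve clips and its argmax drifts earlier than the
configured peak hour, defeating timing recovery by construction.

Emissions: sleep stages never move; quiet wake moves with probability 0.1
per bin, active wake 0.9 (sub-bin cadence realism; the recovery tests
that require a well-specified emission model set active to 1). Moving
bins draw a log-normal displacement with median $3 \cdot bin_s$ pixels —
three times the movement threshold in velocity units at any bin size —
so movement classification is meaningful and testable. Mechanical sleep
deprivation forces movement (state pinned to active wake) inside
configured windows, and an optional homeostat raises the sleep-pressure
weight by `rebound_boost` · exp(−Δt/τ) afterwards (τ = 6 h), producing
genuine rebound sleep for the deprivation analyses.

What the generator does **not** emulate: arena geometry and positional
behaviour (positions are a token bounded walk), social interactions,
stimulus–response arousal thresholds, inter-fly parameter variability
(all flies of a genotype share one chain), and recording artefacts such
as tracking dropouts. A green test therefore establishes that an analysis
recovers the truth of *this* world at desk scale — not that it is robust
to every failure mode of real recordings.

Test worlds are scaled for a single-CPU budget and fixed once: period
recovery uses 1 fly × 8 days simulated at 60-s bins with activity
re-binned to 30 min (periods 19/24/29 h); transition recovery uses
10 flies × 5 days at 30-s bins from a time-homogeneous sticky chain;
occupancy recovery uses 50 flies × 3 days at 60-s bins, compared on 2-h
zeitgeber bins where estimation noise and binwise sampling noise are both
inside the stated tolerances; deep-sleep timing uses 50 flies × 2 days of
the modulated default world.

## Known limitations

* The curated feature values are a faithful but not bit-exact rendition
  of the reference library; models trained on features from one
  implementation should not be applied to features from the other.
* The sleep-stage model is time-homogeneous; fitting it to circadianly
  modulated data estimates time-averaged dynamics, and bin-wise Viterbi
  occupancy inherits systematic deviations from the true stage fractions
  (see the estimator discussion above).
* The χ² periodogram grid is limited to whole-bin periods; sub-bin
  period resolution would require resampling.
* The SMO solver targets the package's specimen counts (tens to low
  hundreds); it is not tuned for thousands of cases.
* Readers implement the minimal documented dialects; exotic vendor
  columns are ignored rather than modelled.
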