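Package: behavkit
Title: Metadata-Linked Behavioural Time-Series Analysis for Sleep and
    Circadian Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-throughput behavioural analysis in Drosophila
    and other animal models: a metadata-linked behavioural table with
    tidyverse-style transformation verbs, readers for ethoscope-style
    SQLite tracking databases and DAM-style beam-count monitor files,
    sleep scoring by the five-minute inactivity rule with bout statistics
    and rebound quantification, chi-squared periodogram and double-plotted
    actogram circadian analysis, a constrained four-state hidden Markov
    model of covert sleep stages, curated 22-feature time-series phenotype
    classification, and a ground-truth population simulator that exercises
    the whole stack.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
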