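Package: hifisim
Title: Simulation of Multi-Sample PacBio HiFi Amplicon Sequencing Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates realistic synthetic PacBio HiFi (CCS) amplicon
    sequencing datasets for microbiome benchmarking. The pipeline covers
    genome-level abundance simulation with copy-number-aware expansion to
    amplicon sequence variants (ASVs), in-silico PCR with degenerate
    primers, dual-barcoded template construction, pass-number-aware
    subread simulation with a configurable error model, plurality-vote
    consensus calling with per-base qualities, and evaluation metrics
    (edit-distance profiles, abundance correlation, positional error
    profiles) together with KL-divergence-based calibration of the
    subread accuracy. A synthetic-fixture generator builds mock
    communities with known ground truth so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
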