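Package: dyadflow
Title: Behavioural and Spectral Connectivity Analysis for Dyadic Reward
    Conditioning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for dyadic (social) Pavlovian reward
    conditioning experiments with paired-site electrophysiology. Quantifies
    anticipatory licking as a read-out of subjective reward valuation and
    tests intervention effects with a chronologically-paired modulation
    statistic and a Monte Carlo permutation null; compares gaze
    region-of-interest occupancy between conditions; computes
    baseline-normalised Morlet wavelet field-field coherence between a
    prefrontal and a hypothalamic recording site with a subsampling
    percentile plus flood-fill cluster significance test; and estimates
    spectral Granger causality from multivariate autoregressive models with
    AIC order selection, model diagnostics, false-discovery-rate control and
    session-level tests. A seeded synthetic-data generator reproduces the
    task structure (variable reward probabilities, a never-both-rewarded
    constraint, probability-dependent anticipatory licking, coupled
    stimulus-locked field potentials) so every stage can be exercised
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
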