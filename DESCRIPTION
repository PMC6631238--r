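Package: wristintake
Title: Eating and Drinking Recognition from Wrist-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-hierarchical recognition of eating and drinking activities
    from wrist accelerometer and gyroscope streams. Implements causal
    preprocessing (downsampling, Butterworth low-pass, half-Gaussian
    smoothing), three data-stream segmentation methods (fixed-length
    overlapping windows, dynamic windows, and dynamic fixed windows with
    periodic threshold resets), a 33-dimensional time-domain feature
    extractor with two-stage feature selection, SMOTE+ENN class balancing,
    two binary random-forest branches, a daily-evidence restriction layer
    (time-of-day meal-probability gating, minimum meal duration, pre-meal
    energy peaks, rotational-peak drink filtering), and event-based
    evaluation (sensitivity, specificity, false positives per hour).
    Ships a seeded synthetic generator of labeled free-living days so the
    whole pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
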