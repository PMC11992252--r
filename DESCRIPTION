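Package: placecode
Title: Place-Cell Stability and Population-Coding Analysis for Virtual-Corridor Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chronic two-photon calcium imaging of
    hippocampal CA1 during a virtual linear-corridor task. Provides lick-based
    spatial-information scoring of behavioral performance, delta-F/F detrending
    with a rolling mode-percentile baseline, velocity-filtered spatial activity
    maps, place-field detection with bootstrap significance, within- and
    cross-session stability classification of place cells, functional-class
    transition statistics against a shuffled null, a Gaussian naive-Bayes
    position decoder with empirical chance levels, population-vector-correlation
    network metrics, pairwise-synchrony structure, and cross-session ROI
    tracking. A seeded synthetic-experiment generator emulates the corridor
    task, GCaMP-like transients, and stroke-like perturbations so that every
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
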