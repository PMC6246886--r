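Package: reachdecode
Title: Decoding 3D Reach Kinematics from Cortical Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decoding three-dimensional
    arm reach kinematics (speed, velocity, and integrated trajectories) from
    multichannel electrocorticographic (ECoG) field potentials. Provides a
    synthetic-data generator for a center-out reaching task with a known
    forward (encoding) model; signal conditioning (common-average
    referencing, band-pass and notch filtering); sliding-window
    autoregressive (Burg maximum-entropy) spectral features with two-stage
    baseline z-scoring and the Savitzky-Golay local motor potential; a
    hierarchical decoder that gates two multivariate partial-least-squares
    regressions with an elastic-net logistic movement/rest classifier;
    surrogate-based significance testing (temporal and weight-shuffle
    nulls, rank-sum statistics with Bonferroni correction); cross-condition
    decoder transfer; and activation-pattern interpretation of decoder
    weights with false-discovery-rate-controlled movement-related
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    mixOmics,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
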