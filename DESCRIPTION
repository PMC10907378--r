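Package: spiketrack
Title: Tracking and Spike Estimation of Single Neurons in Deforming Animals
Version: 0.1.0
Authors@R: person("Spiketrack", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for monitoring single-neuron calcium
    activity in two-channel fluorescence movies of soft, deforming animals
    such as Hydra. Nuclei are detected in a calcium-insensitive anchor
    channel with an undecimated a-trous wavelet transform and statistical
    thresholding, linked into conservative tracklets with a gated
    constant-velocity Kalman tracker, and stitched into full-length tracks
    by thin-plate-spline propagation of undetected positions and a global
    Jonker-Volgenant assignment. Calcium signals are extracted from the
    misaligned activity channel with a prior-weighted sub-ROI search,
    cleaned by two-signal independent component analysis, Butterworth
    detrending and smoothing, and deconvolved with a constrained
    non-negative AR(2) model followed by adaptive spike clustering. A
    synthetic movie generator with full ground truth makes every stage
    testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    clue,
    withr
Config/testthat/edition: 3
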