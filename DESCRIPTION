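Package: nucleodyn
Title: Multiscale Chromatin Dynamics from Single-Nucleosome Tracking and
    Micro-Irradiation Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for live-cell chromatin dynamics at the
    nucleosome scale. Simulates single-particle-tracking experiments with
    three diffusive populations (subdiffusive fractional-Brownian immobile,
    fast Brownian mobile, and two-state hybrid tracks), classifies
    trajectories with a convolutional neural network operating on
    diffusion-colored trajectory renderings (with a segment-threshold
    baseline implementing the segment-to-track mapping rule), computes
    time-averaged and ensemble mean squared displacements with
    anomalous-diffusion fits and effective diffusion coefficients,
    quantifies 10-ms jump-distance distributions with bootstrap confidence
    intervals, Scott's-rule kernel density estimates and the two-sided
    Yuen-Welch test, and measures chromatin compaction from photoactivated
    line images via k-means segmentation and moment-equivalent ellipse
    minor axes, plus photobleaching-corrected recruitment curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
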