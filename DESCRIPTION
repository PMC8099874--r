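Package: tremorid
Title: Two-Stage Classification of Parkinsonian Versus Essential Hand Tremor
    from Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differentiates Parkinsonian tremor from essential tremor using
    three-axis hand accelerometry. Recordings are downsampled, demeaned and
    converted to short-time spectrograms, classified per signal by a small
    convolutional network that receives a six-bit task hint, and fused per
    tremor assessment by a quadratic discriminant (or naive Bayes) likelihood
    ratio over the 54 per-assessment network outputs. Includes patient-wise
    Monte-Carlo evaluation with ROC/AUC, logical-AND patient fusion, wrapper
    feature ranking, Grad-CAM saliency with population-level pixel-wise
    z-tests, and a synthetic tremor cohort generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
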