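Package: photosens
Title: Photometric Robustness Auditing of Image Classifiers via Global
    Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how photometric acquisition uncertainty (brightness,
    contrast, sharpness, saturation, hue) propagates into the output of a
    black-box image classifier. Generates Saltelli sampling designs over
    bounded photometric factors from a seeded Sobol' low-discrepancy
    sequence, applies bit-exact 8-bit perturbations to RGB images, and
    estimates per-image first-order and total-order variance-based
    sensitivity indices, aggregated across a dataset with class and
    metadata stratification. Complements the variance decomposition with
    decision-stability metrics (flip rate, Gini dispersion, Brier score),
    one-at-a-time parameter sweeps, and exact Shapley attribution on a
    tree-ensemble surrogate of the perturbation-response relationship.
    Ships synthetic dermoscopy-like image generators and analytic probe
    predictors so the full workflow is testable without any trained model
    or external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    png,
    ranger,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
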