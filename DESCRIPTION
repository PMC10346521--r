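Package: leafnet
Title: Lightweight Feature-Pyramid Networks for In-Field Leaf Maturity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds, trains and audits a lightweight nine-class leaf-maturity
    image classifier: a depthwise-separable convolutional backbone with a
    top-down feature-pyramid fusion path, spatial attention on the P2 level
    and squeeze-and-excitation recalibration on the P1 level. Includes exact
    parameter accounting for every ablation variant, a stratified data
    pipeline with offline augmentation, cross-entropy training with a
    reduce-on-plateau schedule over an optimizer/learning-rate grid, a
    classification metric suite (accuracy, precision, recall, F1, mean
    average precision), a perturbation-robustness harness (Gaussian noise,
    brightness, occlusion), gradient-free Score-CAM explanations, and a
    synthetic leaf-image generator so the whole stack is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
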