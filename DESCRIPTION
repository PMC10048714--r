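Package: pearfusion
Title: Feature-Level Fusion of Near-Infrared Spectra and RGB Images for
    Fruit Disorder Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the pear woolliness response disorder by fusing
    near-infrared reflectance spectra with RGB fruit images at the feature
    level. Provides reflectance calibration from white/dark reference scans,
    a one-hidden-layer spectral network whose hidden activations serve as the
    spectral feature vector, classical chemometric baselines (PLS-DA, SVM,
    random forest, AdaBoost, XGBoost), scale-reducible convolutional backbones
    (VGG-, ResNet-, Xception- and DenseNet-style) with named intermediate tap
    points, concatenation fusion with a trainable prediction head,
    macro-averaged confusion-matrix metrics, and a seeded synthetic generator
    of paired spectra and images so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    e1071,
    generics,
    ggplot2,
    mixOmics,
    png,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
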