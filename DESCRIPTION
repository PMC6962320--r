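Package: lungtex
Title: Lung Parenchyma Texture Classification with Multi-Dimensional CNN Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies lung-parenchyma tissue patterns (normal parenchyma, five
    interstitial subtypes and two emphysema subtypes) in chest CT by fusing the
    probability outputs of seven convolutional neural networks operating on 2D,
    2.5D and 3D patches. Provides CT volume and point-annotation input/output,
    patch extraction and attenuation normalization, geometric and sponge-model
    (inspiration-level) data augmentation, a compact CNN engine with seven
    reference architectures, weighted-ensemble fusion with Tree-structured
    Parzen Estimator weight optimization, macro-averaged evaluation metrics and
    cross-validation splits, whole-lung grid classification with nearest-node
    interpolation, certainty-thresholded interstitial-lung-abnormality scoring,
    and a synthetic texture-phantom generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pROC,
    png,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
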