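Package: vitispec
Title: 1D Convolutional Neural Network Regression for Grape Berry Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric pipeline for predicting sugar content
    (degrees Brix) and pH of wine grape berries from hyperspectral reflectance
    spectra. Provides reflectance calibration from raw line-scan frames with
    dark and white references, spectral preprocessing (multiplicative scatter
    correction, min-max normalization, Savitzky-Golay smoothing/derivative),
    percentile-stratified train/validation/test splitting, a fixed-topology
    one-dimensional convolutional neural network regressor trained with
    Adadelta and early stopping, Bayesian hyperparameter optimization with a
    Gaussian-process surrogate and expected-improvement acquisition,
    transfer-learning fine-tuning across vintages, and RMSE / absolute
    percentage error evaluation. A synthetic-spectra generator with known
    ground truth makes every stage testable.
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
    signal,
    optparse,
    yaml
Config/testthat/edition: 3
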