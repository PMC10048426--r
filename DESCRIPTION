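Package: grainscan
Title: Grain Scene Segmentation, Feature Extraction and Variety
    Classification for Milled-Rice Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for image-based quality evaluation of
    milled rice and similar grains. Generates seeded synthetic grain scenes
    with pixel-level ground truth; segments individual grains from scene
    images by median denoising, Otsu thresholding, erosion-derived markers
    and marker-based watershed; extracts per-grain geometry, colour-histogram
    and grey-level co-occurrence texture features; benchmarks eight
    classifiers under stratified k-fold cross-validation with
    feature-importance selection and grid search; and converts per-grain
    variety predictions of a mixed sample into price factors and an
    adulteration verdict.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
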