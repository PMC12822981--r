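Package: texent
Title: Entropy-Based Texture Analysis of Tumor MRI Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for differentiating tumor texture classes on
    grayscale MRI regions of interest (ROIs). Implements five two-dimensional
    multiscale entropy measures (sample, fuzzy, permutation, dispersion and
    distribution entropy), classical first-order and gray-level matrix texture
    features (GLCM, GLDM, GLRLM, GLSZM, NGTDM), normality-routed two-group
    statistics, random-forest importance-based feature selection, and
    patient-grouped stratified cross-validated classification with k-nearest
    neighbours, support vector machines and L2-penalized logistic regression.
    Ships a seeded synthetic ROI generator that emulates two texture classes
    with patient-level structure so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    class,
    randomForest,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
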