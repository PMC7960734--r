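Package: remitpredict
Title: Multimodal Prediction of Remission from Alcohol Use Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting remission from alcohol use
    disorder (AUD) from multimodal baseline data: EEG source-level functional
    connectivity (band-averaged magnitude-squared coherence between cortical
    regions of interest), clumping-and-thresholding polygenic risk scores,
    and demographic and medication covariates. Provides sex- and
    ancestry-stratified, age-matched cohort assembly, LASSO feature selection
    followed by a linear support-vector machine, repeated stratified
    cross-validation (in both a select-once and a leakage-free nested mode),
    holdout validation, and feature-weight ranking. Includes a fully
    parameterised synthetic multimodal cohort generator with recorded ground
    truth so that every stage can be exercised and validated without access
    to restricted clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    Rcpp,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    vcfR,
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
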