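Package: microstatr
Title: EEG Microstate Segmentation, Group Statistics and Treatment-Response
    Prediction for Resting-State Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for resting-state EEG microstate
    analysis in clinical cohorts. Provides a synthetic-EEG and cohort
    generator with known microstate ground truth, the standard preprocessing
    chain (resampling, band-pass, notch, average reference), polarity-invariant
    modified K-means segmentation on global-field-power peaks with two-level
    (subject then group) template estimation and back-fitting, per-subject
    temporal metrics (coverage, duration, occurrence) and organizational
    transition matrices, permutation and mixed-ANOVA group statistics, and a
    treatment-response prediction stage with multi-stage bootstrap-stability
    feature selection, an eight-algorithm model zoo evaluated by repeated
    stratified splits, DeLong AUC comparison and exact Shapley attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    ranger,
    xgboost,
    e1071,
    class,
    rpart,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
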