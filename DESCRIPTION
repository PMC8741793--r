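Package: adclassify
Title: Multi-Omics Classification of Atopic Dermatitis from Gut
    Transcriptome and Microbiota Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A supervised machine-learning pipeline for case-control
    classification of atopic dermatitis from paired gut-transcriptome and
    gut-microbiota feature tables. Provides alignment and mean imputation of
    partially overlapping modalities, stratified train/test splitting,
    min-max normalization, Gaussian jittering, a chi-square feature scorer
    implemented from its matrix definition, recursive feature elimination and
    random-forest importance rankers, two cross-validated feature-selection
    plans (nested and single five-fold), four multi-omics integration
    strategies, four classifier families with probability-threshold tuning,
    confusion-matrix metrics with ROC/AUC, and a zero-inflated synthetic
    cohort generator with planted case-control signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    randomForest,
    xgboost,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
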