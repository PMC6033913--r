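Package: sdmensemble
Title: Ensemble Species Distribution Modelling with Bias-Corrected
    Backgrounds and Extrapolation Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A presence-background species distribution modelling pipeline:
    occurrence cleaning and geographic restriction, correlation-based
    predictor screening, randomized spatial thinning to a minimum pairwise
    great-circle distance, random and target-group background generation,
    five suitability learners (stepwise logistic regression, multivariate
    adaptive regression splines, boosted regression trees, random forest,
    and a penalized maximum-entropy-style model) under stratified k-fold
    cross-validation, threshold-dependent accuracy metrics (sensitivity,
    specificity, PCC, TSS), permutation delta-AUC variable importance,
    ensemble suitability maps, and multivariate environmental similarity
    (MESS) surfaces for detecting projection into novel environments.
    Includes a virtual-species landscape simulator so the whole pipeline
    can be validated by parameter recovery without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    glmnet,
    randomForest,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
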