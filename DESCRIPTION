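Package: erpdx
Title: Event-Related Potential Feature Pipelines for Cued Go/NoGo
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating diagnostic classifiers from
    averaged event-related potentials (ERPs) recorded in a visual cued
    Go/NoGo task.  Provides a fixed registry of condition-specific ERP
    components (P3cue, CNV, P300 NoGo, P3b, P3a) over the 19-channel 10-20
    montage, a parametrized sliding-window feature extractor with a
    canonical feature-name template, random-probe Shapley filtering and
    sequential feature selection on inner cross-validation, penalized
    logistic regression, k-nearest-neighbour, support vector machine and
    per-paradigm stacking classifiers with class-imbalance handling,
    grid search on stratified k-fold cross-validation with
    balanced-sensitivity/specificity thresholding, Shapley-based model
    interpretation, behavioral summaries with one-way ANOVA group
    comparison, and a seeded synthetic cohort generator so the full
    pipeline can be exercised without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    data.table,
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
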