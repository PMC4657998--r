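Package: vocclass
Title: Urinary Volatile Organic Compound Classification with Nested
    Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Presence/absence processing of volatile organic compound (VOC)
    profiles from urine headspace GC-MS, dual prevalence filtering, four-way
    consensus feature selection (Boruta-style shadow features, stepwise LDA,
    recursive feature elimination with random-forest and bagged-tree rankers),
    Fisher linear discriminant and random-forest classifiers, and model
    validation by repeated 10-fold cross-validation, repeated double (nested)
    cross-validation and Monte-Carlo label-permutation nulls, as used in
    urinary biomarker studies of prostate cancer.  Includes a synthetic
    cohort generator with planted discriminative features and log-normal
    serum PSA for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
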