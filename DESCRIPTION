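Package: fivegaze
Title: Eye-Movement Feature Pipelines for Five-Pattern Personality Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for predicting five-pattern (traditional
    Chinese medicine) personality traits from eye movements recorded while viewing
    emotional-face pairs. Provides a trait-conditioned synthetic gaze-cohort
    generator, velocity-threshold (I-VT) fixation/saccade detection, a 260-column
    feature extractor (complex eye-movement patterns, gaze-heatmap Shannon entropy,
    area-of-interest dwell times), inventory-score discretization with
    masking-scale exclusion, mutual-information and Lasso feature selection inside
    stratified five-fold cross-validation of five classifiers, and Friedman /
    post-hoc machinery for the paired comparison of pipeline variants.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    e1071,
    nnet,
    rpart,
    pROC,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
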