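Package: fusionhar
Title: Early Fusion of Accelerometer, ECG and PPG Signals for Human
    Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for multimodal human activity recognition
    from wrist-worn triaxial accelerometer (32 Hz), wrist photoplethysmogram
    (64 Hz) and chest electrocardiogram (700 Hz) recordings. Covers
    pairwise-average up-sampling, label-pure non-overlapping windowing,
    time- and frequency-domain feature extraction, train-only
    standardization, Spearman correlation-based feature selection, seven
    early-fusion signal scenarios, and random-forest evaluation under both
    subject-specific (stratified 80/20 with 10-fold cross-validation) and
    cross-subject leave-one-subject-out protocols. Includes a synthetic
    cohort generator that emulates the statistical structure of daily-life
    wearable recordings over five activities (sitting, stairs, table
    soccer, cycling, walking) so the whole pipeline is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    caret,
    jsonlite,
    nnet,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
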