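Package: actigaf
Title: Physical Activity Intensity Classification from Gravity-Based
    Acceleration via Gramian Angular Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying physical activity intensity from raw
    triaxial wrist accelerometry. Computes the Euclidean Norm Minus One
    (ENMO) movement signal, labels fixed-length temporal windows as
    sedentary, light, or moderate-to-vigorous activity using cumulative
    per-second acceleration cut-points, encodes windows as Gramian
    Angular Field images, and classifies image sequences with a hybrid
    vision-transformer/bidirectional-LSTM model trained end to end.
    Includes a seeded synthetic-signal simulator with analytically known
    ENMO for testing the full pipeline, a balanced two-way ANOVA for
    temporal-window by intensity robustness analysis, and a complete
    multiclass evaluation suite (confusion matrix, precision, recall,
    F1, one-vs-rest ROC AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
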