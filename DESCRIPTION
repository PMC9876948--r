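Package: appendiscore
Title: Clinical Scoring and Diagnostic-Accuracy Analysis for Acute Appendicitis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Alvarado, Appendicitis Inflammatory Response (AIR)
    and RIPASA clinical decision scores for suspected acute appendicitis, a
    diagnostic-accuracy evaluation pipeline against the histopathology gold
    standard (confusion matrices, sensitivity, specificity, predictive values,
    likelihood ratios, empirical ROC/AUC, score correlations), an integer
    confusion-matrix reconstruction and audit engine that recovers the 2x2
    tables behind published rounded operating characteristics, and a seeded
    synthetic appendectomy-cohort generator calibrated to published operating
    characteristics so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
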