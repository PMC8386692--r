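Package: kappascreen
Title: Kappa Free Light Chain Index Analysis and Reflex Screening for
    Suspected Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating cerebrospinal-fluid kappa free light
    chains (K-FLC) and the kappa index (K-Index) as screening markers of
    intrathecal immunoglobulin synthesis in patients with suspected
    multiple sclerosis. Computes albumin and kappa quotients with
    detection-limit censoring and low-value imputation, diagnostic
    accuracy statistics (confusion matrices, Wilson score confidence
    intervals, empirical ROC curves with tie-corrected AUC, Youden
    cutoff selection, Mann-Whitney comparisons), and a two-tier reflex
    algorithm that decides when oligoclonal-band testing can be spared.
    Includes a calibrated synthetic-cohort generator and a deterministic
    252-patient cohort reconstructed from published routine-screening
    patient-flow counts, so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
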