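Package: ewstriage
Title: Obstetric and General Early-Warning-Score Triage and Diagnostic
    Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Data-driven implementation of two bedside vital-sign warning
    charts, the Modified Early Obstetric Warning System (MEOWS) and a
    general adult early warning score (EWS), with triage classification
    (green/yellow/red categories, inform/emergency alert thresholds),
    worst-over-stay aggregation of repeated postpartum observations, and
    diagnostic-accuracy evaluation against a severe-maternal-morbidity
    label: sensitivity and specificity with exact Clopper-Pearson
    intervals, predictive values with standard-logit intervals, and
    likelihood ratios with log-method intervals. Includes a seeded
    synthetic postpartum-cohort generator calibrated to the operating
    characteristics of a 723-woman high-dependency-unit cohort, and a
    command-line pipeline that ingests or simulates a cohort and emits the
    full comparison report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
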