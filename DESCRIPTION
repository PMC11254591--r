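Package: sthlm3cost
Title: Cost Modelling of Biomarker-Enhanced Prostate Cancer Diagnostic Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Health-economic evaluation of prostate cancer diagnostic strategies
    in European health care systems. Combines a diagnostic decision tree
    (PSA/MRI, Stockholm3-reflex, and SWOP risk-calculator pathways) with a
    six-year annual-cycle Markov cohort model of care for four disease states
    (benign, low-grade, intermediate/high-grade localized, metastatic).
    Provides cost discounting, calibration of free model parameters to
    per-state cost anchors by bracketed root finding, one-way deterministic
    sensitivity analysis with tornado tables, a seedable individual-level
    microsimulation, and Mann-Whitney comparison of per-man cost distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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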