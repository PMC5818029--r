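Package: caadx
Title: Diagnostic Modelling of Cerebral Amyloid Angiopathy-Associated
    Lobar Intracerebral Haemorrhage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development and internal validation of a diagnostic prediction
    model for lobar intracerebral haemorrhage associated with moderate or
    severe cerebral amyloid angiopathy (CAA), from CT features (subarachnoid
    extension, finger-like projections) and APOE e4 possession. Implements
    Firth penalised-likelihood logistic regression with profile
    penalised-likelihood confidence intervals, bootstrap optimism-corrected
    performance measures (c statistic, Nagelkerke R2, Brier score,
    discrimination slope, Hosmer-Lemeshow calibration), rule-in/rule-out
    diagnostic criteria with continuity-corrected Wilson intervals and
    likelihood ratios, decision curve analysis, contingency-table association
    statistics, inter-rater agreement (Cohen's kappa, ICC), a synthetic
    62-participant fixture cohort reproducing the published marginal counts
    and accuracy statistics of the derivation cohort, and a seeded cohort
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
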