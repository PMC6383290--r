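Package: sepsisagree
Title: Physician Agreement Analysis for Sepsis and SIRS Adjudication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies inter-physician agreement on the differential
    diagnosis of sepsis versus the systemic inflammatory response syndrome
    (SIRS) in critical-care cohorts. Implements the 4-level infection-call
    vocabulary and its mapping to the SIRS/indeterminate/sepsis scale,
    discharge-consensus and expert-panel adjudication rules, overall percent
    agreement with free-marginal (Randolph) and fixed-marginal (Cohen,
    Fleiss) multirater kappa statistics and bootstrap confidence intervals,
    a pipeline over the standard evaluator comparisons with cohort and
    stratum filters, reclassification (risk-transition) summaries, group
    significance tests (two-proportion z, N-1 chi-square, pooled t,
    Kolmogorov-Smirnov), logistic discriminant scoring with ROC analysis and
    recursive feature elimination, and a seeded synthetic cohort generator
    emulating a multi-hospital ICU line-data table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
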