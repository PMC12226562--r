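Package: adetrigger
Title: Trigger-Tool Screening and Evaluation of Adverse Drug Events in
    Elderly Multimorbid Inpatients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An adapted Global Trigger Tool (GTT) engine for retrospective
    adverse-drug-event (ADE) surveillance in elderly inpatients with multiple
    chronic diseases. Screens structured admission records (demographics,
    chronic conditions, medication orders, laboratory results, clinical
    events) against a declarative registry of 38 triggers spanning laboratory
    thresholds, antidote and rescue-medication use, symptoms, outcomes and
    therapeutic drug monitoring; scores causality with the Naranjo scale;
    grades severity on the NCC MERP E-I ladder; and derives the standard GTT
    quantitative outputs (ADEs per 1,000 patient-days and per 100 admissions,
    incidence, per-trigger positive predictive value, severity, drug-class
    and organ-system distributions) together with a screening evaluation
    (sensitivity, specificity, compliance rate, Cohen's kappa). Includes
    Pearson chi-square, Mann-Whitney U, binary logistic regression with Wald
    odds-ratio intervals and rank-based ROC/AUC for risk-factor analysis, a
    deterministic calibration cohort, a stochastic cohort simulator with a
    known ADE-risk model, and systematic time-based random sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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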