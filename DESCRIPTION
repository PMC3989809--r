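Package: rascore
Title: Development and Internal Validation of a Clinical Risk Score for
    Renal Artery Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating integer point-score systems
    that predict significant renal artery stenosis (>=50% lumen narrowing)
    from clinical and carotid-ultrasound covariates in patients undergoing
    coronary angiography. Implements Youden-index dichotomization of
    continuous predictors on the empirical ROC curve, maximum-likelihood
    logistic regression with backward Wald elimination, bootstrap internal
    validation with optimism-corrected discrimination in which the whole
    modelling pipeline (cut-point selection, dichotomization, variable
    selection) is re-run on every resample, derivation of integer points
    from coefficient ratios, score-to-probability calibration, and
    evaluation of a score on grouped (score, n, events) tables:
    tie-corrected Mann-Whitney AUC, sensitivity/specificity/predictive
    values, Hosmer-Lemeshow goodness of fit, and paired AUC comparison by
    the DeLong method. A synthetic-cohort generator reproduces the
    covariate marginals and outcome model of the development setting so
    the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
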