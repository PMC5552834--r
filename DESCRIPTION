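Package: rlspanel
Title: Regularised Least-Squares Biomarker Panel Selection for Prospective Risk Cohorts
Version: 0.1.0
Authors@R: person("rlspanel", "maintainers", email = "rlspanel@example.org", role = c("aut", "cre"))
Description: Metabolomics-based disease-risk prediction for prospective
    cohorts: covariate-adjusted logistic association screening with
    false-discovery-rate q-values, regularised least-squares binary risk
    classification with closed-form leave-one-out error and greedy forward
    feature selection (GreedyRLS), repeated nested stratified
    cross-validation, external-cohort transfer by averaged model parameters,
    and discrimination statistics (AUC, DeLong's test for correlated ROC
    curves, discrimination slope, integrated discrimination improvement).
    Includes a synthetic-cohort generator with planted per-SD effect sizes so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
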