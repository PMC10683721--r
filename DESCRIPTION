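Package: thrombovar
Title: Explainable Machine-Learning Analysis of Between-Hospital Variation
    in Stroke Thrombolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study why emergency stroke hospitals differ in their
    use of thrombolysis. Provides a synthetic stroke-audit data generator
    with a known additive log-odds decision model and per-hospital
    propensity offsets; gradient-boosted tree classifiers of the
    thrombolysis decision (k-fold, all-data and held-out-cohort variants);
    SHAP main-effect and pairwise-interaction decompositions in log-odds,
    verified against a brute-force coalition-enumeration Shapley oracle;
    the "subset SHAP" statistic that splits each patient's attribution
    into patient-descriptive and hospital-descriptive components;
    counterfactual identical-cohort predictions that send one fixed
    cohort to every hospital; regression-based partitioning of
    between-hospital variance in thrombolysis rates; and observed and
    predicted thrombolysis rates for clinically defined patient
    subgroups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    data.table,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
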