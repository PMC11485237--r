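Package: fairshift
Title: Auditing Fairness of Clinical Prediction Models Under Distribution Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for auditing demographic fairness of clinical risk prediction
    models and for understanding how fairness behaves when models are deployed
    outside their training distribution. Computes per-group error rates,
    calibration and equal-opportunity gaps with bootstrap confidence intervals;
    quantifies prevalence, label, covariate and representation shifts with
    total-variation and kernel maximum-mean-discrepancy two-sample tests;
    measures demographic attribute encoding in frozen model embeddings with a
    regularized multinomial linear probe; analyses model grids via
    fairness-performance Pareto fronts, in-distribution to out-of-distribution
    transfer correlations, an exact decomposition of the out-of-distribution
    fairness gap, and oracle-regret evaluation of fairness-aware model selection
    criteria. Includes a seeded synthetic cohort and model-grid generator with
    closed-form group error rates for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'fairshift-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'metrics.R'
    'analysis.R'
    'decompose.R'
    'io.R'
    'synthetic.R'
    'selection.R'
    'pipeline.R'
    'probe.R'
    'shift.R'
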