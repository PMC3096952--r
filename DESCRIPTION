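Package: prognest
Title: Nested Cross-Validated Stability Selection for Cox Prognostic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and honestly assesses composite prognostic models of
    breast-cancer survival. Provides a Cox proportional-hazards prognostic
    index over molecular (AQUA/IHC protein scores) and clinico-pathological
    covariates, an average time-dependent AUCROC evaluation statistic
    computed from staircase ROC curves at each death event,
    performance-weighted stability-based backward elimination inside a
    nested (outer x inner 10-fold) cross-validation, Nottingham Prognostic
    Index stratification with Mann-Whitney model comparison, and a
    synthetic survival-cohort generator emulating a long-follow-up breast
    cancer cohort so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
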