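Package: metaboage
Title: Metabolomic Age and Lifespan Modeling Across Cohorts
Version: 0.1.0
Authors@R:
    person("Metaboage", "Developers", email = "maintainers@metaboage.dev",
           role = c("aut", "cre"))
Description: A tested pipeline for NMR metabolomic aging analysis across
    multiple cohorts: variable quality control, multivariate outlier
    weighting, between-cohort calibration, k-nearest-neighbour imputation
    and variance-inflation-factor pruning; metabolome-wide association
    studies of age and all-cause mortality pooled by inverse-variance
    fixed-effect meta-analysis with Cochran's Q and I2 heterogeneity;
    four metabolomic age/lifespan models (elastic net, degree-2
    multivariate adaptive regression splines, mortality-weighted
    "phenotypic" age, and a penalized-Cox mortality score rescaled to age
    units) plus scoring from published coefficient tables; 7-fold and
    leave-one-cohort-out validation and longitudinal delta-age reports;
    and chronological-age-adjusted association analyses with risk
    factors, biomarkers and incident events. Ships a multi-cohort
    synthetic data generator with known ground truth so every stage is
    testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
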