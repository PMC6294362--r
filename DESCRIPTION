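Package: bhvar
Title: Bayesian Hierarchical Vector Autoregression for Multi-Patient Diary Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sparse Bayesian hierarchical vector autoregressive (VAR) models to
    intensive longitudinal diary panels from many patients at once. Population-level
    lag coefficients carry a doubly adaptive elastic-net shrinkage prior and each
    patient receives multivariate-normal deviations from the population, so short,
    noisy per-patient series borrow strength across the panel. Estimation is by a
    parameter-expanded Gibbs sampler; the package also provides diary preprocessing
    (daily averaging, imputation, log transform, standardization, detrending),
    posterior summaries (empirical modes, credible intervals, significance flags,
    between-patient heterogeneity, Gelman-Rubin diagnostics), recursive posterior
    predictive forecasting with evaluation metrics (MSE, interval coverage, interval
    width comparison), per-patient maximum-likelihood VAR and cross-validated
    elastic-net comparators, and a synthetic-panel generator for the hierarchical
    VAR generative model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
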