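Package: fcsprior
Title: Fully Conditional Specification Imputation with Informative
    Normal-Inverse-Gamma Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian multiple imputation of multivariate normal data by fully
    conditional specification (chained equations) under normal linear models
    with informative normal-inverse-gamma priors. Provides the closed-form
    transformation from a joint normal-inverse-Wishart prior to the per-variable
    conditional normal-inverse-gamma priors (the non-informative-margins
    factorization), the joint-modelling data-augmentation sampler that serves as
    the gold-standard posterior, amputation routines for MCAR and right-tailed
    MAR missingness, Rubin's-rules pooling, and the validation experiments
    (bias/coverage tables, visit-sequence order-effect diagnostics with
    batch-means standard errors, and joint-model versus chained-equations
    posterior comparison) that demonstrate convergence of the chained-equations
    sampler to the joint Bayesian posterior.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
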