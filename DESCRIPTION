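Package: skewtlst
Title: Skew-t Mixture Latent State-Trait Models and Monte Carlo Evaluation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and estimating two-class finite mixture
    latent state-trait (LST) models in which the common trait follows a
    restricted multivariate skew-t distribution. Provides the restricted
    skew-t density, sampler and moment formulas (with the t, skew-normal
    and normal special cases), a constrained measurement-invariant LST
    model specification, maximum-likelihood estimation of the mixture with
    observed-information standard errors, label-switching detection and
    replication-inclusion rules, and Monte Carlo evaluation criteria
    (relative parameter bias, standard-error bias, mean squared error and
    confidence-interval coverage) over a sample-size by occasions by
    skewness design grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
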