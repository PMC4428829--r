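Package: mvrelef
Title: Multivariate Rank-Based Relative Effects with Studentized
    Permutation and Closed Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric two-group comparison of multivariate outcomes
    (such as DNA-methylation beta-values at several CpG loci) via
    coordinate-wise relative effects P(X_A < X_B) + P(X_A = X_B)/2.
    Provides Wald-type quadratic-form statistics studentized by a
    placement-based covariance estimator, asymptotic chi-square and
    studentized-permutation calibrations of the global null, the closure
    principle for strong family-wise error rate control with
    multiplicity-adjusted p-values, a Gaussian-copula beta-marginal
    simulation harness for type-I error, power and FWER experiments, and
    a two-stage screening/confirmation pipeline for locus discovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
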