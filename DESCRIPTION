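Package: mrmashrss
Title: Multivariate Polygenic Scores from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a multivariate, multiple-phenotype Bayesian multiple
    regression (the mr.mash model) from GWAS summary statistics and
    linkage-disequilibrium (LD) estimates, by coordinate-ascent variational
    empirical Bayes on the sufficient statistics (X'X, X'Y, Y'Y).  Effects
    across phenotypes share a mixture-of-multivariate-normals prior whose
    weights (and optionally the residual covariance) are adapted to the data
    by maximizing the evidence lower bound.  Includes canonical and
    data-driven prior covariance construction, a mash-style weight
    initialization for highly polygenic traits, linear polygenic scoring and
    accuracy evaluation, and a synthetic-data generator emulating
    LD-structured genotypes, sparse causal effects under several
    effect-sharing scenarios, single-variant GWAS scans, and
    missing-phenotype robustness settings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
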