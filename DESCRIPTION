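Package: spurgxe
Title: Screening-Testing Detection of Gene-Environment Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage screening-testing detection of gene-environment (GxE)
    interactions in case-control studies with additively coded genotypes.
    Implements the extended SPUR workflow: score-statistic prescreening of
    markers, a single elastic-net penalized multiple regression screening
    model per filter (marginal association or gene-environment correlation),
    an unpenalized joint logistic test-stage model with an omnibus likelihood
    ratio test and per-interaction Wald tests, and hierarchical false
    discovery rate control across the omnibus and interaction hypothesis
    levels. Also provides the one-step and standard screening-testing
    benchmark methods, a latent-Gaussian copula simulator for correlated
    genotypes with a coupled binary or continuous exposure, and a Monte Carlo
    harness for estimating type I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
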