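# Small programmatic fixtures shared across test files.

# Independent-SNP cohort with optional marginal / interaction effects.
tiny_cohort <- function(n = 150, p = 8, maf = 0.3, beta0 = -0.5, betaE = 0.3,
                        betaG = numeric(p), betaGE = numeric(p), seed = 1,
                        covariates = NULL) {
  set.seed(seed)
  g <- matrix(stats::rbinom(n * p, 2, maf), n, p)
  e <- stats::rbinom(n, 1, 0.5)
  eta <- beta0 + betaE * e + drop(g %*% betaG) + e * drop(g %*% betaGE)
  if (!is.null(covariates)) eta <- eta + drop(covariates %*% rep(0.2, ncol(covariates)))
  d <- stats::rbinom(n, 1, stats::plogis(eta))
  cohort(g, e, d, covariates = covariates)
}

# Fully null small design (no effects anywhere) for independence /
# uniformity properties.
flat_null_design <- function(n = 300, p = 200, seed = NULL) {
  simulation_design(n, p, maf = 0.2, snp_snp_corr = 0,
                    exposure_kind = "binary", exposure_prob = 0.5,
                    beta0 = -1, seed = seed)
}

# Brute-force step-up BH oracle (independent of bh_adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
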