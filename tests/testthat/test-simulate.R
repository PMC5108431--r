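# Frozen Monte Carlo regression constants (large-n draws / quadrature):
# - mean pairwise genotype correlation at maf 0.2, latent rho 0.1: 0.0675
# - realized genotype-exposure correlation for latent 0.05 / 0.3 at maf 0.2,
#   Bernoulli(0.5) exposure: 0.0325 / 0.1957
# - null-design disease prevalence: 0.1346 (n = 5e5 draw)

test_that("genotype marginals follow HWE within 3 Monte Carlo SEs", {
  n <- 50000
  for (maf in c(0.05, 0.2, 0.45)) {
    g <- simulate_genotypes(n, 3, maf = maf, rho = 0.1, seed = 7)
    probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    for (k in 0:2) {
      emp <- mean(g[, 1] == k)
      se <- sqrt(probs[k + 1] * (1 - probs[k + 1]) / n)
      expect_lt(abs(emp - probs[k + 1]), 3 * se + 1e-12)
    }
  }
})

test_that("latent rho controls realized genotype correlation", {
  n <- 50000
  g0 <- simulate_genotypes(n, 8, maf = 0.2, rho = 0, seed = 11)
  c0 <- cor(g0)
  expect_lt(max(abs(c0[upper.tri(c0)])), 0.02)

  g1 <- simulate_genotypes(n, 8, maf = 0.2, rho = 0.1, seed = 12)
  c1 <- cor(g1)
  expect_equal(mean(c1[upper.tri(c1)]), 0.0675, tolerance = 0.15)
  # quadrature prediction agrees with the frozen constant
  expect_equal(expected_genotype_corr(0.1, 0.2), 0.0675, tolerance = 1e-2)
})

test_that("genotype generation validates parameters and reproduces bitwise", {
  expect_error(simulate_genotypes(10, 2, maf = 0), "maf")
  expect_error(simulate_genotypes(10, 2, maf = 0.2, rho = 1.2), "rho")
  a <- simulate_genotypes(100, 5, 0.2, 0.1, seed = 3)
  b <- simulate_genotypes(100, 5, 0.2, 0.1, seed = 3)
  expect_identical(a, b)
})

test_that("exposure is independent of SNPs when no targets are set", {
  d <- simulation_design(50000, 6, maf = 0.2, snp_snp_corr = 0.1)
  g <- simulate_genotypes(50000, 6, 0.2, 0.1, seed = 21)
  e <- simulate_exposure(g, d, seed = 22)
  expect_true(all(e %in% c(0, 1)))
  expect_lt(max(abs(cor(e, g))), 0.02)
})

test_that("latent exposure targets realize the attenuated correlations", {
  # latent 0.3 -> observed ~0.1957; latent 0.05 -> observed ~0.0325
  d <- simulation_design(50000, 12, maf = 0.2, snp_snp_corr = 0.1,
                         snp_exposure_corr = setNames(rep(0.3, 5), 1:5))
  g <- simulate_genotypes(50000, 12, 0.2, 0.1, seed = 31)
  e <- simulate_exposure(g, d, seed = 32)
  expect_equal(unname(drop(cor(e, g[, 1:5]))), rep(0.1957, 5), tolerance = 0.1)
  expect_lt(max(abs(cor(e, g[, 6:12]))), 0.02)

  d2 <- simulation_design(50000, 12, maf = 0.2, snp_snp_corr = 0.1,
                          snp_exposure_corr = setNames(rep(0.05, 10), 1:10))
  e2 <- simulate_exposure(g, d2, seed = 33)
  expect_equal(unname(drop(cor(e2, g[, 1:10]))), rep(0.0325, 10),
               tolerance = 0.5)
})

test_that("observed-scale targets are calibrated through the copula", {
  d <- simulation_design(50000, 6, maf = 0.2, snp_snp_corr = 0,
                         snp_exposure_corr = setNames(rep(0.2, 3), 1:3),
                         exposure_corr_scale = "observed")
  g <- simulate_genotypes(50000, 6, 0.2, 0, seed = 41)
  e <- simulate_exposure(g, d, seed = 42)
  expect_equal(unname(drop(cor(e, g[, 1:3]))), rep(0.2, 3), tolerance = 0.1)
})

test_that("infeasible exposure correlation targets raise parameter errors", {
  # beyond the attainable bound for binary/genotype margins
  expect_error(
    simulation_design(1000, 5, maf = 0.2,
                      snp_exposure_corr = setNames(0.9, 1),
                      exposure_corr_scale = "observed") |>
      (\(d) simulate_exposure(simulate_genotypes(1000, 5, 0.2, 0, seed = 1),
                              d))(),
    "attainable bound"
  )
  # jointly infeasible latent loadings
  d <- simulation_design(1000, 5, maf = 0.2, snp_snp_corr = 0,
                         snp_exposure_corr = setNames(rep(0.7, 5), 1:5))
  g <- simulate_genotypes(1000, 5, 0.2, 0, seed = 2)
  expect_error(simulate_exposure(g, d), "infeasible")
})

test_that("outcome follows the logistic disease model", {
  n <- 50000
  g <- simulate_genotypes(n, 4, 0.2, 0, seed = 51)
  e <- rbinom(n, 1, 0.5)
  d0 <- simulation_design(n, 4, beta0 = 0)
  expect_equal(mean(simulate_outcome(g, e, d0, seed = 52)), 0.5,
               tolerance = 0.02)
  dneg <- simulation_design(n, 4, beta0 = -4)
  expect_equal(mean(simulate_outcome(g, e, dneg, seed = 53)),
               plogis(-4), tolerance = 0.2)
})

test_that("null-design prevalence matches the frozen large-n constant", {
  d <- make_null_design()
  d$n_subjects <- 50000L
  d$n_snps <- 10L
  d$betaG <- d$betaG[1:10]
  d$betaGE <- d$betaGE[1:10]
  co <- simulate_cohort(d, seed = 61)
  expect_equal(mean(co$outcome), 0.1346, tolerance = 0.05)
})

test_that("prevalence is monotone increasing in beta0", {
  n <- 20000
  g <- simulate_genotypes(n, 3, 0.2, 0, seed = 71)
  e <- rbinom(n, 1, 0.5)
  prev <- vapply(c(-2, -1, 0, 1), function(b0) {
    d <- simulation_design(n, 3, beta0 = b0, betaE = 0.3, betaG = 0.2)
    mean(simulate_outcome(g, e, d, seed = 72))
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("reference designs encode the study conditions", {
  d0 <- make_null_design()
  expect_equal(d0$n_subjects, 1000L)
  expect_equal(d0$n_snps, 2000L)
  expect_true(all(d0$betaGE == 0))
  expect_identical(which(d0$betaG != 0), 1:10)
  expect_identical(as.integer(names(d0$snp_exposure_corr)), 1:10)

  d1 <- make_power_design(1)
  expect_identical(which(d1$betaGE != 0), 1:5)
  expect_equal(unique(d1$betaGE[1:5]), log(3))
  expect_identical(as.integer(names(d1$snp_exposure_corr)), 6:10)
  expect_identical(which(d1$betaG != 0), 1:5)

  d2 <- make_power_design(2)
  expect_identical(which(d2$betaG != 0), 6:10)
  expect_equal(unique(d2$betaG[6:10]), log(3))
  expect_identical(as.integer(names(d2$snp_exposure_corr)), 1:5)
  expect_error(make_power_design(3), "model")
})

test_that("case-control sampling hits exact composition", {
  pool <- tiny_cohort(n = 400, p = 4, beta0 = 0, seed = 81)
  cc <- sample_case_control(pool, 50, 50, seed = 82)
  expect_equal(sum(cc$outcome == 1), 50)
  expect_equal(sum(cc$outcome == 0), 50)
  expect_equal(mean(cc$outcome), 0.5)

  # exhaustive request returns a permutation of the pool
  small <- subset_cohort(pool, subjects = c(which(pool$outcome == 1)[1:10],
                                            which(pool$outcome == 0)[1:10]))
  all20 <- sample_case_control(small, 10, 10, seed = 83)
  expect_equal(sort(rowSums(all20$genotypes) + 100 * all20$outcome),
               sort(rowSums(small$genotypes) + 100 * small$outcome))

  expect_error(sample_case_control(small, 11, 5, seed = 84), "deficit")
})

test_that("cohort validation rejects malformed inputs", {
  g <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_error(cohort(g, c(0, 1), c(0, 1)), "row 2, column 2")
  g[2, 2] <- 2
  expect_error(cohort(g, c(0, 1), c(0, 2)), "outcome")
  expect_error(cohort(g, c(0.5, 1), c(0, 1)), "binary exposure")
  expect_silent(cohort(g, c(0.5, 1), c(0, 1), exposure_kind = "continuous"))
  expect_error(cohort(g, c(0, 1), c(0, 1), marker_ids = c("a", "a")),
               "unique")
})
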