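test_that("one-step scan matches per-SNP glm fits", {
  co <- tiny_cohort(n = 250, p = 5, betaGE = c(0.7, rep(0, 4)), seed = 43)
  res <- one_step(co)
  expect_equal(res$tested_indices, 1:5)
  for (j in 1:5) {
    df <- data.frame(y = co$outcome, g = co$genotypes[, j], E = co$exposure)
    sm <- summary(stats::glm(y ~ g * E, stats::binomial(), df))$coefficients
    expect_equal(res$pvalues[j], unname(sm["g:E", 4]), tolerance = 1e-5)
    expect_equal(res$table$estimate[j], unname(sm["g:E", 1]), tolerance = 1e-5)
  }
  expect_equal(res$qvalues, bh_adjust(res$pvalues))
})

test_that("one-step honours covariates", {
  set.seed(47)
  cov <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("age", "pc1")))
  co <- tiny_cohort(n = 200, p = 3, seed = 47, covariates = cov)
  res <- one_step(co)
  df <- data.frame(y = co$outcome, g = co$genotypes[, 2], E = co$exposure, cov)
  sm <- summary(stats::glm(y ~ E + age + pc1 + g + g:E, stats::binomial(), df))
  expect_equal(res$pvalues[2], unname(sm$coefficients["E:g", 4]),
               tolerance = 1e-5)
})

test_that("single-marker filters match their glm / lm oracles", {
  co <- tiny_cohort(n = 250, p = 4, betaG = c(0.6, rep(0, 3)), seed = 53)
  flt <- spurgxe:::single_marker_filter(co, "marginal")
  for (j in 1:4) {
    sm <- summary(stats::glm(co$outcome ~ co$genotypes[, j],
                             stats::binomial()))$coefficients
    expect_equal(flt$pvalue[j], unname(sm[2, 4]), tolerance = 1e-4)
  }
  # continuous exposure: least-squares filter vs lm
  coc <- cohort(co$genotypes, rnorm(250), co$outcome,
                exposure_kind = "continuous")
  fltc <- spurgxe:::single_marker_filter(coc, "correlation")
  for (j in 1:4) {
    sm <- summary(stats::lm(coc$exposure ~ coc$genotypes[, j]))$coefficients
    expect_equal(fltc$pvalue[j], unname(sm[2, 4]), tolerance = 1e-8)
    expect_equal(fltc$estimate[j], unname(sm[2, 1]), tolerance = 1e-8)
  }
})

test_that("retaining all markers reproduces the one-step p-values", {
  co <- tiny_cohort(n = 200, p = 12, seed = 59)
  st <- standard_screening_testing(co, "marginal", retain = 12)
  os <- one_step(co)
  expect_equal(st$pvalues, os$pvalues)
  expect_setequal(st$tested_indices, os$tested_indices)
})

test_that("screening-testing is invariant to marker order", {
  co <- tiny_cohort(n = 300, p = 20, betaG = c(rep(0.6, 2), rep(0, 18)),
                    betaGE = c(0.8, rep(0, 19)), seed = 61)
  perm <- sample(20)
  st1 <- standard_screening_testing(co, "marginal", retain = 5)
  st2 <- standard_screening_testing(subset_cohort(co, markers = perm),
                                    "marginal", retain = 5)
  expect_setequal(co$marker_ids[significant_markers(st1, 0.2)],
                  subset_cohort(co, markers = perm)$marker_ids[
                    match(significant_markers(st2, 0.2), seq_along(perm))])
  expect_error(standard_screening_testing(co, "marginal", retain = 21),
               "retain")
})

test_that("filter rank and interaction p-value are independent under the null", {
  # the independence premise of screening-testing: under a fully null
  # design the stage-1 rank carries no information about the stage-2 test
  n_reps <- 120
  rs_marginal <- rs_correlation <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    co <- simulate_cohort(flat_null_design(n = 200, p = 60), seed = 5000 + r)
    os <- one_step(co)
    fm <- spurgxe:::single_marker_filter(co, "marginal")
    fc <- spurgxe:::single_marker_filter(co, "correlation")
    rs_marginal[r] <- suppressWarnings(
      stats::cor(rank(fm$pvalue), os$pvalues, method = "spearman",
                 use = "complete.obs"))
    rs_correlation[r] <- suppressWarnings(
      stats::cor(rank(fc$pvalue), os$pvalues, method = "spearman",
                 use = "complete.obs"))
  }
  expect_lt(abs(mean(rs_marginal)), 0.05)
  expect_lt(abs(mean(rs_correlation)), 0.05)
})
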