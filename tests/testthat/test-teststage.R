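test_that("test-stage fit agrees with glm on coefficients and tests", {
  co <- tiny_cohort(n = 300, p = 6, betaG = c(0.4, rep(0, 5)),
                    betaGE = c(0.6, rep(0, 5)), seed = 23)
  fit <- fit_test_stage(co, 1:3)
  df <- data.frame(y = co$outcome, E = co$exposure,
                   co$genotypes[, 1:3, drop = FALSE])
  ids <- co$marker_ids[1:3]
  fml <- stats::reformulate(
    c("E", ids, paste0(ids, ":E")), response = "y"
  )
  gm <- stats::glm(fml, stats::binomial(), df)
  sm <- summary(gm)$coefficients
  rows <- paste0("E:", ids)
  expect_equal(unname(fit$wald$estimate), unname(sm[rows, 1]), tolerance = 1e-6)
  expect_equal(unname(fit$wald$pvalue), unname(sm[rows, 4]), tolerance = 1e-5)
  red <- stats::glm(stats::reformulate(c("E", ids), "y"), stats::binomial(), df)
  expect_equal(fit$lr_stat,
               as.numeric(2 * (stats::logLik(gm) - stats::logLik(red))),
               tolerance = 1e-6)
  expect_equal(fit$lr_df, 3)
  expect_equal(fit$lr_pvalue,
               stats::pchisq(fit$lr_stat, 3, lower.tail = FALSE))
  # the wald table is the published interface
  expect_identical(wald_tests(fit), fit$wald)
  expect_equal(fit$wald$pvalue, 2 * stats::pnorm(-abs(fit$wald$z)))
})

test_that("q = 0 yields the degenerate identical-model fit", {
  co <- tiny_cohort(seed = 29)
  fit <- fit_test_stage(co, integer(0))
  expect_equal(fit$lr_stat, 0)
  expect_equal(fit$lr_pvalue, 1)
  expect_equal(nrow(fit$wald), 0)
})

test_that("log-likelihood nesting holds across random cohorts", {
  for (r in 1:40) {
    co <- tiny_cohort(n = 150, p = 8, seed = 400 + r)
    fit <- fit_test_stage(co, 1:3)
    if (!fit$converged) next
    expect_gte(fit$loglik_full, fit$loglik_reduced - 1e-8)
    expect_gte(fit$lr_stat, 0)
    expect_true(all(stats::na.omit(fit$wald$pvalue) >= 0 &
                      stats::na.omit(fit$wald$pvalue) <= 1))
  }
})

test_that("marker order permutation leaves the omnibus test unchanged", {
  co <- tiny_cohort(n = 250, p = 10, betaGE = c(0.5, rep(0, 9)), seed = 31)
  f1 <- fit_test_stage(co, c(1, 4, 7))
  f2 <- fit_test_stage(co, c(7, 1, 4))
  expect_equal(f1$lr_stat, f2$lr_stat, tolerance = 1e-8)
  m <- match(f1$wald$marker, f2$wald$marker)
  expect_equal(f1$wald$pvalue, f2$wald$pvalue[m], tolerance = 1e-8)
})

test_that("aliased designs are handled with a warning", {
  co <- tiny_cohort(n = 200, p = 5, seed = 37)
  co$exposure <- rep(1, 200)  # interaction columns duplicate the marginals
  expect_warning(fit <- fit_test_stage(co, 1:2), "aliased")
  expect_equal(fit$lr_df, 0)
  expect_equal(fit$lr_pvalue, 1)
  expect_true(all(fit$wald$flagged))
  expect_true(all(is.na(fit$wald$pvalue)))
})

test_that("Wald and per-term LR tests agree asymptotically", {
  co <- tiny_cohort(n = 1000, p = 10, beta0 = -1,
                    betaGE = c(0.45, 0.35, rep(0, 8)), seed = 41)
  fw <- fit_test_stage(co, 1:5, interaction_test = "wald")
  fl <- fit_test_stage(co, 1:5, interaction_test = "lr")
  band <- !is.na(fw$wald$pvalue) & fw$wald$pvalue >= 0.01 & fw$wald$pvalue <= 0.5
  expect_true(any(band))
  expect_lt(max(abs(fw$wald$pvalue[band] - fl$wald$pvalue[band])), 0.02)
})
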