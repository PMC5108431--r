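test_that("lambda-for-q selection follows the path and bisects brackets", {
  path <- data.frame(lambda = c(1, 0.5, 0.25), nonzero = c(0, 3, 5))
  sel <- select_lambda_for_q(path, 5)
  expect_equal(sel$lambda, 0.25)
  expect_true(sel$exact)

  # q skipped on the path, no refit: closest count above q, not exact
  path2 <- data.frame(lambda = c(1, 0.5, 0.25), nonzero = c(0, 3, 8))
  sel2 <- select_lambda_for_q(path2, 5)
  expect_equal(sel2$lambda, 0.25)
  expect_false(sel2$exact)

  # with a refit callback the bracket is bisected to an exact count
  counts <- function(lam) sum(lam <= c(0.9, 0.8, 0.45, 0.4, 0.35, 0.3, 0.28, 0.26))
  path3 <- data.frame(lambda = c(1, 0.5, 0.25), nonzero = c(counts(1), counts(0.5), counts(0.25)))
  sel3 <- select_lambda_for_q(path3, 5, refit = counts)
  expect_true(sel3$exact)
  expect_equal(counts(sel3$lambda), 5)

  expect_warning(s <- select_lambda_for_q(path, 9), "max achieved")
  expect_equal(s$nonzero, 5)
  expect_error(select_lambda_for_q(list(lambda = numeric(0), nonzero = numeric(0)), 2),
               "empty")
})

test_that("screening selects exactly q markers at the tuned penalty", {
  co <- tiny_cohort(n = 400, p = 60, beta0 = -0.5,
                    betaG = c(rep(0.4, 3), rep(0, 57)), seed = 11)
  res <- fit_screening_model(co, NULL, filter_spec("marginal", q = 10))
  expect_length(res$selected_indices, 10)
  expect_equal(res$achieved, 10)
  expect_length(res$coefficients, 10)
  expect_true(all(res$coefficients != 0))

  # correlation filter with binary exposure uses the exposure as response
  resc <- fit_screening_model(co, NULL, filter_spec("correlation", q = 5))
  expect_length(resc$selected_indices, 5)
})

test_that("screening respects the prescreen and maps to global indices", {
  co <- tiny_cohort(n = 300, p = 40, betaG = c(rep(0.5, 2), rep(0, 38)),
                    seed = 13)
  pre <- prescreen(co, "marginal", k = 20)
  res <- fit_screening_model(co, pre, filter_spec("marginal", q = 6))
  expect_true(all(res$selected_indices %in% pre$kept_indices))
  expect_error(fit_screening_model(co, prescreen(co, "marginal", k = 3),
                                   filter_spec("marginal", q = 6)),
               "only 3 markers")
})

test_that("a strongly associated SNP is reliably screened in", {
  hits <- 0
  for (r in 1:20) {
    co <- tiny_cohort(n = 1000, p = 100, beta0 = -1,
                      betaG = c(log(3), rep(0, 99)), seed = 100 + r)
    res <- fit_screening_model(co, NULL, filter_spec("marginal", q = 1))
    hits <- hits + (res$selected_indices[1] == 1)
  }
  expect_gte(hits, 19)
})

test_that("covariates enter the screening model unpenalized", {
  set.seed(17)
  cov <- matrix(rnorm(300), 300, 1, dimnames = list(NULL, "age"))
  co <- tiny_cohort(n = 300, p = 30, seed = 17, covariates = cov)
  res <- fit_screening_model(co, NULL, filter_spec("marginal", q = 4))
  # the selection counts genotype coefficients only
  expect_length(res$selected_indices, 4)
})

test_that("selection is invariant to marker column order", {
  co <- tiny_cohort(n = 400, p = 30, betaG = c(rep(0.5, 3), rep(0, 27)),
                    seed = 19)
  perm <- sample(30)
  co2 <- subset_cohort(co, markers = perm)
  r1 <- fit_screening_model(co, NULL, filter_spec("marginal", q = 5))
  r2 <- fit_screening_model(co2, NULL, filter_spec("marginal", q = 5))
  expect_setequal(co$marker_ids[r1$selected_indices],
                  co2$marker_ids[r2$selected_indices])
})

test_that("default_q implements the observations-per-predictor budget", {
  # (70/7 - 1 exposure) / 2 terms per marker -> 4
  expect_equal(default_q(70, 0), 4L)
  expect_equal(default_q(572, 3), 38L)
  expect_equal(default_q(572, 3, reserve = 4), 36L)
  expect_error(default_q(20, 0), "too small")
})
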