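#' Filter specification for the penalized screening stage
#'
#' @param filter `"marginal"` (penalized logistic model of the outcome on all
#'   kept markers) or `"correlation"` (penalized model of the exposure on all
#'   kept markers: logistic for a binary exposure, least squares for a
#'   continuous one).
#' @param q Number of markers to select (nonzero penalized genotype
#'   coefficients).
#' @param alpha Elastic-net mixing parameter in [0, 1]; 1 is pure lasso, 0
#'   pure ridge. The default 0.999 is lasso with a small ridge component for
#'   estimation stability.
#' @param exposure_kind `"binary"` or `"continuous"` (used by the correlation
#'   filter).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(filter = c("marginal", "correlation"), q,
                        alpha = 0.999,
                        exposure_kind = c("binary", "continuous")) {
  filter <- match.arg(filter)
  exposure_kind <- match.arg(exposure_kind)
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must be in [0, 1]", call. = FALSE)
  q <- as.integer(q)
  if (q < 1) stop("q must be at least 1", call. = FALSE)
  structure(
    list(filter = filter, alpha = alpha, q = q, exposure_kind = exposure_kind),
    class = "filter_spec"
  )
}

#' Choose the elastic-net penalty that yields q nonzero coefficients
#'
#' Given a regularization path as (lambda, nonzero-count) pairs sorted by
#' decreasing lambda, returns the largest lambda whose count is at least `q`.
#' If that count exceeds `q` and a `refit` callback is supplied, the bracket
#' between the neighboring path points is bisected (each probe refits at the
#' probed lambda) until the count equals `q` or the bracket collapses.
#' Coordinate-descent paths can drop several variables into the model at one
#' step, so an exact count of `q` is not always achievable; in that case the
#' returned lambda gives the closest count above `q` and `exact` is `FALSE`
#' (the caller truncates to the `q` largest-magnitude coefficients).
#'
#' @param path Data frame (or list) with components `lambda` (decreasing) and
#'   `nonzero`.
#' @param q Desired nonzero count.
#' @param refit Optional `function(lambda) -> nonzero count` used for
#'   bisection between path points.
#' @param max_bisect Maximum bisection probes.
#' @return List with `lambda`, `nonzero` (achieved count at `lambda`) and
#'   `exact` (`TRUE` when `nonzero == q`).
#' @export
#' @examples
#' select_lambda_for_q(data.frame(lambda = c(1, 0.5, 0.25), nonzero = c(0, 3, 5)), 5)
select_lambda_for_q <- function(path, q, refit = NULL, max_bisect = 30) {
  lambda <- path$lambda
  nonzero <- path$nonzero
  if (!length(lambda)) stop("empty regularization path", call. = FALSE)
  if (is.unsorted(rev(lambda))) {
    o <- order(lambda, decreasing = TRUE)
    lambda <- lambda[o]
    nonzero <- nonzero[o]
  }
  hit <- which(nonzero >= q)
  if (!length(hit)) {
    warning(sprintf(
      "no lambda on the path yields %d nonzero coefficients (max achieved: %d)",
      q, max(nonzero)
    ), call. = FALSE)
    i <- which.max(nonzero)
    return(list(lambda = lambda[i], nonzero = nonzero[i], exact = FALSE))
  }
  i <- hit[1]
  if (nonzero[i] == q || is.null(refit) || i == 1) {
    return(list(lambda = lambda[i], nonzero = nonzero[i],
                exact = nonzero[i] == q))
  }
  # bisect between the last lambda with count < q and the first with count > q
  lo <- lambda[i]       # smaller lambda, count > q
  hi <- lambda[i - 1]   # larger lambda, count < q
  best <- list(lambda = lo, nonzero = nonzero[i], exact = FALSE)
  for (it in seq_len(max_bisect)) {
    mid <- sqrt(lo * hi)  # lambda paths are log-spaced
    cnt <- refit(mid)
    if (cnt == q) return(list(lambda = mid, nonzero = cnt, exact = TRUE))
    if (cnt > q) {
      if (cnt < best$nonzero) best <- list(lambda = mid, nonzero = cnt, exact = FALSE)
      lo <- mid
    } else {
      hi <- mid
    }
    if (hi / lo < 1 + 1e-6) break
  }
  best
}

#' Fit the penalized screening model and select q markers
#'
#' Fits a single elastic-net penalized multiple regression of the filter
#' target (outcome for the marginal-association filter, exposure for the
#' gene-environment correlation filter) on all prescreened markers jointly,
#' with covariates entering unpenalized, and picks the penalty so that
#' exactly `q` genotype coefficients are nonzero (see
#' [select_lambda_for_q()]; when `q` is skipped by the coordinate-descent
#' path the selection is truncated to the `q` largest standardized
#' coefficients). Genotype columns are standardized internally; coefficients
#' are reported on the original scale.
#'
#' @param cohort A [cohort()].
#' @param kept A [prescreen()] result, or `NULL` to screen all markers.
#' @param spec A [filter_spec()].
#' @return A list of class `screen_result`: `selected_indices` (q global
#'   marker indices, ordered by decreasing |standardized coefficient|),
#'   `lambda`, `coefficients` (named, original scale, over the selected
#'   markers), `achieved` (nonzero count at `lambda`), `filter`, `q`.
#' @export
fit_screening_model <- function(cohort, kept = NULL, spec) {
  stopifnot(inherits(cohort, "gxe_cohort"), inherits(spec, "filter_spec"))
  keep_idx <- if (is.null(kept)) seq_len(n_markers(cohort)) else kept$kept_indices
  if (length(keep_idx) < spec$q) {
    stop(sprintf("only %d markers available for screening but q=%d",
                 length(keep_idx), spec$q), call. = FALSE)
  }
  X <- cohort$genotypes[, keep_idx, drop = FALSE]
  nc <- ncol(cohort$covariates)
  if (nc) X <- cbind(X, cohort$covariates)
  pf <- c(rep(1, length(keep_idx)), rep(0, nc))
  gcols <- seq_along(keep_idx)

  if (spec$filter == "marginal") {
    y <- cohort$outcome
    family <- "binomial"
  } else {
    y <- cohort$exposure
    family <- if (cohort$exposure_kind == "binary") "binomial" else "gaussian"
  }
  fit <- glmnet::glmnet(
    X, y, family = family, alpha = spec$alpha, penalty.factor = pf,
    standardize = TRUE, nlambda = 100, thresh = 1e-7, maxit = 1e5
  )
  beta_path <- fit$beta[gcols, , drop = FALSE]
  nonzero <- Matrix::colSums(beta_path != 0)
  if (max(nonzero) == 0) {
    stop("no lambda on the path yields a nonzero genotype coefficient", call. = FALSE)
  }
  coef_at <- function(lam) {
    b <- glmnet::coef.glmnet(fit, s = lam, exact = TRUE, x = X, y = y,
                             family = family, alpha = spec$alpha,
                             penalty.factor = pf, standardize = TRUE,
                             thresh = 1e-7, maxit = 1e5)
    as.numeric(b[1 + gcols])  # drop intercept row, keep genotype rows
  }
  sel <- select_lambda_for_q(
    list(lambda = fit$lambda, nonzero = nonzero), spec$q,
    refit = function(lam) sum(coef_at(lam) != 0)
  )
  if (!sel$exact && sel$nonzero < spec$q) {
    warning(sprintf("screening achieved only %d of the requested %d markers",
                    sel$nonzero, spec$q), call. = FALSE)
  }
  b <- coef_at(sel$lambda)
  nz <- which(b != 0)
  # rank by standardized magnitude so truncation is scale-free
  sds <- apply(X[, nz, drop = FALSE], 2, stats::sd)
  ord <- nz[order(-(abs(b[nz]) * sds), nz)]
  take <- ord[seq_len(min(spec$q, length(ord)))]
  selected <- keep_idx[take]
  structure(
    list(
      selected_indices = selected, lambda = sel$lambda,
      coefficients = stats::setNames(b[take], cohort$marker_ids[selected]),
      achieved = length(take), requested = spec$q, exact = sel$exact,
      filter = spec$filter, alpha = spec$alpha
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "screen_result: %s filter, %d markers selected at lambda=%.4g (alpha=%.3g)\n",
    x$filter, x$achieved, x$lambda, x$alpha
  ))
  invisible(x)
}

#' Default number of screened markers from the observation-to-predictor rule
#'
#' Largest `q` such that the test-stage model's predictor count (exposure +
#' covariates + q marginal + q interaction terms; the intercept is not
#' counted) stays within `n / ratio`, following the 7-to-1
#' observation-to-predictor guideline for multiple logistic regression.
#' `reserve` adds further non-marker predictors to the count (e.g., extra
#' dummy columns), making other published counting conventions expressible.
#'
#' @param n Number of observations.
#' @param n_covariates Number of covariate columns in the test-stage model.
#' @param ratio Observations per predictor (default 7).
#' @param reserve Additional predictors counted against the budget.
#' @return Integer q >= 1.
#' @export
#' @examples
#' default_q(70, 0) # 4
default_q <- function(n, n_covariates = 0, ratio = 7, reserve = 0) {
  budget <- n / ratio - 1 - n_covariates - reserve
  q <- floor(budget / 2)
  if (q < 1) {
    stop(sprintf(
      "n=%d is too small for any marker at a %g:1 observation-to-predictor ratio",
      n, ratio
    ), call. = FALSE)
  }
  as.integer(q)
}
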