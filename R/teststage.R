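# Unpenalized joint test-stage model and its omnibus / per-interaction tests.

# Logistic fit via glm.fit with aliasing tolerated (aliased columns get NA
# coefficients, as in lm). Returns the log-likelihood (exact for 0/1
# outcomes: -deviance/2) and Wald covariance over the estimable columns.
fit_logistic_matrix <- function(X, y, maxit = 100, tol = 1e-8) {
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = maxit)
  ))
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  se <- rep(NA_real_, length(coefs))
  if (any(!aliased)) {
    w <- fit$weights
    Xok <- X[, !aliased, drop = FALSE]
    xtwx <- crossprod(Xok * sqrt(w))
    cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
    if (!is.null(cov)) se[!aliased] <- sqrt(diag(cov))
  }
  list(
    coefficients = coefs, se = se, aliased = aliased,
    loglik = -fit$deviance / 2, converged = fit$converged,
    boundary = fit$boundary
  )
}

#' Fit the joint unpenalized test-stage model
#'
#' Fits the full logistic model
#' `logit P(D=1) = b0 + bE*E + covariates + sum_i bG_i G_i + sum_i bGE_i G_i E`
#' over the `q` selected markers, and the nested reduced model without the
#' interaction terms. Reports the omnibus likelihood-ratio test of
#' `H0: all bGE_i = 0` (chi-square with df = number of estimable interaction
#' terms) and per-interaction Wald tests. Aliased columns are dropped with a
#' warning; interactions whose estimates diverge beyond 15 on the logit scale
#' (separation) or whose fit did not converge are flagged and carry `NA`
#' p-values so that FDR families exclude them.
#'
#' @param cohort A [cohort()].
#' @param selected Integer vector of q marker indices (e.g.,
#'   `screen_result$selected_indices`). `q = 0` yields the degenerate fit
#'   with `lr_stat = 0`, `lr_pvalue = 1`.
#' @param interaction_test `"wald"` (default) or `"lr"` (per-term
#'   likelihood-ratio tests, one refit per marker).
#' @return A list of class `test_stage_fit` with elements
#'   `selected_indices`, `marker_ids`, `coefficients`, `se`,
#'   `loglik_full`, `loglik_reduced`, `lr_stat`, `lr_df`, `lr_pvalue`,
#'   `wald` (data frame: `marker`, `marker_id`, `estimate`, `se`, `z`,
#'   `pvalue`, `flagged`), `converged`, `dropped` (aliased column names).
#' @export
fit_test_stage <- function(cohort, selected,
                           interaction_test = c("wald", "lr")) {
  stopifnot(inherits(cohort, "gxe_cohort"))
  interaction_test <- match.arg(interaction_test)
  selected <- as.integer(selected)
  q <- length(selected)
  y <- cohort$outcome
  ids <- cohort$marker_ids[selected]

  if (q == 0) {
    return(structure(
      list(
        selected_indices = integer(0), marker_ids = character(0),
        coefficients = numeric(0), se = numeric(0),
        loglik_full = NA_real_, loglik_reduced = NA_real_,
        lr_stat = 0, lr_df = 0L, lr_pvalue = 1,
        wald = data.frame(
          marker = integer(0), marker_id = character(0), estimate = numeric(0),
          se = numeric(0), z = numeric(0), pvalue = numeric(0),
          flagged = logical(0)
        ),
        converged = TRUE, dropped = character(0)
      ),
      class = "test_stage_fit"
    ))
  }

  G <- cohort$genotypes[, selected, drop = FALSE]
  GE <- G * cohort$exposure
  colnames(GE) <- paste0(ids, ":E")
  Xred <- cbind(`(Intercept)` = 1, E = cohort$exposure, cohort$covariates, G)
  Xfull <- cbind(Xred, GE)

  full <- fit_logistic_matrix(Xfull, y)
  red <- fit_logistic_matrix(Xred, y)
  if (any(full$aliased)) {
    warning(sprintf(
      "dropped aliased test-stage columns: %s",
      paste(colnames(Xfull)[full$aliased], collapse = ", ")
    ), call. = FALSE)
  }
  if (!full$converged || !red$converged) {
    warning("test-stage IRLS did not converge; results are flagged", call. = FALSE)
  }

  int_cols <- ncol(Xred) + seq_len(q)
  est <- full$coefficients[int_cols]
  se <- full$se[int_cols]
  lr_df <- sum(!full$aliased[int_cols])
  lr_stat <- max(0, 2 * (full$loglik - red$loglik))
  lr_pvalue <- if (lr_df > 0) {
    stats::pchisq(lr_stat, df = lr_df, lower.tail = FALSE)
  } else 1

  flagged <- is.na(est) | is.na(se) | se <= 0 |
    abs(est) > separation_cap | !full$converged
  z <- ifelse(flagged, NA_real_, est / se)
  pv <- ifelse(flagged, NA_real_, 2 * stats::pnorm(-abs(z)))

  if (interaction_test == "lr") {
    for (i in seq_len(q)) {
      if (flagged[i]) next
      sub <- fit_logistic_matrix(Xfull[, -int_cols[i], drop = FALSE], y)
      pv[i] <- stats::pchisq(2 * (full$loglik - sub$loglik), df = 1,
                             lower.tail = FALSE)
    }
  }

  structure(
    list(
      selected_indices = selected, marker_ids = ids,
      coefficients = full$coefficients, se = full$se,
      loglik_full = full$loglik, loglik_reduced = red$loglik,
      lr_stat = lr_stat, lr_df = lr_df, lr_pvalue = lr_pvalue,
      wald = data.frame(
        marker = selected, marker_id = ids, estimate = unname(est),
        se = unname(se), z = unname(z), pvalue = unname(pv), flagged = flagged,
        row.names = NULL
      ),
      converged = full$converged && red$converged,
      dropped = colnames(Xfull)[full$aliased]
    ),
    class = "test_stage_fit"
  )
}

#' Per-interaction Wald table of a test-stage fit
#'
#' @param fit A [fit_test_stage()] result.
#' @return Data frame with one row per selected marker: `marker`,
#'   `marker_id`, `estimate`, `se`, `z`, `pvalue`, `flagged`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "test_stage_fit"))
  fit$wald
}

#' @export
print.test_stage_fit <- function(x, ...) {
  cat(sprintf(
    "test_stage_fit: %d markers; omnibus LR = %.3f on %d df (p = %.4g)\n",
    length(x$selected_indices), x$lr_stat, x$lr_df, x$lr_pvalue
  ))
  if (length(x$dropped)) {
    cat("  dropped (aliased):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
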