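# R wrappers around the compiled per-SNP IRLS workers. Estimates with
# |coefficient| above `separation_cap` on the logit scale are treated as
# (quasi-)separated fits: the estimate is kept but the Wald p-value is set to
# NA so downstream FDR families exclude it.

separation_cap <- 15

wald_p <- function(estimate, se) {
  2 * stats::pnorm(-abs(estimate / se))
}

#' Per-SNP interaction scan
#'
#' Fits the single-SNP interaction model
#' `logit P(D=1) = b0 + bG*G_j + bE*E + bGE*G_j*E (+ covariates)` for every
#' marker and returns Wald inference on the interaction coefficient.
#' Non-converged or separated fits carry `NA` p-values.
#'
#' @param cohort A [cohort()].
#' @param markers Marker indices to scan (default all).
#' @param maxit,tol IRLS controls.
#' @return Data frame with one row per scanned marker: `marker`, `estimate`
#'   (interaction log-odds), `se`, `pvalue`, `converged`.
#' @export
interaction_scan <- function(cohort, markers = NULL, maxit = 50, tol = 1e-8) {
  stopifnot(inherits(cohort, "gxe_cohort"))
  if (is.null(markers)) markers <- seq_len(n_markers(cohort))
  fit <- batch_interaction_glm_cpp(
    cohort$outcome, cohort$genotypes[, markers, drop = FALSE],
    cohort$exposure, cohort$covariates, maxit, tol
  )
  ok <- fit$converged & !is.na(fit$estimate) &
    abs(fit$estimate) <= separation_cap & fit$se > 0
  p <- rep(NA_real_, length(markers))
  p[ok] <- wald_p(fit$estimate[ok], fit$se[ok])
  data.frame(
    marker = markers, estimate = fit$estimate, se = fit$se,
    pvalue = p, converged = fit$converged
  )
}

# Single-marker filter models: per-SNP p-value for the genotype coefficient.
# filter = "marginal": logistic outcome ~ G_j; "correlation": logistic
# exposure ~ G_j for binary exposures, least squares for continuous ones.
single_marker_filter <- function(cohort, filter = c("marginal", "correlation"),
                                 markers = NULL, maxit = 50, tol = 1e-8) {
  stopifnot(inherits(cohort, "gxe_cohort"))
  filter <- match.arg(filter)
  if (is.null(markers)) markers <- seq_len(n_markers(cohort))
  G <- cohort$genotypes[, markers, drop = FALSE]
  if (filter == "correlation" && cohort$exposure_kind == "continuous") {
    return(linear_filter(cohort$exposure, G, cohort$covariates, markers))
  }
  y <- if (filter == "marginal") cohort$outcome else cohort$exposure
  fit <- batch_single_glm_cpp(y, G, cohort$covariates, maxit, tol)
  ok <- fit$converged & !is.na(fit$estimate) &
    abs(fit$estimate) <= separation_cap & fit$se > 0
  p <- rep(NA_real_, length(markers))
  p[ok] <- wald_p(fit$estimate[ok], fit$se[ok])
  data.frame(
    marker = markers, estimate = fit$estimate, se = fit$se,
    pvalue = p, converged = fit$converged
  )
}

# Vectorized per-SNP least-squares filter for a continuous exposure:
# E ~ G_j (+ covariates), t-test on the genotype slope. Exposure and
# genotypes are residualized on [1, covariates] first (Frisch-Waugh).
linear_filter <- function(e, G, C, markers) {
  n <- length(e)
  q0 <- qr(cbind(1, C))
  er <- qr.resid(q0, e)
  Gr <- qr.resid(q0, G)
  gss <- colSums(Gr^2)
  b <- as.numeric(crossprod(Gr, er)) / gss
  rss <- sum(er^2) - b^2 * gss
  df <- n - q0$rank - 1
  se <- sqrt(pmax(rss, 0) / df / gss)
  tt <- b / se
  p <- 2 * stats::pt(-abs(tt), df)
  p[gss <= 1e-12] <- NA_real_
  data.frame(
    marker = markers, estimate = b, se = se, pvalue = p,
    converged = gss > 1e-12
  )
}
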