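#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1.
#' Missing entries (e.g., flagged non-converged fits) are excluded from the
#' family size m and returned as `NA`.
#'
#' @param pvalues Numeric vector in [0, 1], `NA` allowed.
#' @return Adjusted values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Effective FDR level of two-level hierarchical testing
#'
#' Level-wise BH testing of a two-level hypothesis tree at nominal level `q`
#' controls the level-specific FDR at approximately
#' `q * delta_star * (d + f) / (d + 1)`, where `f` is the number of families
#' tested and `d` the number of discoveries in the level (`delta_star` is
#' approximately 1).
#'
#' @param q Nominal FDR level in (0, 1).
#' @param f Number of families tested (>= 1).
#' @param d Number of discoveries (>= 0).
#' @param delta_star Correction factor, default 1.
#' @return The effective FDR level.
#' @export
#' @examples
#' effective_fdr_level(0.1, f = 2, d = 4) # 0.12
effective_fdr_level <- function(q, f, d, delta_star = 1) {
  stopifnot(q > 0, q < 1, f >= 1, d >= 0)
  q * delta_star * (d + f) / (d + 1)
}

#' Two-level hierarchical FDR
#'
#' Parents (omnibus likelihood-ratio hypotheses, one per filter) are tested
#' by BH at level `q`; the child family of per-interaction hypotheses under
#' each *rejected* parent is then tested by BH at level `q`. Children of
#' non-rejected parents are never tested. The effective FDR level of the
#' child level is reported via [effective_fdr_level()] with `d` the total
#' number of child rejections and `f` the number of parent families.
#'
#' @param parent_pvalues Numeric vector of f omnibus p-values.
#' @param children List of f numeric vectors: per-parent child p-values
#'   (`NA` entries are excluded from their family's size).
#' @param q Nominal FDR level.
#' @param delta_star Passed to [effective_fdr_level()].
#' @return A list of class `hierarchy_result`: `parent_pvalues`,
#'   `parent_qvalues`, `rejected_parents` (indices), `child_tables` (list of
#'   data frames with `pvalue`, `qvalue`, `rejected`; `NULL` for untested
#'   families), `discoveries` (d), `effective_level`, `q`, `f`.
#' @export
hierarchical_fdr <- function(parent_pvalues, children, q = 0.1, delta_star = 1) {
  f <- length(parent_pvalues)
  if (f < 1) stop("at least one parent p-value is required", call. = FALSE)
  if (length(children) != f) {
    stop("children must hold one p-value vector per parent", call. = FALSE)
  }
  parent_q <- bh_adjust(parent_pvalues)
  rejected <- which(!is.na(parent_q) & parent_q <= q)
  child_tables <- vector("list", f)
  d <- 0L
  for (i in rejected) {
    pv <- children[[i]]
    qv <- bh_adjust(pv)
    rej <- !is.na(qv) & qv <= q
    d <- d + sum(rej)
    child_tables[[i]] <- data.frame(pvalue = pv, qvalue = qv, rejected = rej)
  }
  structure(
    list(
      parent_pvalues = parent_pvalues, parent_qvalues = parent_q,
      rejected_parents = rejected, child_tables = child_tables,
      discoveries = d,
      effective_level = effective_fdr_level(q, f, d, delta_star),
      q = q, f = f
    ),
    class = "hierarchy_result"
  )
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat(sprintf(
    "hierarchy_result: %d/%d parent families rejected at q=%.3g, %d child discoveries\n  effective child-level FDR bound: %.4g\n",
    length(x$rejected_parents), x$f, x$q, x$discoveries, x$effective_level
  ))
  invisible(x)
}
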