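#' Score-statistic for marker ranking
#'
#' Computes, for each genotype column, the absolute centered cross-product
#' `a_j = | sum_i (y_i - ybar) * G_ij |` between a target variable (the
#' outcome for the marginal-association filter, the exposure for the
#' gene-environment correlation filter) and the marker. This is the score
#' statistic used to rank markers before penalized regression; it requires a
#' single pass over the genotype matrix.
#'
#' @param target Length-n numeric vector (outcome or exposure).
#' @param genotypes n x p genotype matrix.
#' @return Length-p nonnegative vector of scores.
#' @export
#' @examples
#' score_statistic(c(1, 0), matrix(c(1, 0, 2, 2), 2, 2))
score_statistic <- function(target, genotypes) {
  genotypes <- as.matrix(genotypes)
  if (length(target) != nrow(genotypes)) {
    stop("target length must match the number of genotype rows", call. = FALSE)
  }
  centered <- target - mean(target)
  if (all(centered == 0)) {
    warning("target is constant; all score statistics are 0", call. = FALSE)
    return(numeric(ncol(genotypes)))
  }
  abs(as.numeric(crossprod(genotypes, centered)))
}

#' Score-statistic prescreening
#'
#' Reduces p markers to the k with the largest score statistics before the
#' penalized screening model is fit. The marginal filter scores markers
#' against the outcome, the correlation filter against the exposure. This is
#' a simplified score filter: k is taken as given (at least 20 times the
#' downstream selection size q is recommended) and no KKT verification or
#' iterative enlargement of k is performed.
#'
#' @param cohort A [cohort()].
#' @param filter `"marginal"` (score against the outcome) or `"correlation"`
#'   (score against the exposure).
#' @param k Number of markers to keep, `k <= p`. Ties at the boundary keep
#'   the lower marker index.
#' @return A list of class `prescreen_result` with elements `scores`
#'   (length p), `kept_indices` (length k, ordered by decreasing score), `k`,
#'   and `target_kind` (`"outcome"` or `"exposure"`).
#' @export
prescreen <- function(cohort, filter = c("marginal", "correlation"), k) {
  stopifnot(inherits(cohort, "gxe_cohort"))
  filter <- match.arg(filter)
  p <- n_markers(cohort)
  k <- as.integer(k)
  if (k < 1 || k > p) {
    stop(sprintf("k must be in [1, p]; got k=%d with p=%d", k, p), call. = FALSE)
  }
  target <- if (filter == "marginal") cohort$outcome else cohort$exposure
  scores <- score_statistic(target, cohort$genotypes)
  # order by decreasing score; ties broken toward the lower marker index
  kept <- order(-scores, seq_along(scores))[seq_len(k)]
  structure(
    list(
      scores = scores, kept_indices = kept, k = k,
      target_kind = if (filter == "marginal") "outcome" else "exposure",
      filter = filter
    ),
    class = "prescreen_result"
  )
}

#' @export
print.prescreen_result <- function(x, ...) {
  cat(sprintf(
    "prescreen_result: %s filter, kept %d of %d markers (min kept score %.4g)\n",
    x$filter, x$k, length(x$scores), min(x$scores[x$kept_indices])
  ))
  invisible(x)
}
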