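# Benchmark G-E detection methods: one-step per-SNP testing and standard
# (single-marker filter) screening-testing.

new_benchmark_result <- function(method, tested, table, filter_table = NULL) {
  structure(
    list(
      method = method, tested_indices = tested,
      pvalues = table$pvalue, qvalues = bh_adjust(table$pvalue),
      table = table, filter_table = filter_table
    ),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "benchmark_result (%s): %d interactions tested, min q-value %.4g\n",
    x$method, length(x$tested_indices),
    suppressWarnings(min(x$qvalues, na.rm = TRUE))
  ))
  invisible(x)
}

#' One-step per-SNP interaction testing
#'
#' Fits the single-SNP interaction model for every marker and BH-adjusts the
#' interaction p-values over the whole family of p tests. Simple, but pays
#' the full multiplicity penalty of p hypotheses.
#'
#' @param cohort A [cohort()].
#' @return A `benchmark_result` with `tested_indices = 1:p`, per-marker
#'   `pvalues` and BH `qvalues` (non-converged fits carry `NA`).
#' @export
one_step <- function(cohort) {
  scan <- interaction_scan(cohort)
  new_benchmark_result("one_step", scan$marker, scan)
}

#' Standard screening-testing with a single-marker filter
#'
#' Stage 1 ranks all markers by the p-value of a per-marker filter model
#' (marginal association: logistic outcome on the marker; gene-environment
#' correlation: logistic (binary exposure) or least-squares (continuous
#' exposure) model of the exposure on the marker) and retains the `retain`
#' most significant. Stage 2 tests each retained marker with the single-SNP
#' interaction model; BH adjustment runs over the retained family only. The
#' filter statistic is independent of the interaction test statistic under
#' the null, which is what preserves FDR control after filtering.
#'
#' @param cohort A [cohort()].
#' @param filter `"marginal"` or `"correlation"`.
#' @param retain Number of markers carried to the test stage.
#' @return A `benchmark_result`; `filter_table` holds the stage-1 statistics.
#' @export
standard_screening_testing <- function(cohort,
                                       filter = c("marginal", "correlation"),
                                       retain) {
  stopifnot(inherits(cohort, "gxe_cohort"))
  filter <- match.arg(filter)
  p <- n_markers(cohort)
  retain <- as.integer(retain)
  if (retain < 1 || retain > p) {
    stop(sprintf("retain must be in [1, p]; got %d with p=%d", retain, p),
         call. = FALSE)
  }
  flt <- single_marker_filter(cohort, filter)
  # rank by ascending filter p-value; NA (failed) fits sink; ties keep the
  # lower marker index
  rank_p <- ifelse(is.na(flt$pvalue), Inf, flt$pvalue)
  keep <- order(rank_p, seq_len(p))[seq_len(retain)]
  keep <- sort(keep)
  scan <- interaction_scan(cohort, markers = keep)
  new_benchmark_result(paste0("st_", filter), keep, scan, filter_table = flt)
}

#' Markers declared significant by a benchmark method
#'
#' @param result A `benchmark_result`.
#' @param fdr_q FDR level.
#' @return Integer marker indices with BH q-value at or below `fdr_q`.
#' @export
significant_markers <- function(result, fdr_q = 0.1) {
  stopifnot(inherits(result, "benchmark_result"))
  result$tested_indices[!is.na(result$qvalues) & result$qvalues <= fdr_q]
}
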