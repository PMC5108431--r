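# Orchestration of the full screening-testing workflow:
# prescreen -> elastic-net screen -> joint test stage -> omnibus/Wald -> FDR.

#' Configuration for a SPUR run
#'
#' @param mode One of:
#'   * `"single_marginal"` / `"single_correlation"`: one filter, no omnibus
#'     gate; interaction Wald p-values are BH-adjusted over the q tested
#'     interactions.
#'   * `"hierarchical"`: both filters in parallel; the two omnibus LR
#'     p-values form the parent BH family and interaction Wald families are
#'     tested only under rejected parents ([hierarchical_fdr()]), with the
#'     effective child-level FDR bound reported.
#'   * `"global"`: both filters in parallel; BH over the two omnibus
#'     p-values only, and every interaction term in a test-stage model
#'     inherits its model's omnibus q-value.
#' @param q Number of markers selected by the penalized screen (per filter).
#' @param k Prescreen retention count; default `20 * q` (a warning is issued
#'   below `20 * q`).
#' @param alpha Elastic-net mixing parameter (default 0.999).
#' @param fdr_q Nominal FDR level (default 0.1).
#' @param interaction_test `"wald"` or `"lr"` per-interaction tests.
#' @return A list of class `spur_config`.
#' @export
spur_config <- function(mode = c("single_marginal", "single_correlation",
                                 "hierarchical", "global"),
                        q, k = 20 * q, alpha = 0.999, fdr_q = 0.1,
                        interaction_test = c("wald", "lr")) {
  mode <- match.arg(mode)
  interaction_test <- match.arg(interaction_test)
  q <- as.integer(q)
  k <- as.integer(k)
  if (q < 1) stop("q must be at least 1", call. = FALSE)
  if (k < q) stop("k must be at least q", call. = FALSE)
  if (k < 20 * q) {
    warning(sprintf("k=%d is below the recommended 20*q=%d", k, 20 * q),
            call. = FALSE)
  }
  if (!(fdr_q > 0 && fdr_q < 1)) stop("fdr_q must be in (0, 1)", call. = FALSE)
  structure(
    list(mode = mode, q = q, k = k, alpha = alpha, fdr_q = fdr_q,
         interaction_test = interaction_test),
    class = "spur_config"
  )
}

# One filter branch: prescreen -> penalized screen -> joint test stage.
run_filter_branch <- function(cohort, filter, config) {
  pre <- prescreen(cohort, filter, k = min(config$k, n_markers(cohort)))
  spec <- filter_spec(filter, q = config$q, alpha = config$alpha,
                      exposure_kind = cohort$exposure_kind)
  screen <- fit_screening_model(cohort, pre, spec)
  fit <- fit_test_stage(cohort, screen$selected_indices,
                        interaction_test = config$interaction_test)
  list(prescreen = pre, screen = screen, fit = fit)
}

#' Run the full SPUR workflow
#'
#' Executes score-statistic prescreening, the elastic-net penalized screening
#' model, the joint unpenalized test-stage model and FDR assessment in the
#' mode set by [spur_config()].
#'
#' @param cohort A [cohort()].
#' @param config A [spur_config()].
#' @return A list of class `spur_result`:
#'   * `branches`: per-filter list of `prescreen`, `screen` and `fit`
#'     ([fit_test_stage()]) results;
#'   * `omnibus`: data frame of per-filter omnibus LR statistics, p-values
#'     and (for two-filter modes) BH q-values;
#'   * `interactions`: decision table with `marker`, `marker_id`, `filter`,
#'     `estimate`, `pvalue`, `fdr` and `significant` at `config$fdr_q`;
#'   * `hierarchy`: the [hierarchical_fdr()] result (`hierarchical` mode);
#'   * `effective_level`: effective child-level FDR bound (`hierarchical`
#'     mode);
#'   * `config`.
#' @export
run_spur <- function(cohort, config) {
  stopifnot(inherits(cohort, "gxe_cohort"), inherits(config, "spur_config"))
  filters <- switch(config$mode,
    single_marginal = "marginal",
    single_correlation = "correlation",
    c("marginal", "correlation")
  )
  branches <- lapply(filters, run_filter_branch, cohort = cohort,
                     config = config)
  names(branches) <- filters

  omnibus <- data.frame(
    filter = filters,
    lr_stat = vapply(branches, function(b) b$fit$lr_stat, numeric(1)),
    lr_df = vapply(branches, function(b) b$fit$lr_df, numeric(1)),
    pvalue = vapply(branches, function(b) b$fit$lr_pvalue, numeric(1)),
    row.names = NULL
  )

  wald_of <- function(b) wald_tests(b$fit)
  base_tab <- do.call(rbind, lapply(filters, function(f) {
    w <- wald_of(branches[[f]])
    if (!nrow(w)) return(NULL)
    data.frame(
      marker = w$marker, marker_id = w$marker_id, filter = f,
      estimate = w$estimate, pvalue = w$pvalue, row.names = NULL
    )
  }))

  hierarchy <- NULL
  effective_level <- NA_real_

  if (config$mode %in% c("single_marginal", "single_correlation")) {
    # no omnibus gate: BH over the q tested interactions of the one filter
    base_tab$fdr <- bh_adjust(base_tab$pvalue)
    base_tab$significant <- !is.na(base_tab$fdr) & base_tab$fdr <= config$fdr_q
  } else if (config$mode == "hierarchical") {
    omnibus$qvalue <- bh_adjust(omnibus$pvalue)
    children <- lapply(filters, function(f) wald_of(branches[[f]])$pvalue)
    hierarchy <- hierarchical_fdr(omnibus$pvalue, children, q = config$fdr_q)
    effective_level <- hierarchy$effective_level
    fdr <- rep(NA_real_, nrow(base_tab))
    sig <- rep(FALSE, nrow(base_tab))
    for (i in seq_along(filters)) {
      rows <- base_tab$filter == filters[i]
      tab <- hierarchy$child_tables[[i]]
      if (!is.null(tab)) {
        fdr[rows] <- tab$qvalue
        sig[rows] <- tab$rejected
      }
    }
    base_tab$fdr <- fdr
    base_tab$significant <- sig
  } else { # global
    omnibus$qvalue <- bh_adjust(omnibus$pvalue)
    # every interaction term inherits its model's omnibus q-value
    base_tab$fdr <- omnibus$qvalue[match(base_tab$filter, omnibus$filter)]
    base_tab$significant <- !is.na(base_tab$fdr) & base_tab$fdr <= config$fdr_q
  }

  structure(
    list(
      branches = branches, omnibus = omnibus, interactions = base_tab,
      hierarchy = hierarchy, effective_level = effective_level,
      config = config
    ),
    class = "spur_result"
  )
}

#' @export
print.spur_result <- function(x, ...) {
  cat(sprintf("spur_result (%s mode, q=%d, k=%d, fdr_q=%.3g)\n",
              x$config$mode, x$config$q, x$config$k, x$config$fdr_q))
  cat("omnibus tests:\n")
  print(x$omnibus, row.names = FALSE)
  sig <- x$interactions[which(x$interactions$significant), , drop = FALSE]
  if (nrow(sig)) {
    cat("significant interactions:\n")
    print(sig, row.names = FALSE)
  } else {
    cat("no significant interactions at the nominal level\n")
  }
  if (!is.na(x$effective_level)) {
    cat(sprintf("effective child-level FDR bound: %.4g\n", x$effective_level))
  }
  invisible(x)
}

#' Markers declared significant by a SPUR run
#'
#' @param result A [run_spur()] result.
#' @return Integer marker indices flagged significant (union over filters).
#' @export
spur_significant_markers <- function(result) {
  stopifnot(inherits(result, "spur_result"))
  unique(result$interactions$marker[result$interactions$significant])
}
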