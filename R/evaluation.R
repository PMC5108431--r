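# Monte Carlo harness: type I error and power of all detection methods under
# a simulation design. Per-replicate results are kept in the returned object
# so every summary is recomputable without re-simulation.

eval_methods <- c("one_step", "st_marginal", "st_correlation",
                  "spur_marginal", "spur_correlation",
                  "spur_hierarchical", "spur_global")

# Run one method on one cohort; returns tested markers, their unadjusted
# interaction p-values, and the markers declared significant at fdr_q.
run_eval_method <- function(method, cohort, q, k, retain, fdr_q, alpha,
                            spur_configs) {
  if (method == "one_step") {
    r <- one_step(cohort)
  } else if (method %in% c("st_marginal", "st_correlation")) {
    r <- standard_screening_testing(cohort, sub("^st_", "", method), retain)
  } else {
    r <- run_spur(cohort, spur_configs[[method]])
    return(list(
      tested = r$interactions$marker,
      pvalues = r$interactions$pvalue,
      significant = spur_significant_markers(r)
    ))
  }
  list(tested = r$tested_indices, pvalues = r$pvalues,
       significant = significant_markers(r, fdr_q))
}

make_spur_configs <- function(methods, q, k, alpha, fdr_q, warn_k = FALSE) {
  modes <- c(spur_marginal = "single_marginal",
             spur_correlation = "single_correlation",
             spur_hierarchical = "hierarchical",
             spur_global = "global")
  need <- intersect(methods, names(modes))
  cfg <- lapply(need, function(m) {
    maker <- function() spur_config(modes[[m]], q = q, k = k, alpha = alpha,
                                    fdr_q = fdr_q)
    if (warn_k) maker() else suppressWarnings(maker())
  })
  stats::setNames(cfg, need)
}

new_eval_table <- function(table, detail, meta) {
  structure(list(table = table, detail = detail, meta = meta),
            class = "eval_table")
}

#' @export
print.eval_table <- function(x, ...) {
  cat(sprintf("eval_table: %s design, %d replicates\n",
              x$meta$design_name, x$meta$n_reps))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Estimate type I error rates by simulation
#'
#' Simulates `n_reps` data sets from a null design (no true interactions),
#' runs each method, and reports per method and nominal level `alpha` the
#' pooled proportion of tested null interactions with unadjusted p-value
#' below `alpha`. The denominator is the number of interaction tests actually
#' performed (all p markers for one-step; the retained/selected family for
#' two-stage methods), pooled over replicates.
#'
#' @param design A [simulation_design()] with all interaction coefficients 0.
#' @param methods Subset of `c("one_step", "st_marginal", "st_correlation",
#'   "spur_marginal", "spur_correlation")`.
#' @param n_reps Number of replicate data sets.
#' @param alphas Nominal levels.
#' @param q Markers selected by the penalized screen (and, by default,
#'   retained by standard screening-testing).
#' @param k Prescreen retention count.
#' @param retain Stage-1 retention for standard screening-testing.
#' @param alpha_enet Elastic-net mixing parameter.
#' @param seed Master seed; replicate r uses `seed + r - 1`.
#' @return An `eval_table`: `$table` has columns `method`, `alpha`,
#'   `estimate`, `se`, `n_tests`, `n_reps`; `$detail` holds the per-replicate
#'   p-value vectors.
#' @export
estimate_type1_error <- function(design, methods = c("one_step", "st_marginal",
                                                     "st_correlation",
                                                     "spur_marginal",
                                                     "spur_correlation"),
                                 n_reps = 100, alphas = c(0.05, 0.01),
                                 q = 25, k = 50, retain = q,
                                 alpha_enet = 0.999, seed = 1) {
  stopifnot(inherits(design, "gxe_design"))
  methods <- match.arg(methods, eval_methods, several.ok = TRUE)
  if (any(design$betaGE != 0)) {
    stop("type I error estimation requires a design with no true interactions",
         call. = FALSE)
  }
  cfgs <- make_spur_configs(methods, q, k, alpha_enet, fdr_q = 0.1)
  detail <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(design, seed = seed + r - 1)
    detail[[r]] <- lapply(stats::setNames(methods, methods), function(m) {
      res <- run_eval_method(m, cohort, q, k, retain, fdr_q = 0.1,
                             alpha = NULL, spur_configs = cfgs)
      res[c("tested", "pvalues")]
    })
  }
  rows <- do.call(rbind, lapply(methods, function(m) {
    pv <- unlist(lapply(detail, function(d) d[[m]]$pvalues))
    pv <- pv[!is.na(pv)]
    do.call(rbind, lapply(alphas, function(a) {
      est <- mean(pv < a)
      data.frame(method = m, alpha = a, estimate = est,
                 se = sqrt(est * (1 - est) / length(pv)),
                 n_tests = length(pv), n_reps = n_reps)
    }))
  }))
  new_eval_table(rows, detail, list(
    design_name = "type1", n_reps = n_reps, seed = seed, q = q, k = k,
    retain = retain, alphas = alphas
  ))
}

#' Estimate statistical power by simulation
#'
#' Simulates `n_reps` data sets from a design with true interactions and
#' reports, per method, the proportion of true-interaction SNPs declared
#' significant at FDR level `fdr_q` (pooled over replicates: hits divided by
#' `number of true SNPs x n_reps`). A true-interaction SNP eliminated at
#' prescreening or screening cannot be declared significant and therefore
#' counts as a non-discovery.
#'
#' @inheritParams estimate_type1_error
#' @param fdr_q FDR level at which discoveries are declared.
#' @return An `eval_table`: `$table` has columns `method`, `estimate`, `se`,
#'   `n_true`, `n_reps`; `$detail` holds per-replicate significant sets.
#' @export
estimate_power <- function(design, methods = c("one_step", "st_marginal",
                                               "st_correlation",
                                               "spur_marginal",
                                               "spur_correlation"),
                           n_reps = 100, fdr_q = 0.1,
                           q = 5, k = 100, retain = q,
                           alpha_enet = 0.999, seed = 1) {
  stopifnot(inherits(design, "gxe_design"))
  methods <- match.arg(methods, eval_methods, several.ok = TRUE)
  truth <- which(design$betaGE != 0)
  if (!length(truth)) {
    stop("power estimation requires a design with at least one true interaction",
         call. = FALSE)
  }
  cfgs <- make_spur_configs(methods, q, k, alpha_enet, fdr_q)
  detail <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(design, seed = seed + r - 1)
    detail[[r]] <- lapply(stats::setNames(methods, methods), function(m) {
      res <- run_eval_method(m, cohort, q, k, retain, fdr_q, alpha = NULL,
                             spur_configs = cfgs)
      res["significant"]
    })
  }
  rows <- do.call(rbind, lapply(methods, function(m) {
    hits <- sum(vapply(detail, function(d) {
      length(intersect(d[[m]]$significant, truth))
    }, numeric(1)))
    trials <- length(truth) * n_reps
    est <- hits / trials
    data.frame(method = m, estimate = est,
               se = sqrt(est * (1 - est) / trials),
               n_true = length(truth), n_reps = n_reps)
  }))
  new_eval_table(rows, detail, list(
    design_name = "power", n_reps = n_reps, seed = seed, q = q, k = k,
    retain = retain, fdr_q = fdr_q
  ))
}
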