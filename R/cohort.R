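#' Construct a case-control cohort
#'
#' Bundles additively coded genotypes (minor-allele counts 0/1/2), a binary
#' outcome, a binary or continuous environmental exposure and optional
#' covariates into a validated container used by every downstream stage.
#'
#' @param genotypes Numeric n x p matrix with entries in \{0, 1, 2\}.
#' @param exposure Length-n numeric vector; values in \{0, 1\} when
#'   `exposure_kind = "binary"`.
#' @param outcome Length-n vector of case (1) / control (0) indicators.
#' @param covariates Optional n x c numeric matrix (default: none).
#' @param marker_ids Character vector of p unique marker identifiers; defaults
#'   to the genotype column names or `snp0001`-style labels.
#' @param exposure_kind `"binary"` or `"continuous"`.
#'
#' @return An object of class `gxe_cohort`: a list with elements `genotypes`,
#'   `exposure`, `outcome`, `covariates`, `marker_ids`, `exposure_kind`.
#' @export
#' @examples
#' g <- matrix(rbinom(40, 2, 0.3), 10, 4)
#' cohort(g, rbinom(10, 1, 0.5), rbinom(10, 1, 0.5))
cohort <- function(genotypes, exposure, outcome, covariates = NULL,
                   marker_ids = NULL, exposure_kind = c("binary", "continuous")) {
  exposure_kind <- match.arg(exposure_kind)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  if (anyNA(genotypes) || anyNA(exposure) || anyNA(outcome)) {
    stop("cohort fields must not contain missing values", call. = FALSE)
  }
  bad <- which(!(genotypes %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% n) + 1
    j <- ((bad[1] - 1) %/% n) + 1
    stop(sprintf(
      "genotype value %g at row %d, column %d is not in {0, 1, 2}",
      genotypes[bad[1]], i, j
    ), call. = FALSE)
  }
  outcome <- as.numeric(outcome)
  if (length(outcome) != n || !all(outcome %in% c(0, 1))) {
    stop("outcome must be a length-n vector with values in {0, 1}", call. = FALSE)
  }
  exposure <- as.numeric(exposure)
  if (length(exposure) != n) {
    stop("exposure length does not match the number of subjects", call. = FALSE)
  }
  if (exposure_kind == "binary" && !all(exposure %in% c(0, 1))) {
    stop("binary exposure must take values in {0, 1}", call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per subject", call. = FALSE)
    }
    if (anyNA(covariates)) stop("covariates must not contain missing values", call. = FALSE)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
  }
  if (is.null(marker_ids)) {
    marker_ids <- colnames(genotypes)
    if (is.null(marker_ids)) {
      marker_ids <- sprintf("snp%04d", seq_len(p))
    }
  }
  marker_ids <- as.character(marker_ids)
  if (length(marker_ids) != p || anyDuplicated(marker_ids)) {
    stop("marker_ids must be unique and one per genotype column", call. = FALSE)
  }
  colnames(genotypes) <- marker_ids
  structure(
    list(
      genotypes = genotypes, exposure = exposure, outcome = outcome,
      covariates = covariates, marker_ids = marker_ids,
      exposure_kind = exposure_kind
    ),
    class = "gxe_cohort"
  )
}

#' @export
print.gxe_cohort <- function(x, ...) {
  cat(sprintf(
    "gxe_cohort: %d subjects (%d cases / %d controls), %d markers, %d covariates, %s exposure\n",
    length(x$outcome), sum(x$outcome == 1), sum(x$outcome == 0),
    ncol(x$genotypes), ncol(x$covariates), x$exposure_kind
  ))
  invisible(x)
}

#' @export
dim.gxe_cohort <- function(x) dim(x$genotypes)

n_subjects <- function(x) nrow(x$genotypes)
n_markers <- function(x) ncol(x$genotypes)

#' Subset a cohort by subjects and/or markers
#'
#' @param x A [cohort()] object.
#' @param subjects,markers Index vectors (default: keep all).
#' @return A `gxe_cohort` restricted to the requested rows/columns.
#' @export
subset_cohort <- function(x, subjects = NULL, markers = NULL) {
  stopifnot(inherits(x, "gxe_cohort"))
  if (is.null(subjects)) subjects <- seq_len(n_subjects(x))
  if (is.null(markers)) markers <- seq_len(n_markers(x))
  cohort(
    genotypes = x$genotypes[subjects, markers, drop = FALSE],
    exposure = x$exposure[subjects],
    outcome = x$outcome[subjects],
    covariates = if (ncol(x$covariates)) x$covariates[subjects, , drop = FALSE] else NULL,
    marker_ids = x$marker_ids[markers],
    exposure_kind = x$exposure_kind
  )
}
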