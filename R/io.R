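# Cohort readers/writers: plain TSV and PLINK-style additive-coded RAW text.

#' Describe how a cohort file is laid out
#'
#' @param format `"tsv"` (one table: outcome, exposure, covariates,
#'   genotypes) or `"plink_raw"` (PLINK additive-coded RAW export:
#'   `FID IID PAT MAT SEX PHENOTYPE <snp>_<allele> ...`, phenotype coded
#'   1 = control / 2 = case; exposure and covariates travel in a companion
#'   covariate file with `FID IID` key columns).
#' @param outcome_col,exposure_col Column names (TSV / companion file).
#' @param covariate_cols Character vector of covariate column names (may be
#'   empty).
#' @param exposure_kind `"auto"` (binary when all values are 0/1),
#'   `"binary"`, or `"continuous"`.
#' @return A list of class `cohort_file_spec`.
#' @export
cohort_file_spec <- function(format = c("tsv", "plink_raw"),
                             outcome_col = "outcome",
                             exposure_col = "exposure",
                             covariate_cols = character(0),
                             exposure_kind = c("auto", "binary", "continuous")) {
  format <- match.arg(format)
  exposure_kind <- match.arg(exposure_kind)
  cols <- c(outcome_col, exposure_col, covariate_cols)
  if (anyDuplicated(cols)) {
    stop("outcome, exposure and covariate column names must be disjoint",
         call. = FALSE)
  }
  structure(
    list(format = format, outcome_col = outcome_col,
         exposure_col = exposure_col, covariate_cols = covariate_cols,
         exposure_kind = exposure_kind),
    class = "cohort_file_spec"
  )
}

resolve_exposure_kind <- function(kind, exposure) {
  if (kind != "auto") return(kind)
  if (all(exposure %in% c(0, 1))) "binary" else "continuous"
}

#' Write a cohort to disk
#'
#' Output is bit-stable for a fixed cohort (no timestamps). In `plink_raw`
#' format the genotypes and outcome go to `path` and the exposure plus
#' covariates to `covar_path` (default `<path>.cov`), a PLINK-style covariate
#' table keyed by `FID IID`.
#'
#' @param cohort A [cohort()].
#' @param path Output file path.
#' @param spec A [cohort_file_spec()].
#' @param covar_path Companion covariate file path (`plink_raw` only).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, spec = cohort_file_spec(),
                         covar_path = paste0(path, ".cov")) {
  stopifnot(inherits(cohort, "gxe_cohort"), inherits(spec, "cohort_file_spec"))
  n <- n_subjects(cohort)
  if (spec$format == "tsv") {
    df <- data.frame(cohort$outcome, cohort$exposure, check.names = FALSE)
    names(df) <- c(spec$outcome_col, spec$exposure_col)
    if (ncol(cohort$covariates)) df <- cbind(df, as.data.frame(cohort$covariates))
    df <- cbind(df, as.data.frame(cohort$genotypes, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ids <- sprintf("S%04d", seq_len(n))
  raw <- data.frame(
    FID = ids, IID = ids, PAT = 0, MAT = 0, SEX = 0,
    PHENOTYPE = cohort$outcome + 1, check.names = FALSE
  )
  g <- as.data.frame(cohort$genotypes, check.names = FALSE)
  names(g) <- paste0(cohort$marker_ids, "_A")
  raw <- cbind(raw, g)
  utils::write.table(raw, path, sep = " ", quote = FALSE, row.names = FALSE)
  cov <- data.frame(FID = ids, IID = ids, cohort$exposure, check.names = FALSE)
  names(cov)[3] <- spec$exposure_col
  if (ncol(cohort$covariates)) cov <- cbind(cov, as.data.frame(cohort$covariates))
  utils::write.table(cov, covar_path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Validates genotypes (values outside \{0,1,2\} are rejected naming the
#' offending row, column and value) and the outcome coding. In `plink_raw`
#' format PHENOTYPE 1/2 is recoded to 0/1; missing phenotypes (`-9` or `0`)
#' are rejected.
#'
#' @param path Input file path.
#' @param spec A [cohort_file_spec()].
#' @param covar_path Companion covariate file (`plink_raw` only).
#' @return A `gxe_cohort`.
#' @export
read_cohort <- function(path, spec = cohort_file_spec(),
                        covar_path = paste0(path, ".cov")) {
  stopifnot(inherits(spec, "cohort_file_spec"))
  if (spec$format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    need <- c(spec$outcome_col, spec$exposure_col, spec$covariate_cols)
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(sprintf("malformed header: missing column(s) %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    gcols <- setdiff(names(df), need)
    if (anyNA(df)) {
      bad <- which(rowSums(is.na(df)) > 0)
      stop(sprintf(
        "missing values in row(s) %s; remove or impute these subjects upstream",
        paste(utils::head(bad, 5), collapse = ", ")
      ), call. = FALSE)
    }
    exposure <- df[[spec$exposure_col]]
    return(cohort(
      genotypes = as.matrix(df[gcols]),
      exposure = exposure,
      outcome = df[[spec$outcome_col]],
      covariates = if (length(spec$covariate_cols)) {
        as.matrix(df[spec$covariate_cols])
      },
      marker_ids = gcols,
      exposure_kind = resolve_exposure_kind(spec$exposure_kind, exposure)
    ))
  }
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!identical(names(raw)[seq_along(fixed)], fixed)) {
    stop("malformed PLINK RAW header: expected FID IID PAT MAT SEX PHENOTYPE ...",
         call. = FALSE)
  }
  phen <- raw$PHENOTYPE
  if (any(phen %in% c(-9, 0)) || anyNA(phen)) {
    stop("missing phenotype (-9/0/NA) in PLINK RAW file; remove these subjects",
         call. = FALSE)
  }
  if (!all(phen %in% c(1, 2))) {
    stop("PLINK RAW PHENOTYPE must be coded 1 (control) / 2 (case)", call. = FALSE)
  }
  gcols <- setdiff(names(raw), fixed)
  if (anyNA(raw[gcols])) {
    stop("missing genotype values in PLINK RAW file; remove affected SNPs upstream",
         call. = FALSE)
  }
  marker_ids <- sub("_[ACGT0-9]+$", "", gcols)
  cov <- utils::read.table(covar_path, header = TRUE, check.names = FALSE)
  need <- c("FID", "IID", spec$exposure_col, spec$covariate_cols)
  miss <- setdiff(need, names(cov))
  if (length(miss)) {
    stop(sprintf("covariate file is missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  m <- match(paste(raw$FID, raw$IID), paste(cov$FID, cov$IID))
  if (anyNA(m)) {
    stop("covariate file does not cover every FID/IID in the RAW file",
         call. = FALSE)
  }
  cov <- cov[m, , drop = FALSE]
  exposure <- cov[[spec$exposure_col]]
  cohort(
    genotypes = as.matrix(raw[gcols]),
    exposure = exposure,
    outcome = phen - 1,
    covariates = if (length(spec$covariate_cols)) {
      as.matrix(cov[spec$covariate_cols])
    },
    marker_ids = marker_ids,
    exposure_kind = resolve_exposure_kind(spec$exposure_kind, exposure)
  )
}
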