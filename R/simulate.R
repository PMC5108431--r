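#' Simulation designs for case-control G-E cohorts
#'
#' A `gxe_design` fully parameterizes one generating model: correlated
#' HWE genotypes, a binary or continuous exposure optionally correlated with
#' designated SNPs, and a logistic disease model
#' `logit P(D=1) = beta0 + betaE*E + sum(betaG*G) + sum(betaGE*G*E)`.
#'
#' Genotypes arise from a latent Gaussian copula: each SNP has a standard
#' normal latent coordinate, pairwise latent correlation `snp_snp_corr`
#' (exchangeable), thresholded at the HWE quantiles so marginal genotype
#' frequencies are exactly `((1-maf)^2, 2*maf*(1-maf), maf^2)`. The exposure
#' arises from a propensity coupled to the designated SNPs and is exactly
#' uncorrelated with all other SNPs. With the default
#' `exposure_corr_scale = "latent"` (used by the reference designs) the
#' propensity is one more copula coordinate whose cross-correlations with
#' the designated SNPs' latent coordinates equal the targets; the realized
#' genotype-scale correlations are smaller ([expected_exposure_corr()] maps
#' one scale to the other). With `"observed"` the propensity instead loads
#' on the observed standardized genotypes, with loadings projected through
#' the realized genotype correlation matrix and pre-scaled by the
#' thresholding attenuation, so the realized genotype-exposure correlations
#' land on the targets exactly. Either way, jointly unattainable targets
#' raise a parameter error.
#'
#' @param n_subjects,n_snps Cohort dimensions.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param snp_snp_corr Exchangeable latent SNP-SNP correlation in [0, 1).
#' @param exposure_kind `"binary"` or `"continuous"`.
#' @param exposure_prob Bernoulli parameter for a binary exposure.
#' @param snp_exposure_corr Named numeric vector: names are marker indices,
#'   values the target genotype-exposure correlations. Unnamed markers have
#'   correlation exactly 0.
#' @param exposure_corr_scale `"latent"` (targets apply to the latent
#'   Gaussian coordinates; default) or `"observed"` (targets apply to the
#'   realized genotype/exposure scale).
#' @param beta0,betaE Intercept and exposure log-odds coefficients.
#' @param betaG,betaGE Length-`n_snps` vectors of marginal and interaction
#'   log-odds coefficients (scalars are recycled).
#' @param seed Default RNG seed carried by the design (may be overridden at
#'   simulation time).
#'
#' @return A list of class `gxe_design`.
#' @export
simulation_design <- function(n_subjects, n_snps, maf = 0.2, snp_snp_corr = 0,
                              exposure_kind = c("binary", "continuous"),
                              exposure_prob = 0.5,
                              snp_exposure_corr = numeric(0),
                              exposure_corr_scale = c("latent", "observed"),
                              beta0 = 0, betaE = 0, betaG = 0, betaGE = 0,
                              seed = NULL) {
  exposure_kind <- match.arg(exposure_kind)
  exposure_corr_scale <- match.arg(exposure_corr_scale)
  stopifnot(n_subjects >= 1, n_snps >= 1)
  if (!(maf > 0 && maf <= 0.5)) stop("maf must be in (0, 0.5]", call. = FALSE)
  if (!(snp_snp_corr >= 0 && snp_snp_corr < 1)) {
    stop("snp_snp_corr must be in [0, 1)", call. = FALSE)
  }
  if (exposure_kind == "binary" && !(exposure_prob > 0 && exposure_prob < 1)) {
    stop("exposure_prob must be in (0, 1)", call. = FALSE)
  }
  if (length(snp_exposure_corr)) {
    idx <- as.integer(names(snp_exposure_corr))
    if (anyNA(idx) || any(idx < 1 | idx > n_snps)) {
      stop("snp_exposure_corr names must be valid marker indices", call. = FALSE)
    }
    if (any(abs(snp_exposure_corr) >= 1)) {
      stop("snp_exposure_corr values must lie in (-1, 1)", call. = FALSE)
    }
  }
  betaG <- rep_len(as.numeric(betaG), n_snps)
  betaGE <- rep_len(as.numeric(betaGE), n_snps)
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
      maf = maf, snp_snp_corr = snp_snp_corr,
      exposure_kind = exposure_kind, exposure_prob = exposure_prob,
      snp_exposure_corr = snp_exposure_corr,
      exposure_corr_scale = exposure_corr_scale,
      beta0 = beta0, betaE = betaE, betaG = betaG, betaGE = betaGE,
      seed = seed
    ),
    class = "gxe_design"
  )
}

#' @export
print.gxe_design <- function(x, ...) {
  cat(sprintf(
    paste0(
      "gxe_design: n=%d, p=%d, maf=%.3g, latent SNP-SNP corr=%.3g, %s exposure\n",
      "  nonzero betaG: %d, nonzero betaGE: %d, exposure-correlated SNPs: %d\n"
    ),
    x$n_subjects, x$n_snps, x$maf, x$snp_snp_corr, x$exposure_kind,
    sum(x$betaG != 0), sum(x$betaGE != 0), length(x$snp_exposure_corr)
  ))
  invisible(x)
}

hwe_cuts <- function(maf) {
  c(stats::qnorm((1 - maf)^2), stats::qnorm(1 - maf^2))
}

#' Simulate correlated HWE genotypes
#'
#' Draws a latent multivariate normal matrix with exchangeable correlation
#' `rho` (one-factor construction) and thresholds each coordinate at the HWE
#' quantiles, so genotype marginals follow Hardy-Weinberg probabilities for
#' the given `maf` exactly while columns share positive latent dependence.
#' The realized genotype-scale correlation is smaller than `rho` (for
#' maf 0.2 the attenuation factor is about 0.66); see
#' [expected_genotype_corr()].
#'
#' @param n,p Number of subjects and SNPs.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param rho Latent exchangeable correlation in [0, 1).
#' @param seed Optional RNG seed.
#' @param keep_latent Attach the latent Gaussian matrix as attribute
#'   `"latent"` (required downstream by [simulate_exposure()] when exposure
#'   correlation targets are set).
#' @return Integer-valued n x p matrix over \{0,1,2\}.
#' @export
simulate_genotypes <- function(n, p, maf, rho = 0, seed = NULL,
                               keep_latent = TRUE) {
  if (!(maf > 0 && maf <= 0.5)) stop("maf must be in (0, 0.5]", call. = FALSE)
  if (!(rho >= 0 && rho < 1)) stop("rho must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    u <- stats::rnorm(n)
    z <- sqrt(rho) * u + sqrt(1 - rho) * z
  }
  cuts <- hwe_cuts(maf)
  g <- (z > cuts[1]) + (z > cuts[2])
  storage.mode(g) <- "double"
  if (keep_latent) attr(g, "latent") <- z
  attr(g, "maf") <- maf
  attr(g, "rho") <- rho
  g
}

# Upper-orthant probability P(Z1 > a, Z2 > b) for bivariate standard normals
# with correlation r, by one-dimensional quadrature.
bvn_upper <- function(a, b, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(a, lower.tail = FALSE) *
                               stats::pnorm(b, lower.tail = FALSE))
  s <- sqrt(1 - r^2)
  f <- function(z) {
    stats::dnorm(z) * stats::pnorm((b - r * z) / s, lower.tail = FALSE)
  }
  stats::integrate(f, lower = a, upper = Inf, rel.tol = 1e-10)$value
}

#' Expected observed-scale correlations under the genotype copula
#'
#' `expected_genotype_corr()` gives the population correlation between two
#' genotypes whose latent coordinates have correlation `rho`;
#' `expected_exposure_corr()` gives the population correlation between a
#' genotype and the exposure when their latent coordinates have correlation
#' `r`. Both are exact up to quadrature error and serve to document (and
#' invert) the thresholding attenuation.
#'
#' @param rho,r Latent correlation.
#' @param maf Minor allele frequency.
#' @param exposure_kind,exposure_prob Exposure model (binary exposures are
#'   thresholded at the `1 - exposure_prob` normal quantile).
#' @return A correlation on the observed genotype/exposure scale.
#' @export
expected_genotype_corr <- function(rho, maf) {
  cuts <- hwe_cuts(maf)
  mu <- 2 * maf
  v <- 2 * maf * (1 - maf)
  egg <- bvn_upper(cuts[1], cuts[1], rho) + 2 * bvn_upper(cuts[1], cuts[2], rho) +
    bvn_upper(cuts[2], cuts[2], rho)
  (egg - mu^2) / v
}

#' @rdname expected_genotype_corr
#' @export
expected_exposure_corr <- function(r, maf, exposure_kind = "binary",
                                   exposure_prob = 0.5) {
  cuts <- hwe_cuts(maf)
  v_g <- 2 * maf * (1 - maf)
  if (exposure_kind == "continuous") {
    return(r * (stats::dnorm(cuts[1]) + stats::dnorm(cuts[2])) / sqrt(v_g))
  }
  tau <- stats::qnorm(1 - exposure_prob)
  egx <- bvn_upper(cuts[1], tau, r) + bvn_upper(cuts[2], tau, r)
  (egx - 2 * maf * exposure_prob) /
    sqrt(v_g * exposure_prob * (1 - exposure_prob))
}

# Invert the attenuation: latent cross-correlation achieving an observed
# genotype-exposure correlation `target`.
latent_exposure_corr <- function(target, maf, exposure_kind, exposure_prob) {
  if (target == 0) return(0)
  target <- as.numeric(target)
  rmax <- 0.999
  hi <- expected_exposure_corr(rmax, maf, exposure_kind, exposure_prob)
  if (abs(target) >= hi) {
    stop(sprintf(
      "exposure correlation target %.3g exceeds the attainable bound %.3g for these margins",
      target, hi
    ), call. = FALSE)
  }
  stats::uniroot(
    function(r) expected_exposure_corr(r, maf, exposure_kind, exposure_prob) - target,
    interval = c(-rmax, rmax), tol = 1e-9
  )$root
}

#' Simulate an exposure coupled to designated SNPs
#'
#' The exposure is generated from a unit-variance Gaussian propensity:
#' with `exposure_corr_scale = "latent"` the propensity is one additional
#' coordinate of the latent Gaussian copula (a linear combination of the SNP
#' latents plus independent noise, cross-correlations equal to the targets);
#' with `"observed"` it loads on the observed standardized genotypes with
#' loadings projected so the realized genotype-exposure correlations equal
#' the targets. Binary exposures threshold the propensity at its
#' `1 - exposure_prob` quantile; continuous exposures return it directly.
#' Non-designated SNPs have correlation exactly 0 with the propensity in
#' either case.
#'
#' @param genotypes Matrix from [simulate_genotypes()] with its `"latent"`
#'   attribute (required whenever correlation targets are set).
#' @param design A [simulation_design()].
#' @param seed Optional RNG seed.
#' @return Length-n exposure vector (0/1 or continuous).
#' @export
simulate_exposure <- function(genotypes, design, seed = NULL) {
  stopifnot(inherits(design, "gxe_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  tgt <- design$snp_exposure_corr
  if (!length(tgt) || all(tgt == 0)) {
    return(
      if (design$exposure_kind == "binary") {
        stats::rbinom(n, 1, design$exposure_prob)
      } else {
        stats::rnorm(n)
      }
    )
  }
  idx <- as.integer(names(tgt))
  if (any(idx < 1 | idx > p)) {
    stop("snp_exposure_corr names must be valid marker indices", call. = FALSE)
  }
  if (identical(design$exposure_corr_scale, "observed")) {
    return(exposure_from_observed(genotypes, design, idx, as.numeric(tgt)))
  }
  z <- attr(genotypes, "latent")
  if (is.null(z)) {
    stop(paste(
      "latent-scale exposure correlation targets require the latent copula",
      "coordinates; generate genotypes with",
      "simulate_genotypes(..., keep_latent = TRUE)"
    ), call. = FALSE)
  }
  r <- numeric(p)
  r[idx] <- as.numeric(tgt)
  # a = Sigma^{-1} r for exchangeable Sigma = (1-rho) I + rho J, closed form.
  rho <- design$snp_snp_corr
  a <- (r - rho * sum(r) / (1 + (p - 1) * rho)) / (1 - rho)
  expl <- sum(a * r)  # a' Sigma a
  if (expl >= 1) {
    stop(sprintf(
      "joint exposure correlation targets are infeasible (explained latent variance %.3f >= 1)",
      expl
    ), call. = FALSE)
  }
  w <- drop(z %*% a) + sqrt(1 - expl) * stats::rnorm(n)
  if (design$exposure_kind == "binary") {
    as.numeric(w > stats::qnorm(1 - design$exposure_prob))
  } else {
    w
  }
}

# Observed-scale exposure coupling: the exposure propensity is a linear
# combination of the *observed* standardized genotypes plus independent
# Gaussian noise, with loadings projected through the (exchangeable) realized
# genotype correlation matrix so that Cov(propensity, G*_j) equals the target
# for designated SNPs and is exactly 0 for all others. For a binary exposure
# the propensity is thresholded; the targets are pre-divided by the
# thresholding attenuation factor phi(tau)/sd(E) so the realized
# exposure-genotype correlations land on the requested values.
exposure_from_observed <- function(genotypes, design, idx, targets) {
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  maf <- design$maf
  mu <- 2 * maf
  sd_g <- sqrt(2 * maf * (1 - maf))
  if (design$exposure_kind == "binary") {
    prob <- design$exposure_prob
    tau <- stats::qnorm(1 - prob)
    kappa <- stats::dnorm(tau) / sqrt(prob * (1 - prob))
  } else {
    tau <- NA_real_
    kappa <- 1
  }
  w <- numeric(p)
  w[idx] <- targets / kappa
  if (any(abs(w) >= 1)) {
    stop(sprintf(
      "exposure correlation target %.3g exceeds the attainable bound %.3g for these margins",
      max(abs(targets)), kappa
    ), call. = FALSE)
  }
  rho_g <- if (design$snp_snp_corr > 0) {
    expected_genotype_corr(design$snp_snp_corr, maf)
  } else 0
  b <- (w - rho_g * sum(w) / (1 + (p - 1) * rho_g)) / (1 - rho_g)
  expl <- sum(b * w)  # b' R b
  if (expl >= 1) {
    stop(sprintf(
      "joint exposure correlation targets are infeasible (explained propensity variance %.3f >= 1)",
      expl
    ), call. = FALSE)
  }
  # b is dense after the projection (small compensating loadings on all SNPs)
  prop <- (drop(genotypes %*% b) - mu * sum(b)) / sd_g +
    sqrt(1 - expl) * stats::rnorm(n)
  if (design$exposure_kind == "binary") {
    # empirical-quantile threshold: the propensity is slightly skewed (finite
    # sum of discrete genotypes), so the normal quantile would miss the
    # target margin by O(1%)
    as.numeric(prop > stats::quantile(prop, 1 - design$exposure_prob,
                                      names = FALSE))
  } else {
    prop
  }
}

#' Simulate the binary outcome from the logistic disease model
#'
#' `D_i ~ Bernoulli(plogis(beta0 + betaE*E_i + sum_j betaG_j G_ij +
#' sum_j betaGE_j G_ij E_i))`.
#'
#' @inheritParams simulate_exposure
#' @param exposure Length-n exposure vector.
#' @return Length-n 0/1 outcome vector.
#' @export
simulate_outcome <- function(genotypes, exposure, design, seed = NULL) {
  stopifnot(inherits(design, "gxe_design"))
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(genotypes)
  if (length(design$betaG) != p || length(design$betaGE) != p) {
    stop("design coefficient vectors do not match the number of SNPs", call. = FALSE)
  }
  eta <- rep(design$beta0 + 0, nrow(genotypes)) + design$betaE * exposure
  nzg <- which(design$betaG != 0)
  if (length(nzg)) {
    eta <- eta + drop(genotypes[, nzg, drop = FALSE] %*% design$betaG[nzg])
  }
  nzi <- which(design$betaGE != 0)
  if (length(nzi)) {
    eta <- eta + exposure *
      drop(genotypes[, nzi, drop = FALSE] %*% design$betaGE[nzi])
  }
  stats::rbinom(length(eta), 1, stats::plogis(eta))
}

#' Simulate a full cohort from a design
#'
#' Runs genotype, exposure and outcome generation under a single seed and
#' returns a validated [cohort()].
#'
#' @param design A [simulation_design()].
#' @param seed RNG seed; defaults to `design$seed`.
#' @return A `gxe_cohort`.
#' @export
simulate_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "gxe_design"))
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genotypes(design$n_subjects, design$n_snps, design$maf,
                          design$snp_snp_corr)
  e <- simulate_exposure(g, design)
  d <- simulate_outcome(g, e, design)
  attr(g, "latent") <- NULL
  cohort(g, e, d, exposure_kind = design$exposure_kind)
}

#' Reference simulation designs for the simple simulation study
#'
#' `make_null_design()` is the type-I-error design: 1,000 subjects, 2,000
#' SNPs at MAF 0.2 under HWE, latent SNP-SNP correlation 0.1, Bernoulli(0.5)
#' exposure correlated 0.05 with SNPs 1-10, disease model coefficients
#' `(beta0, betaE, betaG_i) = (-4, log 1.5, log 1.5)` for i = 1..10 and no
#' interactions.
#'
#' `make_power_design(model)` adds true interactions `betaGE = log 3` on SNPs
#' 1-5 and exposure correlation 0.3 on five designated SNPs. Model 1 favors
#' the marginal association filter: marginal effects `log 1.5` on SNPs 1-5
#' (the interacting SNPs), exposure correlation on SNPs 6-10 only. Model 2
#' favors the gene-environment correlation filter: marginal effects `log 3`
#' on SNPs 6-10, exposure correlation on SNPs 1-5 only.
#'
#' @param model 1 or 2.
#' @return A `gxe_design`.
#' @export
make_null_design <- function() {
  betaG <- numeric(2000)
  betaG[1:10] <- log(1.5)
  simulation_design(
    n_subjects = 1000, n_snps = 2000, maf = 0.2, snp_snp_corr = 0.1,
    exposure_kind = "binary", exposure_prob = 0.5,
    snp_exposure_corr = stats::setNames(rep(0.05, 10), 1:10),
    beta0 = -4, betaE = log(1.5), betaG = betaG, betaGE = 0
  )
}

#' @rdname make_null_design
#' @export
make_power_design <- function(model) {
  if (!model %in% c(1, 2)) stop("model must be 1 or 2", call. = FALSE)
  betaG <- numeric(2000)
  betaGE <- numeric(2000)
  betaGE[1:5] <- log(3)
  if (model == 1) {
    betaG[1:5] <- log(1.5)
    corr <- stats::setNames(rep(0.3, 5), 6:10)
  } else {
    betaG[6:10] <- log(3)
    corr <- stats::setNames(rep(0.3, 5), 1:5)
  }
  simulation_design(
    n_subjects = 1000, n_snps = 2000, maf = 0.2, snp_snp_corr = 0.1,
    exposure_kind = "binary", exposure_prob = 0.5,
    snp_exposure_corr = corr,
    beta0 = -4, betaE = log(1.5), betaG = betaG, betaGE = betaGE
  )
}

#' Sample a case-control study from a subject pool
#'
#' Draws exactly `n_cases` cases and `n_controls` controls without
#' replacement from a (typically large) simulated pool, emulating
#' case-control ascertainment from a population cohort.
#'
#' @param pool A [cohort()] acting as the population.
#' @param n_cases,n_controls Required counts.
#' @param seed Optional RNG seed.
#' @return A `gxe_cohort` with the requested composition (rows shuffled).
#' @export
sample_case_control <- function(pool, n_cases, n_controls, seed = NULL) {
  stopifnot(inherits(pool, "gxe_cohort"))
  if (!is.null(seed)) set.seed(seed)
  cases <- which(pool$outcome == 1)
  controls <- which(pool$outcome == 0)
  if (length(cases) < n_cases || length(controls) < n_controls) {
    stop(sprintf(
      "pool has %d cases and %d controls; requested %d and %d (deficit: %d cases, %d controls)",
      length(cases), length(controls), n_cases, n_controls,
      max(0, n_cases - length(cases)), max(0, n_controls - length(controls))
    ), call. = FALSE)
  }
  keep <- c(sample(cases, n_cases), sample(controls, n_controls))
  subset_cohort(pool, subjects = sample(keep))
}
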