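---
title: "Detecting gene-environment interactions by screening-testing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-environment interactions by screening-testing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spurgxe)
```

## The problem

A genome-wide gene-environment (G×E) interaction scan asks, for each of p
SNPs (additively coded 0/1/2), whether the SNP modifies the effect of an
environmental exposure E on a binary outcome D, on the log-odds scale:

$$\mathrm{logit}\,P(D=1\mid G_i,E) = \beta_0 + \beta_{G_i} G_i + \beta_E E + \beta_{G_iE}\,G_i E,$$

with H0: $\beta_{G_iE}=0$. Testing all p markers one at a time ("one-step")
pays the full multiplicity price of p hypotheses and is badly underpowered
for realistic interaction effects. Screening-testing designs first *filter*
markers with a statistic that is independent of the interaction test
statistic under the null — so that FDR control is preserved within the small
family of survivors — and only then test interactions.

`spurgxe` implements a joint-model variant of this idea (SPUR):
rather than filtering with one single-marker model per SNP, a single
penalized *multiple* regression over all (prescreened) markers picks the q
markers that jointly explain the filter target, and a single unpenalized
joint logistic model then tests their interactions. The package also
implements the one-step and single-marker screening-testing benchmarks, and
a Monte Carlo harness reproducing the type-I-error and power study of the
simple simulation design.

## The four-stage workflow

1. **Score-statistic prescreening.** For filter target y (the outcome for
   the marginal-association filter, the exposure for the gene-environment
   correlation filter), each marker gets the score
   $a_j = \lvert \sum_i (y_i - \bar y)\, G_{ij} \rvert$, and the k largest
   survive. This is a simplified score filter: k is fixed in advance (at
   least 20q recommended; `spur_config()` warns below that) and no KKT
   verification or iterative doubling of k is performed. Ties at the k-th
   position keep the lower marker index, for determinism. The printed form
   of this score statistic varies between sources; we use the centered
   cross-product, the only dimensionally consistent reading, which is also
   the classical score statistic for a GLM slope.

2. **Elastic-net screening model.** One penalized multiple regression of the
   filter target on all k kept markers (logistic for D or binary E; least
   squares for continuous E), covariates unpenalized. The penalty
   $\lambda\left[\tfrac{1-\alpha}{2}\|\beta\|_2^2 + \alpha\|\beta\|_1\right]$
   uses mixing parameter $\alpha = 0.999$ by default — lasso with a whisper
   of ridge for estimation stability. $\lambda$ is *not* cross-validated; it
   is tuned so that exactly q genotype coefficients are nonzero (see
   "Numerical choices").

3. **Joint test-stage model.** The q selected markers enter one unpenalized
   logistic model with marginal and interaction terms
   ($\beta_0 + \beta_E E + \sum_i \beta_{G_i} G_i + \sum_i \beta_{G_iE} G_i E$,
   plus covariates). An omnibus likelihood-ratio test compares this model to
   the nested model without interaction terms (chi-square, df = q); Wald
   tests (or optionally per-term LR tests) assess each interaction.

4. **FDR assessment.** Three modes:
   * *single-filter*: no omnibus gate; BH over the q Wald p-values;
   * *hierarchical*: the two filters run in parallel; their omnibus
     p-values form the parent BH family and the interaction families are
     tested (BH again) only under rejected parents. Level-wise BH testing of
     such a two-level tree at nominal q controls the child-level FDR at
     approximately $q\,\delta^*(d+f)/(d+1)$ with $\delta^*\approx 1$, d the
     number of child discoveries and f the number of families; the package
     reports this effective level with every hierarchical run;
   * *global*: BH over the two omnibus p-values only; every interaction in
     a test-stage model inherits its model's omnibus q-value.

Choosing q: the 7-to-1 observation-to-predictor guideline for multiple
logistic regression gives `default_q()`, the largest q with
(exposure + covariates + 2q) ≤ n/7. The counting convention behind
published applications of this rule is not always stated — whether the
intercept or dummy expansions count — so the predictor budget is exposed
via the `reserve` argument rather than hard-coded.

## The synthetic cohort generator

`simulate_cohort()` emulates a case-control cohort with three coupled
components.

**Genotypes** come from a latent Gaussian copula: one standard normal
coordinate per SNP, exchangeable latent correlation `snp_snp_corr`
(simulated by a one-factor construction), thresholded at
$\Phi^{-1}((1-\mathrm{maf})^2)$ and $\Phi^{-1}(1-\mathrm{maf}^2)$. Marginals
therefore follow Hardy-Weinberg proportions *exactly*, at the cost that the
realized genotype-scale correlation is attenuated relative to the latent one
(`expected_genotype_corr(0.1, 0.2)` ≈ 0.0675). We interpret the reference
designs' "pairwise SNP correlation 0.1" on the latent scale and document the
attenuation rather than inverting it; genotype-scale inversion is available
by passing `uniroot(function(r) expected_genotype_corr(r, maf) - target, ...)`
output as `snp_snp_corr`, and in exploratory runs the two readings moved the
study's power estimates by less than their Monte Carlo error.

**Exposure.** A unit-variance propensity is built and, for a binary
exposure, thresholded at its `1 - exposure_prob` quantile. Two coupling
scales are supported:

* `exposure_corr_scale = "latent"` (the default, used by the reference
  designs): the propensity is one more coordinate of the latent copula with
  cross-correlations equal to the targets. The realized genotype-scale
  correlations are attenuated by the double thresholding (latent 0.3 →
  observed ≈ 0.196 at MAF 0.2, latent 0.05 → ≈ 0.033;
  `expected_exposure_corr()` computes the map by quadrature).
* `"observed"`: the propensity loads on the *observed* standardized
  genotypes, with loadings projected through the exchangeable realized
  genotype correlation matrix so the covariance with non-designated SNPs is
  exactly zero, and pre-scaled by the thresholding attenuation factor
  $\phi(\tau)/\sqrt{\pi_E(1-\pi_E)}$ so the realized genotype-exposure
  correlations land on the stated targets (checked empirically in the
  package's tests; the binary threshold uses the propensity's empirical
  quantile because the finite genotype sum is mildly skewed).

The latent scale is the study condition for the reference designs. The
choice is forced by the designs' own internal logic, not merely convention:
realizing a genotype-scale correlation of 0.3 with five near-uncorrelated
SNPs requires the exposure propensity to carry $R^2 \approx 0.76$ on those
genotypes. That much genotype-driven exposure variation feeds back through
the exposure's effect on disease, handing the exposure-correlated SNPs a
strong *induced marginal association* — which contradicts power model 1's
defining property that only the interacting SNPs are marginally
associated. A
latent-coordinate exposure with exact zero leak also cannot reach an
observed 0.3 at all (the designated latents' conditional residual variance
caps it near 0.28). Under the latent reading, the benchmark methods
reproduce the published type-I-error and power estimates within Monte Carlo
noise. Jointly unattainable targets raise a parameter error in either mode.

**Outcome.** Bernoulli draws from the logistic disease model with the
design's coefficient vectors.

The reference designs (`make_null_design()`, `make_power_design(1)`,
`make_power_design(2)`) encode the simple simulation study: n = 1000
subjects, p = 2000 SNPs at MAF 0.2, latent SNP-SNP correlation 0.1,
Bernoulli(0.5) exposure. The null design has marginal effects log 1.5 on
SNPs 1-10, exposure correlation 0.05 on SNPs 1-10, and no interactions;
both power models put interactions of log 3 on SNPs 1-5 with exposure
correlation 0.3 on five designated SNPs (model 1: marginal effects log 1.5
on the interacting SNPs 1-5 and exposure correlation on SNPs 6-10; model 2:
marginal effects log 3 on SNPs 6-10 and exposure correlation on the
interacting SNPs 1-5).

What the generator does *not* emulate: linkage-disequilibrium block
structure (correlation is exchangeable, not local), missing genotypes,
genotyping error, population stratification, covariate confounding. Tests
passing under this generator therefore say nothing about robustness to
those features of real data; they validate the statistical machinery under
the stated sampling model only.

## Numerical choices

* **λ-for-q.** Coordinate-descent paths can add several variables in one
  step, so an exact nonzero count of q may be absent from the default path.
  `select_lambda_for_q()` takes the largest λ with count ≥ q and bisects
  the bracketing interval (geometrically, since paths are log-spaced) with
  exact refits until the count equals q, the bracket collapses, or 30
  probes are spent; if q is still skipped, the selection is truncated to
  the q largest standardized coefficients (deterministic; ties keep the
  lower index). Genotype columns are standardized inside the penalized fit
  and coefficients reported on the original scale, the dominant convention
  of elastic-net software. Convergence threshold 1e-7, iteration cap 1e5.
* **Per-SNP fits.** The one-step scan and single-marker filters run
  IRLS in compiled code (4 + c parameter logistic models, tolerance 1e-8 on
  the coefficient step, 50 iterations). Fits whose normal equations are
  singular, that fail to converge, or whose estimate exceeds 15 on the
  logit scale (a practical separation marker) are flagged and report `NA`
  p-values; `NA`s are excluded from the size m of their BH family. Silent
  garbage p-values from separated fits would corrupt FDR control, which is
  why flagging is the default rather than an option.
* **Test stage.** `glm.fit` with tolerance 1e-8, 100 iterations; aliased
  columns (e.g., interaction columns duplicating marginals when E is
  constant) are dropped with a warning and excluded from the omnibus df.
  The log-likelihood of a Bernoulli model is exactly -deviance/2, so the LR
  statistic is computed from deviances and floored at 0 against roundoff.
* **Degenerate inputs.** q = 0 gives the identical-models fit (LR 0,
  p = 1); a constant prescreening target warns and scores every marker 0;
  requesting more cases than a pool holds names the deficit.
* **δ\*** in the effective-FDR bound is fixed at 1 and exposed as an
  argument.

## Evaluation harness and the desk-scale profile

`estimate_type1_error()` pools, over replicates, the unadjusted interaction
p-values of all *tested* null interactions — all p markers for one-step,
the retained family for two-stage methods — and reports the fraction below
each nominal α. The pooling denominator is the number of interactions
actually tested; the published tables do not state this convention, so it
is documented here and recomputable from the per-replicate detail the
harness retains. `estimate_power()` reports the fraction of true-interaction
SNPs declared significant at FDR q = 0.1, pooled over replicates; a true
SNP eliminated at prescreening or screening counts as a non-discovery,
since it can never be declared.

The original study used 1000 replicates per design. The package's tests and
the acceptance script use a desk profile of 100 replicates (200 for the
hierarchical-bound property), with tolerances widened accordingly
(binomial Monte Carlo error at 100 replicates is about 0.02 for the pooled
type-I estimates and about 0.03-0.05 for power estimates, which cluster by
replicate). Both study conditions follow the published setup: the null
design prescreens 2000 → 50 markers and screens to q = 25 (the published
study's own prescreen retention for this design, although its general
guideline is k ≥ 20q); the power designs prescreen 2000 → 100 and screen to
q = 5, with standard screening-testing retaining the same counts.

## Known limitations

* Only two-level hypothesis hierarchies are supported; deeper trees and
  Storey-type q-value estimation are out of scope.
* The correlation filter for continuous exposures is a least-squares
  screen; robust/sandwich or rank-based alternatives are not provided.
* No Firth penalization: near-separated test-stage fits are flagged, not
  rescued.
* The generic case-control sampler (`sample_case_control()`) supports
  user-supplied disease architectures, but no published architecture
  parameterizations ship with the package.
* PLINK binary formats (.bed/.bim/.fam), VCF and dosage formats are not
  parsed; use PLINK's additive RAW export or plain TSV.
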