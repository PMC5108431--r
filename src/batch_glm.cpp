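// Batch per-SNP logistic regression by IRLS.
//
// The one-step interaction scan and the single-marker filter models fit the
// same small logistic model thousands of times per data set (once per SNP).
// These workers share the design-matrix buffer across SNPs and only swap the
// genotype-dependent columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct IrlsResult {
  arma::vec beta;
  arma::mat cov;
  bool converged;
};

// Plain IRLS for logistic regression; returns converged = false when the
// normal equations are singular (e.g., a constant genotype column) or the
// iteration limit is reached.
IrlsResult irls_logistic(const arma::mat& X, const arma::vec& y,
                         int maxit, double tol) {
  const arma::uword d = X.n_cols;
  IrlsResult res;
  res.beta = arma::zeros(d);
  res.cov = arma::mat(d, d, arma::fill::zeros);
  res.converged = false;

  arma::vec beta = arma::zeros(d);
  double ybar = arma::mean(y);
  if (ybar <= 0.0 || ybar >= 1.0) return res;  // degenerate outcome
  beta(0) = std::log(ybar / (1.0 - ybar));     // column 0 is the intercept

  arma::vec eta, mu, w, z;
  arma::mat XtWX(d, d);
  arma::vec rhs(d), beta_new(d);

  for (int it = 0; it < maxit; ++it) {
    eta = X * beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    mu.clamp(1e-10, 1.0 - 1e-10);
    w = mu % (1.0 - mu);
    XtWX = X.t() * (X.each_col() % w);
    rhs = X.t() * (w % eta + (y - mu));
    bool ok = arma::solve(beta_new, XtWX, rhs,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) return res;
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    if (delta < tol) {
      res.converged = true;
      break;
    }
  }
  if (!res.converged) {
    res.beta = beta;
    return res;
  }
  eta = X * beta;
  mu = 1.0 / (1.0 + arma::exp(-eta));
  mu.clamp(1e-10, 1.0 - 1e-10);
  w = mu % (1.0 - mu);
  XtWX = X.t() * (X.each_col() % w);
  arma::mat cov;
  if (!arma::inv_sympd(cov, XtWX)) {
    res.converged = false;
    res.beta = beta;
    return res;
  }
  res.beta = beta;
  res.cov = cov;
  return res;
}

}  // namespace

// Per-SNP interaction model: logit P(y=1) = b0 + bG G_j + bE E + bGE G_j E
// (+ covariates). Returns the estimate and SE of bGE per SNP.
// [[Rcpp::export]]
List batch_interaction_glm_cpp(const arma::vec& y, const arma::mat& G,
                               const arma::vec& E, const arma::mat& C,
                               int maxit, double tol) {
  const arma::uword n = G.n_rows, p = G.n_cols, c = C.n_cols;
  const arma::uword d = 4 + c;
  arma::mat X(n, d);
  X.col(0).ones();
  X.col(1) = E;
  for (arma::uword k = 0; k < c; ++k) X.col(2 + k) = C.col(k);

  arma::vec est(p), se(p);
  arma::vec estG(p), seG(p);
  LogicalVector converged(p);
  est.fill(NA_REAL); se.fill(NA_REAL);
  estG.fill(NA_REAL); seG.fill(NA_REAL);

  for (arma::uword j = 0; j < p; ++j) {
    X.col(d - 2) = G.col(j);
    X.col(d - 1) = G.col(j) % E;
    IrlsResult fit = irls_logistic(X, y, maxit, tol);
    converged[j] = fit.converged;
    if (fit.converged) {
      est(j) = fit.beta(d - 1);
      se(j) = std::sqrt(fit.cov(d - 1, d - 1));
      estG(j) = fit.beta(d - 2);
      seG(j) = std::sqrt(fit.cov(d - 2, d - 2));
    }
  }
  return List::create(
    _["estimate"] = est, _["se"] = se,
    _["estimate_g"] = estG, _["se_g"] = seG,
    _["converged"] = converged);
}

// Per-SNP single-predictor model: logit P(y=1) = b0 + bG G_j (+ covariates).
// Used by the marginal-association filter (y = outcome) and by the
// gene-environment correlation filter with a binary exposure (y = exposure).
// [[Rcpp::export]]
List batch_single_glm_cpp(const arma::vec& y, const arma::mat& G,
                          const arma::mat& C, int maxit, double tol) {
  const arma::uword n = G.n_rows, p = G.n_cols, c = C.n_cols;
  const arma::uword d = 2 + c;
  arma::mat X(n, d);
  X.col(0).ones();
  for (arma::uword k = 0; k < c; ++k) X.col(1 + k) = C.col(k);

  arma::vec est(p), se(p);
  LogicalVector converged(p);
  est.fill(NA_REAL); se.fill(NA_REAL);

  for (arma::uword j = 0; j < p; ++j) {
    X.col(d - 1) = G.col(j);
    IrlsResult fit = irls_logistic(X, y, maxit, tol);
    converged[j] = fit.converged;
    if (fit.converged) {
      est(j) = fit.beta(d - 1);
      se(j) = std::sqrt(fit.cov(d - 1, d - 1));
    }
  }
  return List::create(_["estimate"] = est, _["se"] = se,
                      _["converged"] = converged);
}
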