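// Logistic-regression IRLS core. Matches stats::glm.fit's algorithm
// (working-response weighted least squares, deviance-based convergence,
// epsilon 1e-8) so the R-level wrapper can expose identical estimates,
// standard errors and log-likelihoods while the permutation scan stays
// fast enough to repeat the full threshold scan thousands of times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double softplus(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct IrlsFit {
  vec beta;
  vec eta;
  double loglik;
  bool converged;
  bool singular;
};

static IrlsFit irls_core(const mat& X, const vec& y, double tol, int maxit) {
  const uword p = X.n_cols;
  IrlsFit out;
  out.beta = zeros<vec>(p);
  out.converged = false;
  out.singular = false;
  double dev = datum::inf;
  for (int it = 0; it < maxit; ++it) {
    vec eta = X * out.beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    vec z = eta + (y - mu) / w;
    mat Xw = X.each_col() % sqrt(w);
    vec bnew;
    bool ok = solve(bnew, Xw.t() * Xw, Xw.t() * (sqrt(w) % z),
                    solve_opts::no_approx);
    if (!ok) { out.singular = true; return out; }
    vec etan = X * bnew;
    double devnew = 0.0;
    for (uword i = 0; i < y.n_elem; ++i)
      devnew += 2.0 * (softplus(etan(i)) - y(i) * etan(i));
    out.beta = bnew;
    if (std::abs(devnew - dev) / (std::abs(devnew) + 0.1) < tol) {
      out.converged = true;
      dev = devnew;
      break;
    }
    dev = devnew;
  }
  out.eta = X * out.beta;
  out.loglik = -dev / 2.0;
  return out;
}

// [[Rcpp::export(name = ".irlsLogistic")]]
Rcpp::List irls_logistic(const arma::mat& X, const arma::vec& y,
                         double tol = 1e-8, int maxit = 100) {
  IrlsFit fit = irls_core(X, y, tol, maxit);
  if (fit.singular)
    return Rcpp::List::create(Rcpp::Named("singular") = true);
  vec mu = 1.0 / (1.0 + exp(-fit.eta));
  vec w = mu % (1.0 - mu);
  mat Xw = X.each_col() % sqrt(w);
  mat info = Xw.t() * Xw;
  mat covb;
  if (!inv_sympd(covb, info))
    return Rcpp::List::create(Rcpp::Named("singular") = true);
  return Rcpp::List::create(
    Rcpp::Named("singular") = false,
    Rcpp::Named("coef") = fit.beta,
    Rcpp::Named("se") = sqrt(covb.diag()).eval(),
    Rcpp::Named("loglik") = fit.loglik,
    Rcpp::Named("converged") = fit.converged,
    Rcpp::Named("fitted") = mu);
}

// Minimum two-sided Wald p over score columns: the design is
// [intercept, score_k, covariates] with the score column replaced in
// place. Fits that fail (singular or separated) yield NA for that column.
// [[Rcpp::export(name = ".scanMinWaldP")]]
Rcpp::NumericVector scan_wald_p(arma::mat X, const arma::mat& scores,
                                const arma::vec& y, double tol = 1e-8,
                                int maxit = 100) {
  const uword K = scores.n_cols;
  Rcpp::NumericVector p(K, NA_REAL);
  for (uword k = 0; k < K; ++k) {
    X.col(1) = scores.col(k);
    IrlsFit fit = irls_core(X, y, tol, maxit);
    if (fit.singular || !fit.converged) continue;
    vec mu = 1.0 / (1.0 + exp(-fit.eta));
    if (mu.min() < 1e-8 || mu.max() > 1.0 - 1e-8) continue;  // separation
    vec w = mu % (1.0 - mu);
    mat Xw = X.each_col() % sqrt(w);
    mat covb;
    if (!inv_sympd(covb, Xw.t() * Xw)) continue;
    double z = fit.beta(1) / std::sqrt(covb(1, 1));
    p[k] = 2.0 * R::pnorm(-std::abs(z), 0.0, 1.0, 1, 0);
  }
  return p;
}
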