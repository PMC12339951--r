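// Newton solver for model steady states, used standalone and as the
// warm-started inner solver of dose-response likelihood evaluations.
// Solves the augmented system in which the EGF row and the first row of
// each conserved pool are replaced by algebraic constraints (the raw
// Jacobian is singular along conservation directions).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

Rcpp::NumericVector rhs_eval_cpp(int model_id, Rcpp::NumericVector x,
                                 Rcpp::NumericVector theta);

static arma::vec aug_f(int model_id, const arma::vec &x,
                       Rcpp::NumericVector &theta, double egf,
                       const Rcpp::List &pools, const arma::vec &totals) {
  Rcpp::NumericVector xr(x.begin(), x.end());
  Rcpp::NumericVector f0 = rhs_eval_cpp(model_id, xr, theta);
  arma::vec f(f0.begin(), f0.size());
  f(0) = x(0) - egf;
  for (int i = 0; i < pools.size(); ++i) {
    Rcpp::IntegerVector idx = pools[i]; // 1-based state indices of pool i
    double s = 0.0;
    for (int j = 0; j < idx.size(); ++j) s += x(idx[j] - 1);
    f(idx[0] - 1) = s - totals(i);
  }
  return f;
}

// [[Rcpp::export]]
Rcpp::List newton_ss_cpp(int model_id, Rcpp::NumericVector x0,
                         Rcpp::NumericVector theta, double egf,
                         Rcpp::List pools, Rcpp::NumericVector pool_totals,
                         double tol, int max_steps) {
  const int n = x0.size();
  arma::vec x(x0.begin(), n);
  arma::vec totals(pool_totals.begin(), pool_totals.size());
  bool converged = false;
  double res_norm = NA_REAL;
  for (int iter = 0; iter < max_steps; ++iter) {
    Rcpp::NumericVector xr(x.begin(), x.end());
    Rcpp::NumericVector f_raw = rhs_eval_cpp(model_id, xr, theta);
    res_norm = 0.0;
    for (int i = 0; i < n; ++i) res_norm += f_raw[i] * f_raw[i];
    res_norm = std::sqrt(res_norm);
    if (res_norm <= tol * (1.0 + arma::norm(x))) {
      converged = true;
      break;
    }
    arma::vec f = aug_f(model_id, x, theta, egf, pools, totals);
    arma::mat J(n, n);
    for (int j = 0; j < n; ++j) {
      double h = std::max(std::abs(x(j)), 1.0) *
        std::sqrt(std::numeric_limits<double>::epsilon());
      arma::vec xp = x;
      xp(j) += h;
      J.col(j) = (aug_f(model_id, xp, theta, egf, pools, totals) - f) / h;
    }
    arma::vec step;
    bool ok = arma::solve(step, J, -f, arma::solve_opts::no_approx);
    if (!ok || !step.is_finite()) break;
    x += step;
    if (!x.is_finite()) break;
  }
  return Rcpp::List::create(
    Rcpp::Named("x") = Rcpp::NumericVector(x.begin(), x.end()),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("residual") = res_norm);
}
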