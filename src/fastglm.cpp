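// Fast (generalized) linear model fitting for the backward-stepwise driver.
// The benchmark refits thousands of moderately sized models (n <= a few
// hundred, p up to n), so the IRLS loop lives in C++.
// X must include the intercept column and be of full column rank; the R
// caller drops aliased columns beforehand.

// [[Rcpp::depends(RcppArmadillo)]]
// singular X'WX is expected under complete separation and handled by the
// pseudoinverse fallback; keep the solver quiet about it
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>

using namespace arma;

static double logistic_deviance(const vec& eta, const vec& y) {
  // dev = 2 * sum(log(1 + exp(eta)) - y * eta), computed stably
  double dev = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i);
    double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    dev += lse - y(i) * e;
  }
  return 2.0 * dev;
}

// [[Rcpp::export]]
Rcpp::List glm_irls(const arma::mat& X, const arma::vec& y,
                    const bool binomial, const int maxit = 25,
                    const double tol = 1e-10, const double dev_min = 0.0,
                    const Rcpp::Nullable<Rcpp::NumericVector> start = R_NilValue) {
  const uword p = X.n_cols;

  if (!binomial) {
    vec beta;
    bool ok = solve(beta, X.t() * X, X.t() * y, solve_opts::likely_sympd);
    if (!ok) beta = pinv(X.t() * X) * (X.t() * y);
    vec resid = y - X * beta;
    double rss = dot(resid, resid);
    return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                              Rcpp::Named("deviance") = rss,
                              Rcpp::Named("converged") = true,
                              Rcpp::Named("iter") = 1);
  }

  vec beta(p, fill::zeros);
  if (start.isNotNull()) {
    Rcpp::NumericVector st(start);
    if ((uword) st.size() == p) beta = Rcpp::as<vec>(st);
  }
  vec eta = X * beta;
  double dev = logistic_deviance(eta, y);
  // a pathological warm start must not beat a cold one: fall back if worse
  // than the null deviance
  {
    vec eta0(X.n_rows, fill::zeros);
    double dev0 = logistic_deviance(eta0, y);
    if (!std::isfinite(dev) || dev > dev0) {
      beta.zeros();
      eta = eta0;
      dev = dev0;
    }
  }
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= maxit; ++iter) {
    vec mu = 1.0 / (1.0 + exp(-clamp(eta, -30.0, 30.0)));
    vec w = mu % (1.0 - mu);
    w = clamp(w, 1e-10, 0.25);
    vec z = eta + (y - mu) / w;
    mat Xw = X.each_col() % w;
    vec beta_new;
    bool ok = solve(beta_new, X.t() * Xw, X.t() * (w % z),
                    solve_opts::likely_sympd);
    if (!ok) beta_new = pinv(X.t() * Xw) * (X.t() * (w % z));

    vec eta_new = X * beta_new;
    double dev_new = logistic_deviance(eta_new, y);
    // step-halving if the deviance increased or went non-finite
    int halvings = 0;
    while ((!std::isfinite(dev_new) || dev_new > dev + 1e-8) && halvings < 25) {
      beta_new = 0.5 * (beta_new + beta);
      eta_new = X * beta_new;
      dev_new = logistic_deviance(eta_new, y);
      ++halvings;
    }
    beta = beta_new;
    eta = eta_new;
    if (std::abs(dev - dev_new) / (std::abs(dev_new) + 0.1) < tol) {
      dev = dev_new;
      converged = true;
      break;
    }
    dev = dev_new;
    // complete separation: the deviance is vanishing and further iterations
    // only inflate the coefficients
    if (dev < dev_min) break;
  }

  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("deviance") = dev,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iter") = iter);
}
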