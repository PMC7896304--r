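// Lean logistic-regression IRLS used to screen the polynomial formulation
// grid. Only the linear predictor on held-out rows is needed for AUC
// ranking, so a capped iteration count with a deviance-based stop is enough;
// the winning formulation is refit with stats::glm.fit afterwards.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::vec irls_logit(const arma::mat& X, const arma::vec& y,
                     const int maxit = 15, const double tol = 1e-6) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  double dev_old = arma::datum::inf;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    mu = arma::clamp(mu, 1e-10, 1.0 - 1e-10);
    arma::vec w = mu % (1.0 - mu);
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    arma::vec b = Xw.t() * z;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, A, b,
                          arma::solve_opts::likely_sympd +
                          arma::solve_opts::no_approx);
    if (!ok) {
      // singular system (e.g. collinear columns): ridge nudge
      A.diag() += 1e-8 * arma::trace(A) / p;
      beta_new = arma::solve(A, b);
    }
    beta = beta_new;
    arma::vec eta2 = X * beta;
    arma::vec mu2 = arma::clamp(1.0 / (1.0 + arma::exp(-eta2)),
                                1e-10, 1.0 - 1e-10);
    double dev = -2.0 * arma::accu(y % arma::log(mu2) +
                                   (1.0 - y) % arma::log(1.0 - mu2));
    if (std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) break;
    dev_old = dev;
  }
  return beta;
}
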