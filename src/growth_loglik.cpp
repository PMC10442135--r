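#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Marginal log-likelihood of the hierarchical stochastic growth model.
//
// Conditional on a subject's average rate lambda, log-size increments from
// the first visit are multivariate normal with mean (lambda - sw^2/2) * dt
// and covariance sw^2 * min(dt_j, dt_k) + sm^2 * (1 + 1[j == k]) (geometric
// Brownian motion plus multiplicative measurement error sharing the baseline
// reading). lambda is integrated out over its lognormal population
// distribution exp(mu + sqrt(2) * tau * x) by Gauss-Hermite quadrature.
//
// series: list of subjects, each list(dt =, dz =) numeric vectors (possibly
// length 0 for single-visit subjects, which contribute 0).
// [[Rcpp::export]]
double growth_loglik_cpp(List series, double mu, double tau, double sigma_w,
                         double sigma_m, NumericVector gh_x,
                         NumericVector gh_w) {
  const int K = gh_x.size();
  const double sqrt2 = std::sqrt(2.0);
  arma::vec lambda(K), logw(K);
  for (int k = 0; k < K; ++k) {
    lambda[k] = std::exp(mu + sqrt2 * tau * gh_x[k]);
    logw[k] = std::log(gh_w[k]) - 0.5 * std::log(M_PI);
  }
  const double sw2 = sigma_w * sigma_w;
  const double sm2 = sigma_m * sigma_m;
  const double neg_inf = -std::numeric_limits<double>::infinity();

  double total = 0.0;
  for (int i = 0; i < series.size(); ++i) {
    List s = series[i];
    arma::vec dt = as<arma::vec>(s["dt"]);
    arma::vec dz = as<arma::vec>(s["dz"]);
    const unsigned int n = dt.n_elem;
    if (n == 0) continue;

    arma::mat S(n, n);
    for (unsigned int a = 0; a < n; ++a) {
      for (unsigned int b = 0; b <= a; ++b) {
        double v = sw2 * std::min(dt[a], dt[b]) + sm2;
        if (a == b) v += sm2;
        S(a, b) = v;
        S(b, a) = v;
      }
    }
    arma::mat L;
    if (!arma::chol(L, S, "lower")) return neg_inf;
    double logdet = 0.0;
    for (unsigned int a = 0; a < n; ++a) logdet += std::log(L(a, a));

    arma::mat R(n, K);
    for (int k = 0; k < K; ++k) {
      R.col(k) = dz - (lambda[k] - 0.5 * sw2) * dt;
    }
    arma::mat U = arma::solve(arma::trimatl(L), R);
    arma::rowvec q = arma::sum(arma::square(U), 0);

    const double cst = -logdet - 0.5 * n * std::log(2.0 * M_PI);
    double m = neg_inf;
    arma::vec le(K);
    for (int k = 0; k < K; ++k) {
      le[k] = logw[k] - 0.5 * q[k] + cst;
      if (le[k] > m) m = le[k];
    }
    if (!std::isfinite(m)) return neg_inf;
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(le[k] - m);
    total += m + std::log(sum);
  }
  return total;
}
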