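// Compiled Gibbs chain for the spike-and-slab measurement-error regression.
// Consumes R's RNG stream (norm_rand / unif_rand / R::rgamma) in exactly the
// same order as the pure-R reference chain, so a fixed seed reproduces the
// reference draws (up to floating-point rounding of the linear algebra).
// Written with plain loops and preallocated buffers: the per-transcript
// problem is tiny (n ~ 48, p <= 4) and the sweep count large (10,000), so
// per-iteration overhead dominates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// in-place upper Cholesky of a small SPD matrix: A = R'R, R upper triangular
static inline void chol_upper(const double* A, double* R, int p) {
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) R[i + j * p] = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = A[j + j * p];
    for (int k = 0; k < j; ++k) s -= R[k + j * p] * R[k + j * p];
    double rjj = std::sqrt(s);
    R[j + j * p] = rjj;
    for (int i = j + 1; i < p; ++i) {
      double t = A[j + i * p];
      for (int k = 0; k < j; ++k) t -= R[k + j * p] * R[k + i * p];
      R[j + i * p] = t / rjj;
    }
  }
}

// [[Rcpp::export]]
List gibbs_chain_cpp(const arma::vec& y, const arma::vec& evar,
                     const arma::mat& X, const arma::vec& tau,
                     const arma::vec& cmult, double nu, double lam,
                     const arma::vec& prior_p, int n_iter, int burn_in,
                     const arma::ivec& fix_delta) {
  const int n = y.n_elem, p = X.n_cols;
  const bool fixed = fix_delta.n_elem > 0;
  const int keep = n_iter - burn_in;

  arma::mat beta_out(keep, p);
  arma::imat delta_out(keep, p);
  arma::vec s2_out(keep);

  std::vector<double> z(n), beta(p, 0.0), d(p), xb(n, 0.0);
  std::vector<double> prec(p * p), R(p * p), Xtz(p), w(p), mu_b(p), eps(p);
  std::vector<int> delta(p, 0);
  if (fixed) for (int i = 0; i < p; ++i) delta[i] = fix_delta[i];
  double s2 = 1.0;
  for (int j = 0; j < n; ++j) z[j] = y[j];

  // precompute X'X and per-observation error precisions
  std::vector<double> XtX(p * p), inv_e(n);
  for (int a = 0; a < p; ++a)
    for (int b = 0; b <= a; ++b) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += X(j, a) * X(j, b);
      XtX[b + a * p] = XtX[a + b * p] = s;
    }
  for (int j = 0; j < n; ++j) inv_e[j] = 1.0 / evar[j];

  const double shape = 0.5 * (n + p + nu);

  for (int it = 1; it <= n_iter; ++it) {
    // --- z | beta, sigma2 (diagonal, elementwise) ---
    const double inv_s2 = 1.0 / s2;
    for (int j = 0; j < n; ++j) {
      double xbj = 0.0;
      for (int i = 0; i < p; ++i) xbj += X(j, i) * beta[i];
      xb[j] = xbj;
      double l = 1.0 / (inv_e[j] + inv_s2);
      double m = l * (xbj * inv_s2 + y[j] * inv_e[j]);
      z[j] = m + std::sqrt(l) * norm_rand();
    }
    // --- beta | z, sigma2, delta ---
    for (int i = 0; i < p; ++i) {
      double sd_i = tau[i] * ((delta[i] == 1) ? cmult[i] : 1.0);
      d[i] = sd_i * sd_i;
    }
    for (int k = 0; k < p * p; ++k) prec[k] = XtX[k] * inv_s2;
    for (int i = 0; i < p; ++i) prec[i + i * p] += 1.0 / (s2 * d[i]);
    chol_upper(prec.data(), R.data(), p);
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += X(j, i) * z[j];
      Xtz[i] = s * inv_s2;
    }
    // forward solve R'w = Xtz, back solve R mu = w
    for (int i = 0; i < p; ++i) {
      double s = Xtz[i];
      for (int k = 0; k < i; ++k) s -= R[k + i * p] * w[k];
      w[i] = s / R[i + i * p];
    }
    for (int i = p - 1; i >= 0; --i) {
      double s = w[i];
      for (int k = i + 1; k < p; ++k) s -= R[i + k * p] * mu_b[k];
      mu_b[i] = s / R[i + i * p];
    }
    for (int i = 0; i < p; ++i) eps[i] = norm_rand();
    for (int i = p - 1; i >= 0; --i) {
      double s = eps[i];
      for (int k = i + 1; k < p; ++k) s -= R[i + k * p] * w[k];
      w[i] = s / R[i + i * p];          // w = R^{-1} eps
    }
    for (int i = 0; i < p; ++i) beta[i] = mu_b[i] + w[i];
    // --- sigma2 | z, beta, delta ---
    double rss = 0.0;
    for (int j = 0; j < n; ++j) {
      double xbj = 0.0;
      for (int i = 0; i < p; ++i) xbj += X(j, i) * beta[i];
      double r = z[j] - xbj;
      rss += r * r;
    }
    double bdb = 0.0;
    for (int i = 0; i < p; ++i) bdb += beta[i] * beta[i] / d[i];
    double rate = 0.5 * (nu * lam + rss + bdb);
    s2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    // --- delta | beta, sigma2 ---
    if (!fixed) {
      for (int i = 0; i < p; ++i) {
        double log_ratio = std::log(cmult[i]) -
          beta[i] * beta[i] * (1.0 - 1.0 / (cmult[i] * cmult[i])) /
          (2.0 * s2 * tau[i] * tau[i]);
        double prob = 1.0 / (1.0 + std::exp(log_ratio +
                      std::log1p(-prior_p[i]) - std::log(prior_p[i])));
        if (prob < 1e-12) prob = 1e-12;
        if (prob > 1.0 - 1e-12) prob = 1.0 - 1e-12;
        delta[i] = (unif_rand() < prob) ? 1 : 0;
      }
    }
    if (it > burn_in) {
      const int r = it - burn_in - 1;
      for (int i = 0; i < p; ++i) {
        beta_out(r, i) = beta[i];
        delta_out(r, i) = delta[i];
      }
      s2_out[r] = s2;
    }
  }
  return List::create(_["beta"] = beta_out,
                      _["delta"] = delta_out,
                      _["sigma2"] = s2_out);
}
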