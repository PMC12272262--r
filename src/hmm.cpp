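#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward pass for a gaussian K-state HMM on a 1-D series.
// Returns log-likelihood, smoothed state probabilities (gamma) and summed
// transition expectations (xi), as needed by one EM iteration.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector means,
                          NumericVector sds, NumericMatrix trans,
                          NumericVector init) {
  const int n = x.size(), K = means.size();
  NumericMatrix b(n, K);          // emission densities
  for (int t = 0; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (x[t] - means[k]) / sds[k];
      b(t, k) = std::exp(-0.5 * z * z) / (sds[k] * 2.5066282746310002);
      if (b(t, k) < 1e-300) b(t, k) = 1e-300;
    }
  NumericMatrix alpha(n, K), beta(n, K);
  NumericVector c(n);             // scaling factors
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * b(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = a * b(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double v = 0.0;
      for (int j = 0; j < K; ++j)
        v += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = v / c[t + 1];
    }
  }
  NumericMatrix gamma(n, K);
  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  NumericMatrix xi(K, K);         // summed over time
  for (int t = 0; t < n - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * trans(j, k) * b(t + 1, k) *
                    beta(t + 1, k) / c[t + 1];
  double loglik = 0.0;
  for (int t = 0; t < n; ++t) loglik += std::log(c[t]);
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Viterbi decoding (log domain); ties broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector means,
                          NumericVector sds, NumericMatrix trans,
                          NumericVector init) {
  const int n = x.size(), K = means.size();
  NumericMatrix logb(n, K);
  for (int t = 0; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (x[t] - means[k]) / sds[k];
      logb(t, k) = -0.5 * z * z - std::log(sds[k]) - 0.9189385332046727;
    }
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(init[k] > 0 ? init[k] : 1e-300) + logb(0, k);
  for (int t = 1; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      int best = 0;
      double bestv = delta(t - 1, 0) + std::log(trans(0, k) > 0 ? trans(0, k) : 1e-300);
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + std::log(trans(j, k) > 0 ? trans(j, k) : 1e-300);
        if (v > bestv) { bestv = v; best = j; }   // strict: lower index wins ties
      }
      delta(t, k) = bestv + logb(t, k);
      psi(t, k) = best;
    }
  IntegerVector path(n);
  int best = 0;
  for (int k = 1; k < K; ++k) if (delta(n - 1, k) > delta(n - 1, best)) best = k;
  path[n - 1] = best;
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < n; ++t) path[t] += 1;       // 1-based states
  return path;
}
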