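#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a discrete-time HMM with Gaussian
// (or any) emission log-densities supplied row-wise. Chains restart at each
// segment boundary: segments are independent realisations sharing (pi, A).
//
// logB: T x K emission log-densities
// A:    K x K row-stochastic transition matrix
// pi:   K initial distribution (applied at the first sample of every segment)
// seg_starts: 1-based first sample of each segment (ascending, first == 1)
//
// Each logB row is shifted by its maximum before exponentiation, so the
// scaled recursion is numerically equivalent to log-space message passing.
// [[Rcpp::export]]
List forward_backward_cpp(const NumericMatrix& logB, const NumericMatrix& A,
                          const NumericVector& pi, const IntegerVector& seg_starts) {
  const int T = logB.nrow(), K = logB.ncol(), S = seg_starts.size();
  NumericMatrix gamma(T, K), xi(K, K);
  NumericMatrix b(T, K);
  NumericVector m(T), c(T);
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > mx) mx = logB(t, k);
    m[t] = mx;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t, k) - mx);
  }

  NumericMatrix alpha(T, K), beta(T, K);

  for (int s = 0; s < S; ++s) {
    const int t0 = seg_starts[s] - 1;
    const int t1 = (s + 1 < S ? seg_starts[s + 1] - 1 : T) - 1;

    // forward
    double cs = 0.0;
    for (int k = 0; k < K; ++k) { alpha(t0, k) = pi[k] * b(t0, k); cs += alpha(t0, k); }
    if (cs <= 0.0) stop("forward pass underflow at segment start");
    for (int k = 0; k < K; ++k) alpha(t0, k) /= cs;
    c[t0] = cs;
    for (int t = t0 + 1; t <= t1; ++t) {
      cs = 0.0;
      for (int j = 0; j < K; ++j) {
        double a = 0.0;
        for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
        a *= b(t, j);
        alpha(t, j) = a;
        cs += a;
      }
      if (cs <= 0.0) stop("forward pass underflow");
      for (int j = 0; j < K; ++j) alpha(t, j) /= cs;
      c[t] = cs;
    }

    // backward
    for (int k = 0; k < K; ++k) beta(t1, k) = 1.0;
    for (int t = t1 - 1; t >= t0; --t) {
      for (int i = 0; i < K; ++i) {
        double v = 0.0;
        for (int j = 0; j < K; ++j) v += A(i, j) * b(t + 1, j) * beta(t + 1, j);
        beta(t, i) = v / c[t + 1];
      }
    }

    // posteriors and pooled two-slice statistics
    for (int t = t0; t <= t1; ++t) {
      double z = 0.0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); z += gamma(t, k); }
      for (int k = 0; k < K; ++k) gamma(t, k) /= z;
    }
    for (int t = t0; t < t1; ++t) {
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
          xi(i, j) += alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j) / c[t + 1];
    }

    for (int t = t0; t <= t1; ++t) loglik += std::log(c[t]) + m[t];
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}
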