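#include <Rcpp.h>
using namespace Rcpp;

// Sample a Markov chain path given row-wise cumulative transition
// probabilities, an initial state (1-based) and pre-drawn uniforms
// (length n - 1). Uniforms are drawn in R so the path obeys set.seed().
// [[Rcpp::export]]
IntegerVector markov_path_cpp(const NumericMatrix& cumA, int init, const NumericVector& u) {
  const int n = u.size() + 1, K = cumA.ncol();
  IntegerVector s(n);
  s[0] = init;
  for (int t = 1; t < n; ++t) {
    const int i = s[t - 1] - 1;
    const double v = u[t - 1];
    int j = 0;
    while (j < K - 1 && v > cumA(i, j)) ++j;
    s[t] = j + 1;
  }
  return s;
}
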