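// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Zero-mean Gaussian log-densities for K states.
// Rinv: list of d x d upper-triangular inverses of the Cholesky factors
// (Sigma_k = R_k' R_k, so x' Sigma^-1 x = ||x' R^-1||^2).
// Computed here rather than in R to avoid allocating T x d temporaries in
// the R heap on every EM iteration.
// [[Rcpp::export]]
arma::mat gauss_logdens_cpp(const arma::mat& X, const List& Rinv,
                            const arma::vec& logdet) {
  const arma::uword T = X.n_rows, K = Rinv.size(), d = X.n_cols;
  arma::mat out(T, K);
  const double cst = -0.5 * d * std::log(2.0 * M_PI);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat Ri = Rinv[k];
    arma::mat Z = X * Ri;
    out.col(k) = cst - 0.5 * logdet[k] - 0.5 * arma::sum(arma::square(Z), 1);
  }
  return out;
}

// Posterior-weighted scatter matrices: S_k = X' diag(g_k) X / sum(g_k).
// [[Rcpp::export]]
List weighted_scatter_cpp(const arma::mat& X, const arma::mat& g) {
  const arma::uword K = g.n_cols;
  List out(K);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat Xw = X.each_col() % g.col(k);
    arma::mat S = X.t() * Xw / arma::accu(g.col(k));
    out[k] = arma::symmatu((S + S.t()) / 2.0);
  }
  return out;
}
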