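#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Matrix of component-wise Gaussian log-densities: one row per observation,
// one column per mixture component. Computed through the Cholesky factor of
// each covariance so that log-scale evaluation stays stable for large R.
// [[Rcpp::export(name = ".mvn_logdens_all")]]
arma::mat mvn_logdens_all(const arma::mat& Y, const arma::mat& means,
                          const arma::cube& sigmas) {
  const uword N = Y.n_rows, R = Y.n_cols, C = means.n_cols;
  mat out(N, C);
  const double c0 = -0.5 * (double)R * std::log(2.0 * M_PI);
  for (uword c = 0; c < C; ++c) {
    mat L;
    if (!chol(L, sigmas.slice(c), "lower"))
      Rcpp::stop("covariance matrix of component %d is singular or not positive definite",
                 (int)(c + 1));
    mat Yc = Y.each_row() - means.col(c).t();
    // z = L^{-1} (y - mu); Mahalanobis distance = ||z||^2
    mat Z = solve(trimatl(L), Yc.t());
    rowvec q = sum(square(Z), 0);
    double ldet = accu(log(L.diag()));
    out.col(c) = (c0 - ldet - 0.5 * q).t();
  }
  return out;
}

// Weighted scatter about a given centre: sum_i w_i (y_i - m)(y_i - m)'.
// Weights must be non-negative (posterior responsibilities).
// [[Rcpp::export(name = ".weighted_scatter")]]
arma::mat weighted_scatter(const arma::mat& Y, const arma::vec& w,
                           const arma::rowvec& center) {
  mat Yc = Y.each_row() - center;
  Yc.each_col() %= sqrt(w);
  return Yc.t() * Yc;
}

// Row-wise log-sum-exp of a matrix (used to normalise posteriors and to
// accumulate the observed-data mixture log-likelihood).
// [[Rcpp::export(name = ".row_logsumexp")]]
arma::vec row_logsumexp(const arma::mat& A) {
  vec m = max(A, 1);
  vec out = m + log(sum(exp(A.each_col() - m), 1));
  return out;
}
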