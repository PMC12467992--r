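#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Euler-Maruyama discretization of dX = A X dt + diag(noise_sd) dW.
// Uses R's RNG so set.seed() on the R side controls the path exactly.
// [[Rcpp::export]]
arma::mat ou_simulate_cpp(const arma::mat& A, const arma::vec& noise_sd,
                          double dt, int n, int burn_in) {
  const int d = A.n_rows;
  arma::vec x(d, arma::fill::zeros);
  arma::mat out(d, n);
  const double sq = std::sqrt(dt);
  arma::vec eps(d);
  for (int t = 0; t < burn_in + n; ++t) {
    for (int k = 0; k < d; ++k) eps[k] = R::norm_rand();
    x += dt * (A * x) + sq * (noise_sd % eps);
    if (t >= burn_in) out.col(t - burn_in) = x;
  }
  return out;
}
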