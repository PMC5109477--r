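#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Euler-Maruyama integration of dX = -A X dt + B dW, run independently for
// each of the 3 spatial components (isotropic site coupling).  Gaussian
// increments come from R's RNG, so set.seed() in R makes the output
// reproducible.  Burn-in steps are integrated but not stored.
//
// Returns an n_steps x n_sites x 3 array (frame-major, matching the deltas
// layout of a FluctuationSeries).
// [[Rcpp::export]]
NumericVector ou_simulate_cpp(const arma::mat& A, const arma::mat& B,
                              double dt, int n_steps, int n_burn) {
  const int n = A.n_rows;
  const double sdt = std::sqrt(dt);
  NumericVector out(Dimension(n_steps, n, 3));
  const arma::mat Adt = A * dt;
  for (int comp = 0; comp < 3; ++comp) {
    arma::vec x(n, arma::fill::zeros);
    arma::vec z(n);
    for (int step = 0; step < n_burn + n_steps; ++step) {
      for (int k = 0; k < n; ++k) z[k] = ::norm_rand();
      x += -Adt * x + sdt * (B * z);
      if (step >= n_burn) {
        const R_xlen_t t = step - n_burn;
        for (int k = 0; k < n; ++k)
          out[t + (R_xlen_t)n_steps * (k + (R_xlen_t)n * comp)] = x[k];
      }
    }
  }
  return out;
}
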