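// Fast non-negative least squares (Bro & de Jong 1997 variant of
// Lawson-Hanson) operating on the normal equations. Used by the Monte
// Carlo inversion's weight solves, where the same design matrix shape is
// solved thousands of times per voxel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min ||A x - b||_2 s.t. x >= 0 given AtA = A'A and Atb = A'b.
// [[Rcpp::export]]
Rcpp::NumericVector fnnls_cpp(const arma::mat& AtA, const arma::vec& Atb,
                              double tol = -1.0, int max_iter = -1) {
  const uword n = AtA.n_cols;
  if (max_iter < 0) max_iter = 10 * static_cast<int>(n);
  if (tol < 0) tol = 10 * datum::eps * norm(AtA, 1) * n;

  vec x = zeros<vec>(n);
  uvec passive = zeros<uvec>(n);  // active-set flags
  vec w = Atb;                    // negative gradient

  int outer = 0;
  while (outer++ < max_iter) {
    // most violating variable among the zero-constrained set
    double wmax = -datum::inf;
    sword t = -1;
    for (uword j = 0; j < n; ++j) {
      if (!passive(j) && w(j) > wmax) { wmax = w(j); t = j; }
    }
    if (t < 0 || wmax <= tol) break;
    passive(t) = 1;

    // inner loop: solve on the passive set, clip negatives
    for (int inner = 0; inner < max_iter; ++inner) {
      uvec p = find(passive == 1);
      vec s_p;
      bool ok = solve(s_p, AtA.submat(p, p), Atb.elem(p),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) s_p = pinv(AtA.submat(p, p)) * Atb.elem(p);

      if (s_p.min() > 0) {
        x.zeros();
        x.elem(p) = s_p;
        break;
      }
      // step toward s along the feasible segment
      double alpha = datum::inf;
      for (uword k = 0; k < p.n_elem; ++k) {
        if (s_p(k) <= 0) {
          double a = x(p(k)) / (x(p(k)) - s_p(k));
          if (a < alpha) alpha = a;
        }
      }
      vec xp = x.elem(p);
      xp += alpha * (s_p - xp);
      x.zeros();
      x.elem(p) = xp;
      for (uword k = 0; k < p.n_elem; ++k) {
        if (x(p(k)) <= tol) { passive(p(k)) = 0; x(p(k)) = 0; }
      }
    }
    w = Atb - AtA * x;
  }
  return Rcpp::wrap(x);
}
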