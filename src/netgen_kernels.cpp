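// One-pass kernels for instance generation and the Fisher score transform.
// The naive R versions allocate several N x N temporaries (upper-triangle
// masks, transposed copies, pmax results), which dominates the runtime at
// N = 5000; these kernels do each job in a single pass. Noise is drawn
// through R's RNG so instances remain bit-reproducible per seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// J = max(0, W - tau + zeta), zeta symmetric N(0, nu^2) drawn on the upper
// triangle (column-major order) and mirrored; diagonal zeroed.
// [[Rcpp::export(name = ".rectify_noisy_cpp")]]
arma::mat rectify_noisy_cpp(const arma::mat &W, const double tau,
                            const double nu) {
  const uword N = W.n_rows;
  mat J(N, N);
  Rcpp::RNGScope scope;
  for (uword j = 1; j < N; ++j) {
    for (uword i = 0; i < j; ++i) {
      const double z = R::rnorm(0.0, nu);
      const double v = W(i, j) - tau + z;
      const double r = v > 0.0 ? v : 0.0;
      J(i, j) = r;
      J(j, i) = r;
    }
  }
  J.diag().zeros();
  return J;
}

// S_ij = (J_ij + tau)/nu^2 where J_ij > 0, s0 where J_ij = 0; diagonal 0.
// Validates non-negativity and symmetry (elementwise transform is a single
// sequential pass; the symmetry check is one transposed comparison).
// [[Rcpp::export(name = ".fisher_score_cpp")]]
arma::mat fisher_score_cpp(const arma::mat &J, const double tau,
                           const double nu, const double s0) {
  const uword N = J.n_rows;
  const double inv_nu2 = 1.0 / (nu * nu);
  if (J.min() < 0.0) Rcpp::stop("'J' must be non-negative");
  // blocked symmetry check: tile pairs fit in cache, avoiding the strided
  // full-matrix transpose
  const uword bsz = 64;
  for (uword jb = 0; jb < N; jb += bsz) {
    const uword je = std::min(jb + bsz, N);
    for (uword ib = 0; ib <= jb; ib += bsz) {
      const uword ie = std::min(ib + bsz, N);
      for (uword j = jb; j < je; ++j)
        for (uword i = ib; i < std::min(ie, j); ++i)
          if (J(i, j) != J(j, i)) Rcpp::stop("'J' must be symmetric");
    }
  }
  mat S(N, N);
  const double *jp = J.memptr();
  double *sp = S.memptr();
  const uword n2 = N * N;
  for (uword k = 0; k < n2; ++k) {
    const double v = jp[k];
    sp[k] = v > 0.0 ? (v + tau) * inv_nu2 : s0;
  }
  S.diag().zeros();
  return S;
}
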