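// Mean-field message-passing iteration for the pattern-reconstruction
// problem. The R driver run_amp() prepares the score matrix, the
// initialisation and the options; this kernel runs the iteration loop.
// The slot-sequential sweep with the cross-pattern field correction is
// O(N^2 P) per iteration and dominates the cost, which is why it lives in
// compiled code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Scalar posterior mean/variance of one pattern component under the tilted
// prior p(x) exp(b x - a x^2 / 2). Families: 0 binary, 1 sparse,
// 2 low-coding. Mirrors tilt_mean_var() in R/priors.R (kept in step by the
// test suite).
static inline void tilt_scalar(const int fam, const double rho,
                               const double a, const double b,
                               double &mean, double &var) {
  if (fam == 0) {                       // x in {-1, +1}, p = 1/2
    const double t = std::tanh(b);
    mean = t;
    var = 1.0 - t * t;
  } else if (fam == 1) {                // x in {-1, 0, +1}
    const double lm = std::log(rho / 2) - b - 0.5 * a;
    const double l0 = std::log(1.0 - rho);
    const double lp = std::log(rho / 2) + b - 0.5 * a;
    const double mx = std::max(l0, std::max(lm, lp));
    const double wm = std::exp(lm - mx), w0 = std::exp(l0 - mx),
                 wp = std::exp(lp - mx);
    const double Z = wm + w0 + wp;
    mean = (wp - wm) / Z;
    const double m2 = (wp + wm) / Z;
    var = std::max(m2 - mean * mean, 0.0);
  } else {                              // x in {1 - rho, -rho}
    const double xa = 1.0 - rho, xi = -rho;
    const double la = std::log(rho) + b * xa - 0.5 * a * xa * xa;
    const double li = std::log(1.0 - rho) + b * xi - 0.5 * a * xi * xi;
    const double mx = std::max(la, li);
    const double wa = std::exp(la - mx), wi = std::exp(li - mx);
    const double Z = wa + wi;
    mean = (wa * xa + wi * xi) / Z;
    const double m2 = (wa * xa * xa + wi * xi * xi) / Z;
    var = std::max(m2 - mean * mean, 0.0);
  }
}

// [[Rcpp::export(name = ".amp_meanfield_cpp")]]
Rcpp::List amp_meanfield_cpp(const arma::mat &S, const arma::mat &S2,
                             arma::mat Xhat, const int fam, const double rho,
                             const int max_iter, const double tol,
                             const double damping, const bool onsager,
                             const int n_sweep, const int block_size) {
  const uword N = S.n_rows, P = Xhat.n_cols;
  const double sqN = std::sqrt(static_cast<double>(N));
  mat Xprev(N, P, fill::zeros), Sigma(N, P, fill::zeros);
  bool converged = false;
  int iterations = 0;
  mat G, H;

  for (int it = 1; it <= max_iter; ++it) {
    mat B = (S * Xhat) / sqN;
    if (onsager) B -= ((S2 * Sigma) / double(N)) % Xprev;
    mat a = (S2 * square(Xhat)) / double(N);

    mat Xin = Xhat, Vin = Sigma;
    if (P > 1) {
      // cross-pattern field correction, sequential over blocks of slots:
      // c_ij = (1/N) sum_m S2(m,i) G(m,i) Xhat(m,j), G_mi = xhat_m . xin_i.
      // Within a block the correction uses the means frozen at the start
      // of the block; G is refreshed between blocks, so later blocks see
      // the freshest values (pure slot-sequential when block_size = 1).
      const uword bs = std::max(1, block_size);
      G = Xhat * Xin.t();
      for (int sw = 0; sw < n_sweep; ++sw) {
        for (uword j0 = 0; j0 < P; j0 += bs) {
          const uword j1 = std::min(j0 + bs, P) - 1;
          H = S2 % G;
          mat C = H.t() * Xhat.cols(j0, j1) / double(N);
          mat dX(N, j1 - j0 + 1);
          for (uword j = j0; j <= j1; ++j) {
            for (uword i = 0; i < N; ++i) {
              const double cross =
                  C(i, j - j0) - a(i, j) * Xin(i, j);
              double mean, var;
              tilt_scalar(fam, rho, a(i, j), B(i, j) - cross, mean, var);
              dX(i, j - j0) = mean - Xin(i, j);
              Xin(i, j) = mean;
              Vin(i, j) = var;
            }
          }
          if (j1 + 1 < P || sw + 1 < n_sweep)
            G += Xhat.cols(j0, j1) * dX.t();
        }
      }
    } else {
      for (uword i = 0; i < N; ++i) {
        double mean, var;
        tilt_scalar(fam, rho, a(i, 0), B(i, 0), mean, var);
        Xin(i, 0) = mean;
        Vin(i, 0) = var;
      }
    }

    if (damping > 0) {
      Xin = (1.0 - damping) * Xin + damping * Xhat;
      Vin = (1.0 - damping) * Vin + damping * Sigma;
    }
    const double upd = accu(square(Xin - Xhat)) / double(N);
    Xprev = Xhat;
    Xhat = Xin;
    Sigma = Vin;
    iterations = it;
    if (!Xhat.is_finite())
      Rcpp::stop("message-passing iteration diverged (non-finite estimates); "
                 "consider damping (amp_options(damping = 0.5))");
    if (upd < tol) {
      converged = true;
      break;
    }
  }

  return Rcpp::List::create(Rcpp::Named("estimate") = Xhat,
                            Rcpp::Named("covariances") = Sigma,
                            Rcpp::Named("iterations") = iterations,
                            Rcpp::Named("converged") = converged);
}
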