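#' Pattern prior specification
#'
#' Defines the distribution of the entries of the stored patterns. Three
#' families are supported, all with zero mean per component:
#' \describe{
#'   \item{\code{binary}}{Hopfield patterns, entries \eqn{\pm 1} with equal
#'     probability. \code{rho} is fixed to 1.}
#'   \item{\code{sparse}}{sparse Hopfield patterns on \eqn{\{-1, 0, +1\}}: a
#'     component is non-zero with probability \code{rho}, and then \eqn{\pm 1}
#'     with equal probability.}
#'   \item{\code{low_coding}}{low-coding-level (Tsodyks-type) patterns on
#'     \eqn{\{-\rho, 1-\rho\}}: a neuron is active (value \eqn{1-\rho}) with
#'     probability \code{rho}, inactive (value \eqn{-\rho}) otherwise. The
#'     values are activities with the mean activity subtracted, so the prior
#'     has zero mean but is skewed for \eqn{\rho \ne 1/2}.}
#' }
#'
#' @param family one of \code{"binary"}, \code{"sparse"}, \code{"low_coding"}.
#' @param rho coding level / sparsity in (0, 1); ignored for \code{binary}.
#' @return an object of class \code{prior_spec} with fields \code{family} and
#'   \code{rho}.
#' @examples
#' prior_spec("sparse", rho = 0.3)
#' @export
prior_spec <- function(family = c("binary", "sparse", "low_coding"),
                       rho = NULL) {
  family <- match.arg(family)
  if (family == "binary") {
    if (!is.null(rho) && !isTRUE(all.equal(rho, 1)))
      warning("'rho' is ignored for the binary prior (fixed to 1)")
    rho <- 1
  } else {
    if (is.null(rho))
      stop("'rho' is required for the ", family, " prior")
    rho_max <- if (family == "sparse") 1 else 1 - 1e-12  # sparse(1) == binary
    if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
        rho <= 0 || rho > rho_max)
      stop("'rho' must be a single number in (0, 1)",
           if (family == "sparse") "]" else ")")
  }
  structure(list(family = family, rho = rho), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> family =", x$family)
  if (x$family != "binary") cat(", rho =", format(x$rho))
  cat("\n")
  invisible(x)
}

#' @export
format.prior_spec <- function(x, ...) {
  if (x$family == "binary") "binary" else
    sprintf("%s(rho = %g)", x$family, x$rho)
}

# Support values and prior probabilities of the per-component distribution.
prior_table <- function(spec) {
  rho <- spec$rho
  switch(spec$family,
    binary     = list(x = c(-1, 1),    p = c(0.5, 0.5)),
    sparse     = list(x = c(-1, 0, 1), p = c(rho / 2, 1 - rho, rho / 2)),
    low_coding = list(x = c(-rho, 1 - rho), p = c(1 - rho, rho))
  )
}

#' Closed-form moments of the per-component prior
#'
#' @param spec a \code{\link{prior_spec}}.
#' @return named numeric vector with the first three moments \code{m1},
#'   \code{m2}, \code{m3} of a single pattern component. \code{m1} is 0 for
#'   every family; \code{m2} is 1 (binary), \eqn{\rho} (sparse) or
#'   \eqn{\rho(1-\rho)} (low_coding).
#' @examples
#' prior_moments(prior_spec("low_coding", 0.3))
#' @export
prior_moments <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  tb <- prior_table(spec)
  c(m1 = sum(tb$p * tb$x),
    m2 = sum(tb$p * tb$x^2),
    m3 = sum(tb$p * tb$x^3))
}

#' Sample a matrix of i.i.d. patterns
#'
#' Draws a P x N matrix of pattern entries i.i.d. from the prior. Rows are
#' patterns, columns are neurons; column i is the "tuning curve" of neuron i
#' across the stored patterns.
#'
#' @param spec a \code{\link{prior_spec}}.
#' @param P number of patterns (rows), >= 1.
#' @param N number of neurons (columns), >= 1.
#' @param seed integer seed; sampling is reproducible for a fixed seed.
#' @return a P x N numeric matrix with attribute \code{prior} set to
#'   \code{spec}.
#' @export
sample_patterns <- function(spec, P, N, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), P >= 1, N >= 1)
  if (!is.null(seed)) set.seed(seed)
  tb <- prior_table(spec)
  X <- matrix(sample(tb$x, P * N, replace = TRUE, prob = tb$p), nrow = P)
  attr(X, "prior") <- spec
  X
}

# Enumerate all support^P column vectors of the prior, with log prior weights.
# Returns list(X: P x K matrix of support vectors, logp: length-K vector).
enumerate_support <- function(spec, P) {
  tb <- prior_table(spec)
  k <- length(tb$x)
  cap <- if (spec$family == "sparse") 12L else 20L
  if (P > cap)
    stop("exact enumeration supports P <= ", cap, " for the ", spec$family,
         " prior (", k, "^P terms); use posterior_mean_var_mf() instead")
  grid <- do.call(expand.grid, rep(list(seq_len(k)), P))
  idx <- as.matrix(grid)
  X <- matrix(tb$x[idx], nrow = nrow(idx))        # K x P
  logp <- rowSums(matrix(log(tb$p)[idx], nrow = nrow(idx)))
  list(X = t(X), logp = logp)
}

#' Exact posterior mean and covariance under a Gaussian-tilted prior
#'
#' Evaluates the threshold function of the message-passing algorithm: the
#' mean and covariance of a length-P pattern column x under the tilted
#' distribution proportional to \eqn{p_X(x) \exp(b^T x - x^T A x / 2)},
#' by exact enumeration of the prior support (\eqn{|X|^P} terms, computed in
#' log space). The covariance equals the derivative of the mean with respect
#' to b.
#'
#' @param spec a \code{\link{prior_spec}}.
#' @param A symmetric P x P matrix (scalar allowed for P = 1).
#' @param b numeric P-vector.
#' @return list with \code{mean} (P-vector) and \code{cov} (P x P matrix).
#' @seealso \code{\link{posterior_mean_var_mf}} for the factorised
#'   (mean-field) approximation used at large P.
#' @examples
#' posterior_mean_cov(prior_spec("binary"), A = 0.7, b = 0.3)$mean # tanh(0.3)
#' @export
posterior_mean_cov <- function(spec, A, b) {
  stopifnot(inherits(spec, "prior_spec"))
  b <- as.numeric(b)
  P <- length(b)
  A <- as.matrix(A)
  if (!all(dim(A) == P)) stop("'A' must be P x P with P = length(b)")
  if (max(abs(A - t(A))) > 1e-8 * (1 + max(abs(A))))
    stop("'A' must be symmetric")
  en <- enumerate_support(spec, P)          # X: P x K
  X <- en$X
  quad <- colSums(X * (A %*% X))            # x^T A x per support vector
  logw <- en$logp + colSums(b * X) - 0.5 * quad
  logw <- logw - max(logw)                  # log-sum-exp stabilisation
  w <- exp(logw)
  w <- w / sum(w)
  mean <- as.numeric(X %*% w)
  Exx <- X %*% (w * t(X))
  cov <- Exx - tcrossprod(mean)
  list(mean = mean, cov = (cov + t(cov)) / 2)
}

# Scalar tilted posterior mean and variance for one component:
# weights prop. to p(x) * exp(b*x - a*x^2/2), vectorised over (a, b).
# This is the P = 1 exact threshold function; the mean-field threshold
# applies it componentwise, and state evolution integrates it over z.
tilt_mean_var <- function(spec, a, b) {
  tb <- prior_table(spec)
  k <- length(tb$x)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  # log-weights: n x k
  lw <- outer(b, tb$x) - 0.5 * outer(a, tb$x^2) +
    rep(log(tb$p), each = n)
  mx <- lw[cbind(seq_len(n), max.col(lw))]
  w <- exp(lw - mx)
  Z <- rowSums(w)
  m1 <- as.vector(w %*% tb$x) / Z
  m2 <- as.vector(w %*% tb$x^2) / Z
  list(mean = m1, var = pmax(m2 - m1^2, 0))
}

#' Mean-field (factorised) posterior mean and variance
#'
#' Factorised approximation of the tilted posterior: the P x P curvature
#' matrix A is replaced by its diagonal \code{a}, so the posterior factorises
#' over components and each component reduces to a two- or three-point
#' distribution with closed-form mean and variance. Exact for P = 1; for
#' P > 1 it discards the off-diagonal curvature, which is what makes
#' message passing with many patterns tractable.
#'
#' @param spec a \code{\link{prior_spec}}.
#' @param a numeric P-vector of curvatures (diagonal of A).
#' @param b numeric P-vector of fields.
#' @return list with \code{mean} and \code{var}, both P-vectors; \code{var}
#'   is the derivative of \code{mean} with respect to \code{b}.
#' @export
posterior_mean_var_mf <- function(spec, a, b) {
  stopifnot(inherits(spec, "prior_spec"))
  n <- max(length(a), length(b))
  tilt_mean_var(spec, rep_len(as.numeric(a), n), rep_len(as.numeric(b), n))
}

#' Skewness criterion for a first-order transition (hard phase)
#'
#' A zero-mean prior admits a first-order transition in the state evolution
#' -- and hence a hard phase where recovery is possible but message passing
#' fails from an uninformed start -- when it is sufficiently skewed:
#' \eqn{\langle x^3\rangle^2 > 2 \langle x^2\rangle^3}. Symmetric priors
#' (binary, sparse) have \eqn{\langle x^3\rangle = 0} and never satisfy it
#' (the criterion is sufficient, not necessary). For the low-coding prior
#' the criterion reduces to \eqn{6\rho^2 - 6\rho + 1 > 0}, i.e. it holds for
#' coding levels below \eqn{\rho_c = 1/2 - 1/\sqrt{12} \approx 0.2113}
#' (restricting to \eqn{\rho < 1/2}).
#'
#' @param spec a \code{\link{prior_spec}}.
#' @return list with \code{skewed} (logical: criterion satisfied at this
#'   spec's rho) and \code{rho_critical} (for \code{low_coding}, the coding
#'   level in (0, 1/2) at which the criterion becomes an equality, found by
#'   root-finding on the exact moments; \code{NA} otherwise).
#' @export
hard_phase_criterion <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  crit <- function(s) {
    mm <- prior_moments(s)
    mm[["m3"]]^2 - 2 * mm[["m2"]]^3
  }
  skewed <- crit(spec) > 0
  rho_c <- NA_real_
  if (spec$family == "low_coding") {
    f <- function(r) crit(prior_spec("low_coding", r))
    rho_c <- stats::uniroot(f, c(1e-9, 0.5 - 1e-9), tol = 1e-14)$root
  }
  list(skewed = unname(skewed), rho_critical = rho_c)
}
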