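#' Rectified-Gaussian output channel specification
#'
#' The connectivity matrix is modelled as \eqn{J_{ij} = \max(0, W_{ij} - \tau
#' + \zeta_{ij})}: the Hebbian signal \eqn{W_{ij}}, minus a threshold
#' \eqn{\tau}, plus symmetric Gaussian noise of standard deviation \eqn{\nu},
#' rectified to give non-negative (excitatory) weights. Observed weights are
#' therefore a mixture of a point mass at zero (absent synapse) and a
#' truncated Gaussian on \eqn{J > 0}.
#'
#' @param tau rectification threshold, >= 0 (dimensionless).
#' @param nu noise standard deviation, > 0 (dimensionless).
#' @return an object of class \code{channel_spec}.
#' @examples
#' ch <- channel_spec(tau = 0.5, nu = 1)
#' p_connect(ch)
#' @export
channel_spec <- function(tau, nu) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("'tau' must be a single finite number >= 0")
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop("'nu' must be a single finite number > 0")
  structure(list(tau = tau, nu = nu), class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> tau = %g, nu = %g  (p_connect = %.4g, Delta = %.4g)\n",
              x$tau, x$nu, p_connect(x), effective_noise(x)))
  invisible(x)
}

#' Connection probability of the channel
#'
#' Probability that an observed weight is strictly positive when the Hebbian
#' signal is negligible (the leading order in large N):
#' \eqn{p_C = \frac{1}{2}\mathrm{erfc}(\tau / \sqrt{2}\nu)}.
#'
#' @param ch a \code{\link{channel_spec}}.
#' @return probability in (0, 1/2] for tau >= 0.
#' @export
p_connect <- function(ch) {
  stopifnot(inherits(ch, "channel_spec"))
  stats::pnorm(ch$tau / ch$nu, lower.tail = FALSE)
}

#' Log-density of the output channel
#'
#' Mixed conditional law of an observed weight J given the pre-activation
#' signal w: a point mass at J = 0 with probability
#' \eqn{\Phi((\tau - w)/\nu)} and a Gaussian density with mean \eqn{w - \tau}
#' and sd \eqn{\nu} on J > 0. The atom plus the integral of the density is 1.
#'
#' @param J observed weight(s), >= 0 (vectorised).
#' @param w pre-activation signal(s) (vectorised).
#' @param ch a \code{\link{channel_spec}}.
#' @return log-probability at J = 0, log-density at J > 0.
#' @export
log_output_density <- function(J, w, ch) {
  stopifnot(inherits(ch, "channel_spec"))
  if (any(J < 0)) stop("'J' must be non-negative")
  n <- max(length(J), length(w))
  J <- rep_len(J, n); w <- rep_len(w, n)
  out <- numeric(n)
  zero <- J == 0
  out[zero] <- stats::pnorm((ch$tau - w[zero]) / ch$nu, log.p = TRUE)
  out[!zero] <- stats::dnorm(J[!zero], mean = w[!zero] - ch$tau, sd = ch$nu,
                             log = TRUE)
  out
}

# Score of the channel at the null signal for zero-weight entries:
# d/dw log P(J=0|w) at w = 0  =  -phi(t) / (nu * Phi(t)),  t = tau/nu.
score_at_zero <- function(ch) {
  t <- ch$tau / ch$nu
  -exp(stats::dnorm(t, log = TRUE) - stats::pnorm(t, log.p = TRUE)) / ch$nu
}

#' Fisher score matrix of a connectivity matrix
#'
#' Elementwise derivative of the log output channel with respect to the
#' signal, evaluated at the null signal w = 0:
#' \eqn{S_{ij} = (J_{ij}+\tau)/\nu^2} where \eqn{J_{ij} > 0}, and a negative
#' constant \eqn{-\phi(\tau/\nu)/(\nu\,\Phi(\tau/\nu))} where
#' \eqn{J_{ij} = 0}. S is the sufficient statistic driving the message
#' passing iteration and the improved spectral baseline; it has zero mean
#' under the null channel. The diagonal (self-couplings, unobserved) is set
#' to 0.
#'
#' @param J symmetric non-negative N x N connectivity matrix.
#' @param ch a \code{\link{channel_spec}}.
#' @return N x N symmetric score matrix with zero diagonal.
#' @export
fisher_score <- function(J, ch) {
  stopifnot(inherits(ch, "channel_spec"))
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("'J' must be square")
  .fisher_score_cpp(J, ch$tau, ch$nu, score_at_zero(ch))
}

#' Effective noise of the channel
#'
#' The inverse Fisher information of the output channel at the null signal,
#' \eqn{1/\Delta = E_{P_{out}(J|w=0)}[S(J)^2]}. This single scalar is all
#' the message-passing algorithm and its state evolution retain about the
#' channel ("channel universality"): reconstruction is possible iff
#' \eqn{\Delta} is below the prior-dependent critical value
#' \code{\link{critical_delta}}.
#'
#' With \eqn{t = \tau/\nu}, the closed form (derived by reducing the
#' defining expectation) is
#' \deqn{1/\Delta = \phi(t)^2 / (\nu^2 \Phi(t)) + (1 - \Phi(t) + t\phi(t))/\nu^2.}
#' \code{method = "quadrature"} instead integrates the defining expectation
#' numerically (atom term plus \code{integrate()} over J > 0); the two agree
#' to better than 1e-8 and the quadrature route is kept as an independent
#' check.
#'
#' @param ch a \code{\link{channel_spec}}.
#' @param method \code{"analytic"} (default) or \code{"quadrature"}.
#' @return the effective noise Delta (scalar, > 0).
#' @export
effective_noise <- function(ch, method = c("analytic", "quadrature")) {
  stopifnot(inherits(ch, "channel_spec"))
  method <- match.arg(method)
  nu <- ch$nu
  if (method == "analytic") {
    t <- ch$tau / nu
    atom <- exp(2 * stats::dnorm(t, log = TRUE) -
                  stats::pnorm(t, log.p = TRUE)) / nu^2
    tail <- (stats::pnorm(t, lower.tail = FALSE) + t * stats::dnorm(t)) / nu^2
    inv_delta <- atom + tail
  } else {
    s0 <- score_at_zero(ch)
    p0 <- stats::pnorm(ch$tau / nu)          # P(J = 0 | w = 0)
    dens <- function(J) exp(log_output_density(J, 0, ch)) *
      ((J + ch$tau) / nu^2)^2
    q <- stats::integrate(dens, 0, Inf, rel.tol = 1e-12, abs.tol = 0)
    if (q$message != "OK") stop("quadrature failed: ", q$message)
    inv_delta <- p0 * s0^2 + q$value
  }
  1 / inv_delta
}

#' Solve for the noise level realising a target effective noise
#'
#' Finds all noise standard deviations \eqn{\nu \in [10^{-4}, 10^3]} with
#' \code{effective_noise(channel_spec(tau, nu)) == delta_target}. At
#' \eqn{\tau = 0} the relation is \eqn{\Delta = \nu^2 / (1/2 + 1/\pi)} and
#' the unique root is returned in closed form. For \eqn{\tau > 0},
#' \eqn{\Delta(\nu)} is non-monotone (stochastic resonance: noise first
#' helps, then hurts), so sign changes are bracketed on a 400-point
#' geometric grid and each is polished by \code{uniroot}; small targets may
#' return two roots.
#'
#' @param delta_target target effective noise, > 0.
#' @param tau channel threshold, >= 0.
#' @return numeric vector of roots nu (increasing); errors if none exists in
#'   range.
#' @export
solve_nu_for_delta <- function(delta_target, tau) {
  stopifnot(is.numeric(delta_target), delta_target > 0, tau >= 0)
  if (tau == 0)
    return(sqrt(delta_target * (0.5 + 1 / pi)))
  g <- function(nu) effective_noise(channel_spec(tau, nu)) - delta_target
  grid <- exp(seq(log(1e-4), log(1e3), length.out = 400))
  vals <- vapply(grid, g, numeric(1))
  sgn <- sign(vals)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i)
    stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root, numeric(1))
  exact <- grid[vals == 0]
  roots <- sort(unique(c(roots, exact)))
  if (length(roots) == 0L)
    stop("unreachable Delta = ", delta_target, " at tau = ", tau,
         ": no nu in [1e-4, 1e3] attains it")
  roots
}

#' Critical noise level as a function of connection probability
#'
#' For a given connection probability \eqn{p_C} the threshold is eliminated
#' exactly via \eqn{\tau = \nu\,\Phi^{-1}(1 - p_C)} (the inverse of
#' \code{\link{p_connect}}), which fixes the ratio \eqn{t = \tau/\nu}. The
#' system \eqn{\{\Delta(\tau, \nu) = \Delta_c,\; p_C(\tau,\nu) = p_C\}} then
#' reduces to one dimension and the largest noise standard deviation at
#' which reconstruction remains possible is
#' \eqn{\nu^* = \sqrt{\Delta_c\, c(t)}} with
#' \eqn{c(t) = \phi(t)^2/\Phi(t) + 1 - \Phi(t) + t\phi(t)}.
#'
#' @param p_C connection probability in (0, 0.5].
#' @param prior a \code{\link{prior_spec}} (sets the critical effective
#'   noise).
#' @return list with \code{nu} (the critical noise sd), \code{tau} (the
#'   matching threshold) and \code{delta} (the realised effective noise,
#'   equal to the prior's critical value).
#' @export
critical_nu_of_pc <- function(p_C, prior) {
  stopifnot(is.numeric(p_C), p_C > 0, p_C <= 0.5)
  delta_c <- critical_delta(prior)
  t <- stats::qnorm(1 - p_C)                 # tau / nu fixed by p_C
  c_t <- exp(2 * stats::dnorm(t, log = TRUE) - stats::pnorm(t, log.p = TRUE)) +
    stats::pnorm(t, lower.tail = FALSE) + t * stats::dnorm(t)
  nu <- sqrt(delta_c * c_t)
  list(nu = nu, tau = t * nu, delta = delta_c)
}
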