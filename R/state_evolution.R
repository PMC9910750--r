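# Gauss-Hermite rule cached per session; 201 nodes is deliberately
# generous -- the integrand is analytic times a Gaussian, so accuracy is
# limited by double precision well before node count.
gh_env <- new.env(parent = emptyenv())

gh_rule <- function(n = 201L) {
  key <- as.character(n)
  if (is.null(gh_env[[key]])) {
    r <- pracma::gaussHermite(n)
    # E_z[h(z)] for z ~ N(0,1): change of variables z = sqrt(2) * node
    gh_env[[key]] <- list(z = sqrt(2) * r$x, w = r$w / sqrt(pi))
  }
  gh_env[[key]]
}

#' One step of the scalar state evolution
#'
#' The overlap \eqn{m^t} between the message-passing estimate and the ground
#' truth evolves, in the large-N limit and under the uncorrelated-pattern
#' ansatz \eqn{M^t = m^t I_P}, by the scalar recursion
#' \deqn{m^{t+1} = E_{x_0, z}\left[ f\!\left(\frac{m}{\Delta},
#'   \frac{m}{\Delta} x_0 + \sqrt{\frac{m}{\Delta}}\, z\right) x_0 \right],}
#' where \eqn{f(a, b)} is the scalar posterior-mean (threshold) function of
#' the prior, \eqn{x_0} is a draw from the prior and \eqn{z} a standard
#' Gaussian. The expectation over \eqn{x_0} is an exact sum over the prior
#' support; the expectation over \eqn{z} uses Gauss-Hermite quadrature. The
#' same generic recursion serves all three prior families (their closed-form
#' specialisations are used as test oracles, not as the implementation).
#'
#' @param m current overlap, >= 0 (vectorised).
#' @param delta effective noise, > 0.
#' @param prior a \code{\link{prior_spec}}.
#' @param nodes number of Gauss-Hermite nodes (default 201).
#' @return next overlap(s).
#' @export
se_step <- function(m, delta, prior, nodes = 201L) {
  stopifnot(inherits(prior, "prior_spec"), delta > 0)
  if (any(m < 0)) stop("'m' must be non-negative")
  gh <- gh_rule(nodes)
  tb <- prior_table(prior)
  vapply(m, function(mi) {
    if (mi == 0) return(0)
    a <- mi / delta
    s <- sqrt(mi / delta)
    acc <- 0
    for (k in seq_along(tb$x)) {
      b <- a * tb$x[k] + s * gh$z
      fv <- tilt_mean_var(prior, a, b)$mean
      acc <- acc + tb$p[k] * tb$x[k] * sum(gh$w * fv)
    }
    acc
  }, numeric(1))
}

#' Iterate the state evolution to a fixed point
#'
#' Fixed-point iteration of \code{\link{se_step}} from either a vanishing
#' initial overlap (\code{"random"}: \eqn{m^0 = \delta_{seed}}, the overlap
#' an uninformed prior draw would have) or an informed one
#' (\code{"informed"}: \eqn{m^0 = m_2 (1 - \delta_{seed})}, i.e. starting at
#' the solution; \eqn{m_2} is the prior second moment). The two branches
#' coincide in the easy phase and separate in a hard phase.
#'
#' @param delta effective noise, > 0.
#' @param prior a \code{\link{prior_spec}}.
#' @param init \code{"random"} or \code{"informed"}.
#' @param delta_seed initial perturbation (default 1e-6).
#' @param tol convergence tolerance on |m_{t+1} - m_t| (default 1e-10).
#' @param max_iter iteration cap (default 5000).
#' @param nodes Gauss-Hermite nodes passed to \code{\link{se_step}}.
#' @return object of class \code{se_result}: list with \code{m_trajectory},
#'   \code{m_fixed}, \code{mse_predicted} (normalized per-pattern error
#'   \eqn{(m_2 - m)/m_2}), \code{mse_raw} (per-pattern, \eqn{m_2 - m}),
#'   \code{iterations}, \code{converged}, \code{initialisation}.
#' @export
iterate_se <- function(delta, prior, init = c("random", "informed"),
                       delta_seed = 1e-6, tol = 1e-10, max_iter = 5000L,
                       nodes = 201L) {
  stopifnot(inherits(prior, "prior_spec"), delta > 0)
  init <- match.arg(init)
  m2 <- prior_moments(prior)[["m2"]]
  m <- if (init == "random") delta_seed else m2 * (1 - delta_seed)
  traj <- m
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m_new <- se_step(m, delta, prior, nodes = nodes)
    m_new <- min(max(m_new, 0), m2)
    traj <- c(traj, m_new)
    if (abs(m_new - m) < tol) { m <- m_new; converged <- TRUE; break }
    m <- m_new
  }
  structure(list(m_trajectory = traj, m_fixed = m,
                 mse_predicted = (m2 - m) / m2,
                 mse_raw = m2 - m,
                 iterations = length(traj) - 1L,
                 converged = converged, initialisation = init),
            class = "se_result")
}

#' @export
print.se_result <- function(x, ...) {
  cat(sprintf("<se_result> init = %s, m* = %.6g, normalized mse = %.6g (%d iterations%s)\n",
              x$initialisation, x$m_fixed, x$mse_predicted, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Critical effective noise of a prior
#'
#' The effective noise at which the uninformative fixed point \eqn{m = 0} of
#' the state evolution loses stability. Linearising the recursion gives
#' \eqn{m^{t+1} = (\langle x^2\rangle^2/\Delta)\, m^t}, so
#' \eqn{\Delta_c = \langle x^2\rangle^2}: 1 for binary, \eqn{\rho^2} for
#' sparse, \eqn{\rho^2(1-\rho)^2} for low-coding patterns. Above
#' \eqn{\Delta_c} no reconstruction better than a prior draw is possible for
#' message passing (and, for the symmetric priors, conjecturally for any
#' polynomial-time algorithm).
#'
#' @param prior a \code{\link{prior_spec}}.
#' @return the critical effective noise (scalar).
#' @export
critical_delta <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  prior_moments(prior)[["m2"]]^2
}

#' Recoverability phase diagram over the channel parameters
#'
#' Evaluates, on a (tau, nu) grid, the effective noise of the channel and
#' marks a cell recoverable iff it is below the prior's critical value.
#' The connection probability is evaluated on the same grid for contour
#' overlays. At fixed tau > 0 the recoverable set is an interval in nu
#' (possibly empty): too little noise and the rectification erases the
#' sub-threshold signal, too much and the noise drowns it (stochastic
#' resonance).
#'
#' @param prior a \code{\link{prior_spec}}.
#' @param tau_grid numeric vector of thresholds (>= 0).
#' @param nu_grid numeric vector of noise sds (> 0).
#' @return data.frame with columns \code{tau}, \code{nu}, \code{delta},
#'   \code{p_connect}, \code{recoverable}.
#' @export
phase_diagram <- function(prior, tau_grid, nu_grid) {
  stopifnot(inherits(prior, "prior_spec"),
            all(tau_grid >= 0), all(nu_grid > 0))
  dc <- critical_delta(prior)
  g <- expand.grid(tau = tau_grid, nu = nu_grid)
  g$delta <- mapply(function(tau, nu) effective_noise(channel_spec(tau, nu)),
                    g$tau, g$nu)
  g$p_connect <- mapply(function(tau, nu) p_connect(channel_spec(tau, nu)),
                        g$tau, g$nu)
  g$recoverable <- g$delta < dc
  g
}
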