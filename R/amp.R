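#' Options for the message-passing reconstruction
#'
#' @param mode \code{"exact"} (full P x P curvature, threshold function by
#'   exact enumeration of the prior support) or \code{"meanfield"}
#'   (factorised posterior, diagonal curvature only; required for large P).
#' @param init \code{"random"} (estimate initialised with a fresh draw from
#'   the prior -- an uninformed start carrying only the O(1/sqrt(N)) chance
#'   overlap) or \code{"informed"} (initialised at the ground truth).
#' @param damping scalar eta in [0, 1): new iterate mixed as
#'   (1-eta) * new + eta * old after thresholding. Default 0 (no damping);
#'   0.5 is a reasonable fallback if the iteration oscillates.
#' @param max_iter iteration cap (default 200).
#' @param tol convergence threshold epsilon on the mean squared update
#'   of the estimate, (1/N) sum_i ||xhat_i^t - xhat_i^{t-1}||^2 (default 1e-8).
#' @param seed integer seed for the random initialisation.
#' @param onsager keep the memory (Onsager) correction in the field update
#'   (default TRUE). Disabling it turns the iteration into naive iterated
#'   thresholding, which no longer tracks state evolution; exposed for
#'   diagnostics only.
#' @param n_sweep number of sequential sweeps of the mean-field threshold
#'   per iteration (default 1; meanfield mode only).
#' @param block_size slots updated together within a sweep; the cross-slot
#'   correction is refreshed between blocks (default 1 = fully sequential;
#'   larger blocks trade a little sequencing for BLAS-level speed).
#' @param backend \code{"cpp"} (compiled mean-field kernel, default) or
#'   \code{"R"} (reference implementation of the same update, used for
#'   cross-validation; much slower).
#' @return an object of class \code{amp_options}.
#' @export
amp_options <- function(mode = c("exact", "meanfield"),
                        init = c("random", "informed"),
                        damping = 0, max_iter = 200L, tol = 1e-8,
                        seed = NULL, onsager = TRUE, n_sweep = 1L,
                        block_size = 1L, backend = c("cpp", "R")) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  backend <- match.arg(backend)
  stopifnot(damping >= 0, damping < 1, max_iter >= 1, tol > 0, n_sweep >= 1,
            block_size >= 1)
  structure(list(mode = mode, init = init, damping = damping,
                 max_iter = as.integer(max_iter), tol = tol, seed = seed,
                 onsager = isTRUE(onsager), n_sweep = as.integer(n_sweep),
                 block_size = as.integer(block_size), backend = backend),
            class = "amp_options")
}

prior_code <- function(spec)
  match(spec$family, c("binary", "sparse", "low_coding")) - 1L

# Exact-mode threshold step, vectorised over neurons.
# B: N x P fields; Aflat: N x P^2 curvatures (row i = vec(A_i), column-major).
# Returns list(mean: N x P, covflat: N x P^2).
threshold_exact <- function(prior, B, Aflat) {
  P <- ncol(B)
  en <- enumerate_support(prior, P)        # X: P x K
  X <- en$X
  K <- ncol(X)
  # log-weights for every neuron x support vector: N x K
  quad <- matrix(vapply(seq_len(K),
                        function(k) as.vector(tcrossprod(X[, k])),
                        numeric(P * P)), nrow = P * P)     # P^2 x K
  logw <- B %*% X - 0.5 * (Aflat %*% quad) +
    rep(en$logp, each = nrow(B))
  mx <- logw[cbind(seq_len(nrow(logw)), max.col(logw))]
  W <- exp(logw - mx)
  W <- W / rowSums(W)
  mean <- W %*% t(X)                       # N x P
  Exx <- W %*% t(quad)                     # N x P^2
  idx <- expand.grid(p = seq_len(P), q = seq_len(P))
  covflat <- Exx - mean[, idx$p, drop = FALSE] * mean[, idx$q, drop = FALSE]
  list(mean = mean, covflat = covflat)
}

#' Run the Low-RAMP message-passing reconstruction
#'
#' Iterates the approximate-message-passing update for symmetric low-rank
#' matrix factorisation on the Fisher score matrix S of an observed
#' connectivity matrix. Per neuron i, the data enter through a Gaussian
#' field and curvature
#' \deqn{b_i = \frac{1}{\sqrt N}\sum_k S_{ki}\,\hat x_k -
#'   \Big(\frac{1}{N}\sum_k S^2_{ki}\,\sigma_k\Big)\hat x_i^{t-1}, \qquad
#'   A_i = \frac{1}{N}\sum_k S^2_{ki}\,\hat x_k \hat x_k^\top,}
#' and the estimate is refreshed through the prior's posterior-mean
#' threshold function, \eqn{\hat x_i = f(A_i, b_i)}, with
#' \eqn{\sigma_i = \partial_b f} its covariance. The second (Onsager) term
#' in \eqn{b_i} cancels the feedback of neuron i's own previous estimate;
#' without it the iteration no longer tracks state evolution. The iteration
#' stops when the mean squared update falls below \code{options$tol} or at
#' \code{options$max_iter}.
#'
#' @param S N x N symmetric score matrix with zero diagonal (from
#'   \code{\link{fisher_score}}).
#' @param prior a \code{\link{prior_spec}}.
#' @param P number of patterns to infer (defaults to
#'   \code{nrow(ground_truth)}).
#' @param options an \code{\link{amp_options}} object.
#' @param ground_truth optional P x N pattern matrix; if supplied, the
#'   per-iteration aligned reconstruction error is recorded and the final
#'   overlap matrix is computed. Required for \code{init = "informed"}.
#' @return an object of class \code{amp_result}: list with \code{estimate}
#'   (N x P posterior means), \code{covariances} (N x P^2 flattened per-
#'   neuron covariances in exact mode, N x P variances in meanfield mode),
#'   \code{overlap} (P x P matrix \eqn{M = \frac1N\sum_i \hat x_i x_i^{*T}},
#'   or NULL), \code{iterations}, \code{converged},
#'   \code{mse_trajectory} (aligned raw per-pattern mse each iteration on
#'   the R backends, the final value on the compiled kernels, or NULL),
#'   \code{mirror_restart} (TRUE when a skewed-prior run was restarted
#'   from its mirrored estimate -- the likelihood is sign-symmetric, so an
#'   uninformed start can land in the sign-flipped basin, which is
#'   detected from the sign of the estimate's third moment),
#'   \code{options}.
#' @export
run_amp <- function(S, prior, P = NULL, options = amp_options(),
                    ground_truth = NULL) {
  stopifnot(inherits(prior, "prior_spec"), inherits(options, "amp_options"))
  S <- as.matrix(S)
  N <- nrow(S)
  if (ncol(S) != N) stop("'S' must be square")
  if (max(abs(diag(S))) > 0) stop("'S' must have zero diagonal")
  if (is.null(P)) {
    if (is.null(ground_truth)) stop("supply 'P' or 'ground_truth'")
    P <- nrow(ground_truth)
  }
  if (!is.null(ground_truth) && (nrow(ground_truth) != P ||
                                 ncol(ground_truth) != N))
    stop("'ground_truth' must be P x N")
  if (options$init == "informed" && is.null(ground_truth))
    stop("informed initialisation requires 'ground_truth'")
  if (options$mode == "exact")
    enumerate_support(prior, P)  # enforce the enumeration cap up front

  if (options$init == "random") {
    if (!is.null(options$seed)) set.seed(options$seed)
    Xhat <- t(sample_patterns(prior, P, N))
  } else {
    Xhat <- t(ground_truth)
  }

  r <- amp_iterate(S, prior, P, options, Xhat, ground_truth)

  # Mirror-basin escape for skewed priors: the likelihood depends on the
  # patterns only through X'X and is therefore sign-symmetric, while a
  # skewed prior is not -- an uninformed start can fall into a metastable
  # mirrored basin where the roles of active and inactive neurons are
  # swapped. That state is a genuine fixed point but fits the data much
  # worse (the quadratic form tr(Xhat' S Xhat) grows with the squared
  # overlap, which the prior suppresses in the mirrored basin). For skewed
  # priors a second run is therefore started from the mirrored estimate
  # and the better-fitting of the two states is kept.
  if (options$init == "random" && prior_moments(prior)[["m3"]] != 0) {
    fit <- function(X) sum(X * (S %*% X))
    r2 <- amp_iterate(S, prior, P, options, -r$estimate, ground_truth)
    iters <- r$iterations + r2$iterations
    if (fit(r2$estimate) > fit(r$estimate)) {
      r2$mirror_restart <- TRUE
      r <- r2
    }
    r$iterations <- iters
  }

  overlap <- if (is.null(ground_truth)) NULL else
    crossprod(r$estimate, t(ground_truth)) / N
  structure(list(estimate = r$estimate, covariances = r$covariances,
                 overlap = overlap, iterations = r$iterations,
                 converged = r$converged, mse_trajectory = r$mse_traj,
                 mirror_restart = isTRUE(r$mirror_restart),
                 options = options),
            class = "amp_result")
}

# One full run of the iteration from a given initial estimate; returns the
# raw state (estimate, covariances, iterations, converged, mse_traj).
amp_iterate <- function(S, prior, P, options, Xhat, ground_truth = NULL) {
  N <- nrow(S)
  sqN <- sqrt(N)
  eta <- options$damping

  if (options$backend == "cpp" && (options$mode == "meanfield" || P == 1L)) {
    # at P = 1 the exact and mean-field thresholds coincide, so the fused
    # single-pattern kernel serves both modes
    r <- if (P == 1L)
      .amp_rank1_cpp(S, as.vector(Xhat), prior_code(prior), prior$rho,
                     options$max_iter, options$tol, eta, options$onsager)
    else
      .amp_meanfield_cpp(S, S * S, Xhat, prior_code(prior), prior$rho,
                         options$max_iter, options$tol, eta,
                         options$onsager, options$n_sweep,
                         options$block_size)
    r$estimate <- matrix(r$estimate, N)
    r$covariances <- matrix(r$covariances, N)
    mse_traj <- if (is.null(ground_truth)) NULL else
      reconstruction_error(r$estimate, ground_truth, prior = prior,
                           aligned = TRUE) / P
    return(list(estimate = r$estimate, covariances = r$covariances,
                iterations = r$iterations, converged = r$converged,
                mse_traj = mse_traj))
  }

  S2 <- S * S
  Xprev <- matrix(0, N, P)
  Sigma <- if (options$mode == "exact") matrix(0, N, P * P) else
    matrix(0, N, P)

  mse_traj <- if (is.null(ground_truth)) NULL else numeric(0)
  converged <- FALSE
  iterations <- 0L

  for (t in seq_len(options$max_iter)) {
    B <- (S %*% Xhat) / sqN
    if (options$mode == "exact") {
      Cmat <- (S2 %*% Sigma) / N                     # N x P^2
      if (options$onsager)
        for (p in seq_len(P))
          B[, p] <- B[, p] -
            rowSums(Cmat[, (seq_len(P) - 1L) * P + p, drop = FALSE] * Xprev)
      Aflat <- matrix(0, N, P * P)
      for (q in seq_len(P))
        Aflat[, (q - 1L) * P + seq_len(P)] <-
          (S2 %*% (Xhat * Xhat[, q])) / N
      th <- threshold_exact(prior, B, Aflat)
      Xnew <- th$mean; Snew <- th$covflat
    } else {
      if (options$onsager) B <- B - ((S2 %*% Sigma) / N) * Xprev
      a <- (S2 %*% (Xhat * Xhat)) / N
      if (P > 1L) {
        # mean-field treatment of the cross-pattern curvature: slot j of
        # neuron i sees the field b_ij - sum_{k != j} A_i[j,k] xin_ik with
        # A_i = (1/N) sum_m S2_mi xhat_m xhat_m'. Evaluated slot-
        # sequentially (each slot sees the freshest means of the others)
        # via G_mi = xhat_m . xin_i, never forming the per-neuron A_i.
        # This competition term is what steers the estimate columns to
        # distinct patterns; the synchronous variant oscillates at large P.
        # R reference for the compiled kernel in src/amp_meanfield.cpp.
        Xin <- Xhat; Vin <- Sigma
        bs <- options$block_size
        G <- tcrossprod(Xhat, Xin)
        for (sw in seq_len(options$n_sweep)) {
          for (j0 in seq(1L, P, by = bs)) {
            j1 <- min(j0 + bs - 1L, P)
            Cb <- crossprod(S2 * G, Xhat[, j0:j1, drop = FALSE]) / N
            dX <- matrix(0, N, j1 - j0 + 1L)
            for (j in j0:j1) {
              cj <- Cb[, j - j0 + 1L] - a[, j] * Xin[, j]
              th <- tilt_mean_var(prior, a[, j], B[, j] - cj)
              dX[, j - j0 + 1L] <- th$mean - Xin[, j]
              Xin[, j] <- th$mean; Vin[, j] <- th$var
            }
            G <- G + Xhat[, j0:j1, drop = FALSE] %*% t(dX)
          }
        }
        Xnew <- Xin; Snew <- Vin
      } else {
        th <- tilt_mean_var(prior, as.vector(a), as.vector(B))
        Xnew <- matrix(th$mean, N, P)
        Snew <- matrix(th$var, N, P)
      }
    }
    if (!all(is.finite(Xnew)))
      stop("message-passing iteration diverged (non-finite estimates); ",
           "consider damping (amp_options(damping = 0.5))")
    if (eta > 0) {
      Xnew <- (1 - eta) * Xnew + eta * Xhat
      Snew <- (1 - eta) * Snew + eta * Sigma
    }
    upd <- sum((Xnew - Xhat)^2) / N
    Xprev <- Xhat
    Xhat <- Xnew
    Sigma <- Snew
    iterations <- t
    if (!is.null(ground_truth))
      mse_traj <- c(mse_traj,
                    reconstruction_error(Xhat, ground_truth, prior = prior,
                                         aligned = TRUE) / P)
    if (upd < options$tol) { converged <- TRUE; break }
  }

  list(estimate = Xhat, covariances = Sigma, iterations = iterations,
       converged = converged, mse_traj = mse_traj)
}

#' @export
print.amp_result <- function(x, ...) {
  cat(sprintf("<amp_result> N = %d, P = %d, mode = %s, %d iterations%s\n",
              nrow(x$estimate), ncol(x$estimate), x$options$mode,
              x$iterations, if (x$converged) " (converged)" else
                " (NOT converged)"))
  if (!is.null(x$mse_trajectory))
    cat(sprintf("  final aligned per-pattern mse: %.6g\n",
                utils::tail(x$mse_trajectory, 1)))
  invisible(x)
}

#' Align an estimate with the ground-truth patterns
#'
#' The posterior is invariant under permutations of the patterns, and -- for
#' the sign-symmetric priors (binary, sparse) -- under per-pattern sign
#' flips, so an estimate can only be compared to the ground truth up to
#' these symmetries. Computes the P x P cross-overlap matrix and greedily
#' matches estimate columns to truth rows by maximum absolute overlap (ties
#' broken by lowest index). Signs are taken from the matched overlaps for
#' sign-symmetric priors and fixed to +1 for the (skewed) low-coding prior.
#'
#' @param estimate N x P matrix of estimated tuning curves.
#' @param truth P x N ground-truth pattern matrix.
#' @param prior the generating \code{\link{prior_spec}}; defaults to
#'   \code{attr(truth, "prior")}. If unknown, sign flips are allowed.
#' @return list with \code{permutation} (P-vector: column
#'   \code{permutation[q]} of the estimate matches truth row q) and
#'   \code{signs} (P-vector of +/-1).
#' @export
align_patterns <- function(estimate, truth, prior = attr(truth, "prior")) {
  estimate <- as.matrix(estimate)
  P <- nrow(truth)
  if (ncol(estimate) != P || nrow(estimate) != ncol(truth))
    stop("shape mismatch between estimate and truth")
  sign_symmetric <- is.null(prior) || prior$family %in% c("binary", "sparse")
  O <- crossprod(estimate, t(truth)) / ncol(truth)   # P_est x P_truth
  A <- abs(O)
  perm <- integer(P); signs <- rep(1, P)
  for (step in seq_len(P)) {
    k <- which.max(A)                      # lowest linear index on ties
    p <- (k - 1L) %% P + 1L                # estimate column
    q <- (k - 1L) %/% P + 1L               # truth row
    perm[q] <- p
    if (sign_symmetric) signs[q] <- if (O[p, q] >= 0) 1 else -1
    A[p, ] <- -Inf
    A[, q] <- -Inf
  }
  list(permutation = perm, signs = signs)
}

# Apply an alignment: column q of the result is signs[q] * estimate[, perm[q]].
apply_alignment <- function(estimate, alignment) {
  sweep(estimate[, alignment$permutation, drop = FALSE], 2L,
        alignment$signs, `*`)
}

#' Reconstruction mean squared error
#'
#' The total reconstruction error
#' \eqn{\mathrm{mse} = \frac1N \sum_i \|\hat x_i - x^*_i\|_2^2} (summed over
#' the P components of each neuron's tuning curve). With
#' \code{aligned = TRUE} the estimate is first matched to the truth by
#' \code{\link{align_patterns}}. With \code{normalized = TRUE} the error is
#' divided by \eqn{P\,m_2} (the error of the all-zero estimate), so that an
#' uninformative reconstruction scores 1 for every prior; otherwise the raw
#' error is returned.
#'
#' @param estimate N x P matrix.
#' @param truth P x N pattern matrix.
#' @param aligned match patterns (and signs, where symmetric) first
#'   (default TRUE).
#' @param normalized divide by P * m2 (default FALSE).
#' @param prior the generating \code{\link{prior_spec}}; defaults to
#'   \code{attr(truth, "prior")}; required when \code{normalized = TRUE}.
#' @return scalar mse.
#' @export
reconstruction_error <- function(estimate, truth, aligned = TRUE,
                                 normalized = FALSE,
                                 prior = attr(truth, "prior")) {
  estimate <- as.matrix(estimate)
  if (ncol(estimate) != nrow(truth) || nrow(estimate) != ncol(truth))
    stop("shape mismatch between estimate and truth")
  if (aligned)
    estimate <- apply_alignment(estimate,
                                align_patterns(estimate, truth, prior))
  mse <- sum((estimate - t(truth))^2) / ncol(truth)
  if (normalized) {
    if (is.null(prior)) stop("'prior' is required for normalized = TRUE")
    mse <- mse / (nrow(truth) * prior_moments(prior)[["m2"]])
  }
  mse
}
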