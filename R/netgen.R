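#' Generate a synthetic rectified-Hopfield instance
#'
#' Produces a complete instance of the generative model: patterns
#' \eqn{X^*} (P x N, i.i.d. from the prior), the Hebbian matrix
#' \eqn{W = X^{*T} X^* / \sqrt{N}}, and the observed connectivity
#' \eqn{J = \max(0, W - \tau + \zeta)} with \eqn{\zeta} a symmetric Gaussian
#' noise matrix of sd \eqn{\nu} (drawn once on the upper triangle and
#' mirrored). The \eqn{1/\sqrt{N}} scaling puts the model at the spiked
#' Wigner operating point, where signal and noise compete at the same order
#' and reconstruction is neither trivial nor hopeless. The diagonal of both
#' W and J is stored as 0: self-couplings are unobserved and carry no
#' information. An entry is an absent synapse (exactly 0) iff
#' \eqn{W_{ij} - \tau + \zeta_{ij} \le 0}.
#'
#' @param prior a \code{\link{prior_spec}}.
#' @param ch a \code{\link{channel_spec}}.
#' @param N number of neurons, >= 2.
#' @param P number of stored patterns, >= 1.
#' @param seed integer seed; instances are bit-reproducible per seed.
#' @param keep_hebbian keep the noiseless Hebbian matrix W in the result
#'   (doubles memory at large N; default TRUE).
#' @return an object of class \code{memrec_instance}: list with
#'   \code{patterns} (P x N), \code{hebbian} (N x N or NULL),
#'   \code{connectivity} (N x N, symmetric, non-negative, zero diagonal),
#'   \code{prior}, \code{channel}, \code{seed}.
#' @examples
#' inst <- generate_instance(prior_spec("binary"), channel_spec(0, 1),
#'                           N = 200, P = 2, seed = 1)
#' mean(inst$connectivity[upper.tri(inst$connectivity)] > 0) # ~ p_connect
#' @export
generate_instance <- function(prior, ch, N, P, seed = NULL,
                              keep_hebbian = TRUE) {
  stopifnot(inherits(prior, "prior_spec"), inherits(ch, "channel_spec"),
            N >= 2, P >= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- sample_patterns(prior, P, N)
  W <- crossprod(X) / sqrt(N)              # N x N, W_ij = sum_mu X_mui X_muj / sqrt(N)
  # noise drawn once on the upper triangle and mirrored; rectification and
  # symmetrisation in one pass (compiled; R RNG, so seed-reproducible)
  J <- .rectify_noisy_cpp(W, ch$tau, ch$nu)
  diag(W) <- 0
  structure(list(patterns = X,
                 hebbian = if (keep_hebbian) W else NULL,
                 connectivity = J,
                 prior = prior, channel = ch, seed = seed),
            class = "memrec_instance")
}

#' @export
print.memrec_instance <- function(x, ...) {
  N <- ncol(x$patterns); P <- nrow(x$patterns)
  cat(sprintf("<memrec_instance> N = %d, P = %d, prior = %s, tau = %g, nu = %g\n",
              N, P, format(x$prior), x$channel$tau, x$channel$nu))
  cat(sprintf("  connection density: %.4f (channel p_C = %.4f)\n",
              mean(x$connectivity[upper.tri(x$connectivity)] > 0),
              p_connect(x$channel)))
  invisible(x)
}

#' Write a connectivity matrix (dense CSV or sparse Matrix Market)
#'
#' Entries are raw weights; format is chosen by the file extension
#' (\code{.csv} for dense comma-separated values without header, \code{.mtx}
#' for Matrix Market sparse storage of the non-zero weights).
#'
#' @param J numeric matrix.
#' @param path output file path ending in \code{.csv} or \code{.mtx}.
#' @export
write_connectivity <- function(J, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(J, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(J, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
  } else stop("unsupported extension '", ext, "' (use .csv or .mtx)")
  invisible(path)
}

#' Read a connectivity matrix written by \code{\link{write_connectivity}}
#'
#' @param path file path ending in \code{.csv} or \code{.mtx}.
#' @return a dense numeric matrix.
#' @export
read_connectivity <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else if (ext == "mtx") {
    as.matrix(Matrix::readMM(path))
  } else stop("unsupported extension '", ext, "' (use .csv or .mtx)")
}

#' Write a full instance to a directory
#'
#' Writes the connectivity (\code{connectivity.csv} or \code{.mtx}), the
#' ground-truth patterns (\code{patterns.csv}) and a JSON sidecar
#' (\code{instance.json}) with all hyper-parameters.
#'
#' @param inst a \code{memrec_instance}.
#' @param dir output directory (created if needed).
#' @param format \code{"csv"} or \code{"mtx"} for the connectivity.
#' @return the directory, invisibly.
#' @export
write_instance <- function(inst, dir, format = c("csv", "mtx")) {
  stopifnot(inherits(inst, "memrec_instance"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_connectivity(inst$connectivity,
                     file.path(dir, paste0("connectivity.", format)))
  utils::write.table(inst$patterns, file.path(dir, "patterns.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(N = ncol(inst$patterns), P = nrow(inst$patterns),
               prior = list(family = inst$prior$family, rho = inst$prior$rho),
               channel = list(tau = inst$channel$tau, nu = inst$channel$nu),
               seed = inst$seed)
  jsonlite::write_json(meta, file.path(dir, "instance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
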