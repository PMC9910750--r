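# Independent brute-force oracles used across the test files.

# Literal sum over the full support grid of the tilted distribution
# p(x) * exp(b'x - x'Ax/2) -- no log-space tricks, plain arithmetic.
brute_posterior <- function(spec, A, b) {
  tb <- memrec:::prior_table(spec)
  P <- length(b)
  A <- as.matrix(A)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_along(tb$x)), P)))
  Z <- 0
  m <- numeric(P)
  Exx <- matrix(0, P, P)
  for (r in seq_len(nrow(grid))) {
    x <- tb$x[grid[r, ]]
    w <- prod(tb$p[grid[r, ]]) * exp(sum(b * x) - 0.5 * sum(x * (A %*% x)))
    Z <- Z + w
    m <- m + w * x
    Exx <- Exx + w * tcrossprod(x)
  }
  m <- m / Z
  list(mean = m, cov = Exx / Z - tcrossprod(m))
}

# Brute-force optimal signed permutation: minimises the aligned mse over
# all P! x 2^P signed pattern assignments.
brute_align_mse <- function(estimate, truth, signs_allowed = TRUE) {
  P <- nrow(truth)
  perms <- if (P == 1) matrix(1) else
    as.matrix(do.call(expand.grid, rep(list(seq_len(P)), P)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == P), ,
                 drop = FALSE]
  sgns <- if (signs_allowed)
    as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), P))) else
      matrix(1, 1, P)
  best <- Inf
  for (i in seq_len(nrow(perms))) for (j in seq_len(nrow(sgns))) {
    est <- sweep(estimate[, perms[i, ], drop = FALSE], 2, sgns[j, ], `*`)
    best <- min(best, sum((est - t(truth))^2) / ncol(truth))
  }
  best
}

# Central finite difference of the log output channel in the signal w.
fd_score <- function(J, ch, h = 1e-5) {
  (log_output_density(J, h, ch) - log_output_density(J, -h, ch)) / (2 * h)
}

all_priors <- function() list(
  binary = prior_spec("binary"),
  sparse = prior_spec("sparse", 0.3),
  low_coding = prior_spec("low_coding", 0.3))
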