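make_instance <- function(prior, delta_frac, N, P, seed, tau = 0) {
  delta <- delta_frac * critical_delta(prior)
  ch <- channel_spec(tau, solve_nu_for_delta(delta, tau)[1])
  inst <- generate_instance(prior, ch, N, P, seed = seed,
                            keep_hebbian = FALSE)
  list(inst = inst, S = fisher_score(inst$connectivity, ch), delta = delta)
}

test_that("pattern alignment recovers planted permutations and signs", {
  pb <- prior_spec("binary")
  X <- sample_patterns(pb, 3, 400, seed = 2)
  perm <- c(3, 1, 2)
  signs <- c(-1, 1, -1)
  est <- t(X[perm, ] * signs)          # estimate column j = signs * truth perm
  al <- align_patterns(est, X)
  expect_equal(reconstruction_error(est, X, aligned = TRUE), 0)
  aligned <- memrec:::apply_alignment(est, al)
  expect_equal(aligned, t(unclass(X)), ignore_attr = TRUE)
  # P = 1 anti-correlated estimate gets sign -1
  x1 <- sample_patterns(pb, 1, 200, seed = 3)
  al1 <- align_patterns(-t(x1), x1)
  expect_equal(al1$signs, -1)
  # low-coding prior: no sign flips allowed
  lc <- prior_spec("low_coding", 0.3)
  Xl <- sample_patterns(lc, 2, 200, seed = 4)
  all <- align_patterns(-t(Xl), Xl)
  expect_equal(all$signs, c(1, 1))
})

test_that("greedy alignment matches exhaustive search over signed permutations", {
  set.seed(99)
  pb <- prior_spec("binary")
  for (P in c(2, 3)) {
    for (rep in 1:4) {
      X <- sample_patterns(pb, P, 300)
      est <- t(X) * 0.6 + matrix(rnorm(300 * P, sd = 0.8), 300, P)
      got <- reconstruction_error(est, X, aligned = TRUE)
      expect_equal(got, brute_align_mse(est, X), tolerance = 1e-12)
    }
  }
})

test_that("reconstruction error: exact, trivial and normalized baselines", {
  for (spec in all_priors()) {
    X <- sample_patterns(spec, 2, 300, seed = 6)
    m2 <- prior_moments(spec)[["m2"]]
    expect_equal(reconstruction_error(t(X), X), 0)
    # all-zero estimate scores P * m2 raw, 1 normalized (up to sampling noise)
    z <- matrix(0, 300, 2)
    expect_equal(reconstruction_error(z, X),
                 sum(X^2) / 300, tolerance = 1e-12)
    expect_equal(reconstruction_error(z, X, normalized = TRUE),
                 1, tolerance = 0.15)
  }
  # sign flip is free for the binary prior
  X <- sample_patterns(prior_spec("binary"), 1, 100, seed = 7)
  expect_equal(reconstruction_error(-t(X), X, aligned = TRUE), 0)
  expect_error(reconstruction_error(matrix(0, 10, 2),
                                    sample_patterns(prior_spec("binary"),
                                                    1, 10)),
               "shape")
})

test_that("estimates stay within the prior support bounds", {
  w <- make_instance(prior_spec("low_coding", 0.3), 0.5, 600, 1, seed = 13)
  res <- run_amp(w$S, prior_spec("low_coding", 0.3), P = 1,
                 options = amp_options(seed = 1))
  expect_true(all(res$estimate >= -0.3 - 1e-12))
  expect_true(all(res$estimate <= 0.7 + 1e-12))
})

test_that("informed initialisation stays at the informative fixed point", {
  pb <- prior_spec("binary")
  w <- make_instance(pb, 0.5, 1500, 1, seed = 21)
  res <- run_amp(w$S, pb, options = amp_options(init = "informed"),
                 ground_truth = w$inst$patterns)
  se <- iterate_se(w$delta, pb, init = "informed")
  expect_true(res$converged)
  expect_lt(abs(utils::tail(res$mse_trajectory, 1) - se$mse_raw), 0.08)
})

test_that("exact and mean-field modes coincide for a single pattern", {
  pb <- prior_spec("binary")
  w <- make_instance(pb, 0.6, 800, 1, seed = 31)
  re <- run_amp(w$S, pb, P = 1,
                options = amp_options(mode = "exact", seed = 5,
                                      backend = "R"),
                ground_truth = w$inst$patterns)
  # R backends record the trajectory; the fused compiled kernel must agree
  # on the final state
  rr <- run_amp(w$S, pb, P = 1,
                options = amp_options(mode = "meanfield", seed = 5,
                                      backend = "R"),
                ground_truth = w$inst$patterns)
  rc <- run_amp(w$S, pb, P = 1,
                options = amp_options(mode = "meanfield", seed = 5),
                ground_truth = w$inst$patterns)
  expect_equal(re$mse_trajectory, rr$mse_trajectory, tolerance = 1e-6)
  expect_equal(re$estimate, rr$estimate, tolerance = 1e-6)
  expect_equal(rc$estimate, rr$estimate, tolerance = 1e-10)
  expect_equal(rc$iterations, rr$iterations)
})

test_that("the Onsager correction is required to track state evolution", {
  pb <- prior_spec("binary")
  w <- make_instance(pb, 0.5, 2000, 1, seed = 41)
  se <- iterate_se(w$delta, pb)
  with_ons <- run_amp(w$S, pb, P = 1, options = amp_options(seed = 8),
                      ground_truth = w$inst$patterns)
  without <- run_amp(w$S, pb, P = 1,
                     options = amp_options(seed = 8, onsager = FALSE),
                     ground_truth = w$inst$patterns)
  dev_with <- abs(utils::tail(with_ons$mse_trajectory, 1) - se$mse_raw)
  dev_without <- abs(utils::tail(without$mse_trajectory, 1) - se$mse_raw)
  expect_lt(dev_with, 0.05)
  expect_gt(dev_without, dev_with)
})

test_that("multi-pattern exact mode recovers all planted patterns", {
  pb <- prior_spec("binary")
  w <- make_instance(pb, 0.3, 1000, 3, seed = 51)
  res <- run_amp(w$S, pb, P = 3, options = amp_options(seed = 12),
                 ground_truth = w$inst$patterns)
  se <- iterate_se(w$delta, pb)
  expect_true(res$converged)
  expect_lt(utils::tail(res$mse_trajectory, 1), 2 * se$mse_raw + 0.02)
  # overlap matrix close to m* times a signed permutation
  M <- res$overlap
  expect_equal(sort(apply(abs(M), 1, max)),
               rep(se$m_fixed, 3), tolerance = 0.1)
})

test_that("input validation catches malformed score matrices", {
  pb <- prior_spec("binary")
  S <- matrix(rnorm(16), 4)
  expect_error(run_amp(S, pb, P = 1), "diagonal")
  S2 <- matrix(0, 4, 5)
  expect_error(run_amp(S2, pb, P = 1), "square")
  S3 <- matrix(0.1, 4, 4); diag(S3) <- 0
  expect_error(run_amp(S3, pb), "'P' or 'ground_truth'")
  expect_error(run_amp(S3, pb, P = 1,
                       options = amp_options(init = "informed")),
               "informed")
})
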