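test_that("closed-form moments match brute-force expectations over the support", {
  for (rho in c(0.05, 0.3, 0.45, 0.7)) {
    for (fam in c("sparse", "low_coding")) {
      if (fam == "low_coding" && rho >= 1) next
      spec <- prior_spec(fam, rho)
      tb <- memrec:::prior_table(spec)
      mm <- prior_moments(spec)
      expect_equal(mm[["m1"]], sum(tb$p * tb$x), tolerance = 1e-15)
      expect_equal(mm[["m1"]], 0, tolerance = 1e-12)
      expect_equal(mm[["m2"]],
                   if (fam == "sparse") rho else rho * (1 - rho))
      expect_equal(mm[["m3"]],
                   if (fam == "sparse") 0 else rho * (1 - rho) * (1 - 2 * rho),
                   tolerance = 1e-12)
    }
  }
  expect_equal(unname(prior_moments(prior_spec("binary"))), c(0, 1, 0))
})

test_that("sampled patterns live on the support with the stated statistics", {
  N <- 1e5
  X <- sample_patterns(prior_spec("binary"), P = 2, N = N, seed = 1)
  expect_true(all(X %in% c(-1, 1)))
  expect_lt(abs(mean(X)), 3 / sqrt(2 * N))
  expect_equal(mean(X^2), 1)

  X <- sample_patterns(prior_spec("sparse", 0.3), P = 1, N = N, seed = 2)
  expect_true(all(X %in% c(-1, 0, 1)))
  expect_lt(abs(mean(X != 0) - 0.3), 0.01)

  X <- sample_patterns(prior_spec("low_coding", 0.3), P = 1, N = N, seed = 3)
  expect_true(all(X %in% c(-0.3, 0.7)))
  expect_lt(abs(mean(X^2) - 0.21), 0.01)

  # reproducibility
  expect_identical(sample_patterns(prior_spec("binary"), 3, 50, seed = 9),
                   sample_patterns(prior_spec("binary"), 3, 50, seed = 9))
})

test_that("invalid coding levels are rejected", {
  expect_error(prior_spec("sparse"), "required")
  expect_error(prior_spec("sparse", 0), "must be")
  expect_error(prior_spec("low_coding", 1), "must be")
  expect_error(prior_spec("low_coding", -0.1), "must be")
  expect_silent(prior_spec("sparse", 1))  # sparse(1) degenerates to binary
})

test_that("posterior_mean_cov equals literal brute-force enumeration", {
  set.seed(42)
  for (spec in all_priors()) {
    for (P in 1:3) {
      for (rep in 1:5) {
        R <- matrix(rnorm(P * P), P)
        A <- (R + t(R)) / 2
        b <- rnorm(P)
        got <- posterior_mean_cov(spec, A, b)
        want <- brute_posterior(spec, A, b)
        expect_equal(got$mean, want$mean, tolerance = 1e-12)
        expect_equal(got$cov, want$cov, tolerance = 1e-12)
      }
    }
  }
})

test_that("binary posterior mean is tanh(b), independent of the curvature", {
  expect_equal(posterior_mean_cov(prior_spec("binary"), 0.7, 0.3)$mean,
               tanh(0.3), tolerance = 1e-14)
  set.seed(7)
  for (a in runif(5, -2, 5)) {
    r <- posterior_mean_var_mf(prior_spec("binary"), a, c(-1.2, 0, 2.5))
    expect_equal(r$mean, tanh(c(-1.2, 0, 2.5)), tolerance = 1e-13)
    expect_equal(r$var, 1 - tanh(c(-1.2, 0, 2.5))^2, tolerance = 1e-12)
  }
  # symmetric prior, no field: mean exactly zero
  P <- 4
  A <- diag(P) + 0.3
  expect_equal(posterior_mean_cov(prior_spec("binary"), A, rep(0, P))$mean,
               rep(0, P), tolerance = 1e-14)
})

test_that("sparse scalar threshold matches its closed form", {
  rho <- 0.3
  spec <- prior_spec("sparse", rho)
  closed <- function(a, b)
    rho * exp(-a / 2) * sinh(b) / (1 + rho * (exp(-a / 2) * cosh(b) - 1))
  for (a in c(0, 0.5, 3)) for (b in c(-2, 0.1, 1.5)) {
    expect_equal(posterior_mean_cov(spec, a, b)$mean, closed(a, b),
                 tolerance = 1e-12)
    expect_equal(posterior_mean_var_mf(spec, a, b)$mean, closed(a, b),
                 tolerance = 1e-12)
  }
})

test_that("low-coding scalar threshold matches the two-point closed form", {
  rho <- 0.3
  spec <- prior_spec("low_coding", rho)
  closed <- function(a, b) {
    E <- exp(a * (rho - 0.5) + b)
    rho * (1 - rho) * (E - 1) / ((1 - rho) + rho * E)
  }
  for (a in c(0, 1, 4)) for (b in c(-1, 0, 2)) {
    expect_equal(posterior_mean_cov(spec, a, b)$mean, closed(a, b),
                 tolerance = 1e-12)
  }
  r <- posterior_mean_var_mf(spec, 0, 0)
  expect_equal(r$mean, 0, tolerance = 1e-14)
  expect_equal(r$var, 0.21, tolerance = 1e-14)
})

test_that("mean-field equals the exact threshold at P = 1 and factorises", {
  set.seed(11)
  for (spec in all_priors()) {
    a <- runif(1, 0, 2); b <- rnorm(1)
    ex <- posterior_mean_cov(spec, a, b)
    mf <- posterior_mean_var_mf(spec, a, b)
    expect_equal(mf$mean, ex$mean, tolerance = 1e-13)
    expect_equal(mf$var, as.numeric(ex$cov), tolerance = 1e-13)
  }
})

test_that("sparse prior with rho = 1 reproduces binary outputs", {
  sp1 <- prior_spec("sparse", 1)
  pb <- prior_spec("binary")
  set.seed(5)
  for (rep in 1:5) {
    A <- matrix(rnorm(4), 2); A <- (A + t(A)) / 2
    b <- rnorm(2)
    expect_equal(posterior_mean_cov(sp1, A, b)$mean,
                 posterior_mean_cov(pb, A, b)$mean, tolerance = 1e-13)
  }
  expect_equal(critical_delta(sp1), critical_delta(pb))
})

test_that("posterior means are bounded by the support, variances non-negative", {
  set.seed(23)
  for (spec in all_priors()) {
    tb <- memrec:::prior_table(spec)
    a <- runif(200, -1, 6)
    b <- rnorm(200, sd = 5)
    r <- posterior_mean_var_mf(spec, a, b)
    expect_true(all(r$mean >= min(tb$x) - 1e-12))
    expect_true(all(r$mean <= max(tb$x) + 1e-12))
    expect_true(all(r$var >= 0))
  }
  # extreme fields must not overflow (log-space evaluation)
  r <- posterior_mean_var_mf(prior_spec("low_coding", 0.1), 500, 800)
  expect_true(all(is.finite(c(r$mean, r$var))))
})

test_that("enumeration cap is enforced with a helpful error", {
  expect_error(posterior_mean_cov(prior_spec("sparse", 0.3),
                                  diag(13), rep(0, 13)),
               "posterior_mean_var_mf")
  expect_error(posterior_mean_cov(prior_spec("binary"),
                                  diag(21), rep(0, 21)), "P <= 20")
})

test_that("skewness criterion identifies the hard-phase coding levels", {
  expect_false(hard_phase_criterion(prior_spec("binary"))$skewed)
  expect_false(hard_phase_criterion(prior_spec("sparse", 0.05))$skewed)
  # low coding level: skewed (hard) below the critical rho, not above
  expect_true(hard_phase_criterion(prior_spec("low_coding", 0.1))$skewed)
  expect_false(hard_phase_criterion(prior_spec("low_coding", 0.3))$skewed)
  hp <- hard_phase_criterion(prior_spec("low_coding", 0.3))
  expect_equal(hp$rho_critical, 0.5 - 1 / sqrt(12), tolerance = 1e-9)
  # the root satisfies the moment equality
  mm <- prior_moments(prior_spec("low_coding", hp$rho_critical))
  expect_equal(mm[["m3"]]^2, 2 * mm[["m2"]]^3, tolerance = 1e-10)
})
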