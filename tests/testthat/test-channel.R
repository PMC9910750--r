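test_that("connection probability follows the erfc law", {
  expect_equal(p_connect(channel_spec(0, 1)), 0.5)
  expect_equal(p_connect(channel_spec(0, 0.01)), 0.5)
  # tau/(sqrt(2) nu) = 1  ->  erfc(1)/2
  expect_equal(p_connect(channel_spec(sqrt(2), 1)),
               0.5 * 2 * pnorm(sqrt(2), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(p_connect(channel_spec(sqrt(2), 1)), 0.0786496,
               tolerance = 1e-6)
  expect_lt(p_connect(channel_spec(50, 1)), 1e-100)
})

test_that("output channel is a normalised atom + truncated Gaussian", {
  ch <- channel_spec(1, 1)
  # atom at J = 0 when signal sits at threshold: probability 1/2
  expect_equal(log_output_density(0, 1, ch), log(0.5), tolerance = 1e-12)
  # generative check: P(J=0 | w=0) = Phi(tau/nu)
  expect_equal(exp(log_output_density(0, 0, ch)), pnorm(1), tolerance = 1e-12)
  # atom + integral of the positive density = 1 for random (w, tau, nu)
  set.seed(4)
  for (rep in 1:5) {
    ch <- channel_spec(runif(1, 0, 2), runif(1, 0.2, 3))
    w <- rnorm(1)
    atom <- exp(log_output_density(0, w, ch))
    dens <- stats::integrate(function(J) exp(log_output_density(J, w, ch)),
                             0, Inf, rel.tol = 1e-10)$value
    expect_equal(atom + dens, 1, tolerance = 1e-7)
  }
  expect_error(log_output_density(-0.5, 0, ch), "non-negative")
})

test_that("Fisher score matches the analytic branches and finite differences", {
  ch <- channel_spec(0, 1)
  J <- matrix(c(0, 0.5, 0.5, 0), 2)
  S <- fisher_score(J, ch)
  expect_equal(S[1, 2], 0.5)                       # (J + tau)/nu^2
  ch2 <- channel_spec(0.7, 1.3)
  J <- matrix(0, 2, 2)
  S <- fisher_score(J, ch2)
  expect_equal(S[1, 2], memrec:::score_at_zero(ch2))
  expect_equal(memrec:::score_at_zero(channel_spec(0, 1)), -sqrt(2 / pi),
               tolerance = 1e-12)
  # finite-difference oracle on the log channel at w = 0
  set.seed(8)
  for (rep in 1:5) {
    ch <- channel_spec(runif(1, 0, 1.5), runif(1, 0.3, 2))
    Jv <- c(0, runif(3, 0.01, 3))
    analytic <- ifelse(Jv > 0, (Jv + ch$tau) / ch$nu^2,
                       memrec:::score_at_zero(ch))
    expect_equal(analytic, fd_score(Jv, ch), tolerance = 1e-5)
  }
})

test_that("fisher_score validates input and preserves symmetry", {
  ch <- channel_spec(0.5, 1)
  set.seed(2)
  J <- matrix(rexp(25), 5); J <- (J + t(J)) / 2; diag(J) <- 0
  J[J < 0.8] <- 0
  S <- fisher_score(J, ch)
  expect_identical(S, t(S))
  expect_equal(diag(S), rep(0, 5))
  expect_error(fisher_score(matrix(rnorm(25), 5), ch))
  expect_error(fisher_score(-J, ch), "non-negative")
})

test_that("effective noise: closed form, quadrature, and known values agree", {
  # tau = 0: 1/Delta = 1/2 + 1/pi
  expect_equal(effective_noise(channel_spec(0, 1)), 1 / (0.5 + 1 / pi),
               tolerance = 1e-12)
  # scaling Delta ~ nu^2 at tau = 0
  expect_equal(effective_noise(channel_spec(0, 2)),
               4 * effective_noise(channel_spec(0, 1)), tolerance = 1e-12)
  # quadrature route agrees with the analytic reduction
  for (tau in c(0, 0.3, 1, 2)) for (nu in c(0.3, 1, 2.5)) {
    ch <- channel_spec(tau, nu)
    expect_equal(effective_noise(ch, "quadrature"), effective_noise(ch),
                 tolerance = 1e-8)
  }
})

test_that("the score has zero mean under the null channel", {
  for (tau in c(0, 0.5, 1.5)) {
    ch <- channel_spec(tau, 0.8)
    s0 <- memrec:::score_at_zero(ch)
    atom <- pnorm(tau / ch$nu) * s0
    tail <- stats::integrate(function(J)
      exp(log_output_density(J, 0, ch)) * (J + tau) / ch$nu^2,
      0, Inf, rel.tol = 1e-12)$value
    expect_equal(atom + tail, 0, tolerance = 1e-9)
  }
})

test_that("nu can be solved back from a target effective noise", {
  # round trip at tau = 0
  for (d in c(0.05, 1, 20)) {
    nu <- solve_nu_for_delta(d, 0)
    expect_equal(effective_noise(channel_spec(0, nu)), d, tolerance = 1e-10)
  }
  expect_equal(solve_nu_for_delta(1.2220310, 0), 1, tolerance = 1e-4)
  # tau > 0: every root reproduces the target; count matches a dense scan
  tau <- 0.5
  for (d in c(0.5, 2)) {
    roots <- solve_nu_for_delta(d, tau)
    for (nu in roots)
      expect_equal(effective_noise(channel_spec(tau, nu)), d,
                   tolerance = 1e-8)
    grid <- exp(seq(log(1e-4), log(1e3), length.out = 4001))
    vals <- vapply(grid, function(nu)
      effective_noise(channel_spec(tau, nu)) - d, numeric(1))
    n_flips <- sum(diff(sign(vals)) != 0)
    expect_equal(length(roots), n_flips)
  }
  # stochastic resonance: two branches at small Delta, tau > 0
  expect_length(solve_nu_for_delta(0.5, 0.5), 2)
  expect_error(solve_nu_for_delta(1e-9, 2), "unreachable")
})

test_that("critical noise vs connection probability behaves as expected", {
  pb <- prior_spec("binary")
  res <- critical_nu_of_pc(0.3, pb)
  # both defining equations hold
  expect_equal(p_connect(channel_spec(res$tau, res$nu)), 0.3,
               tolerance = 1e-8)
  expect_equal(effective_noise(channel_spec(res$tau, res$nu)),
               critical_delta(pb), tolerance = 1e-8)
  # monotone increasing in p_C, vanishing as p_C -> 0
  pcs <- c(0.001, 0.01, 0.1, 0.3, 0.5)
  nus <- vapply(pcs, function(p) critical_nu_of_pc(p, pb)$nu, numeric(1))
  expect_true(all(diff(nus) > 0))
  expect_lt(critical_nu_of_pc(1e-8, pb)$nu, 0.01)
})
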