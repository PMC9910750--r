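#' Configuration for scripted experiments
#'
#' Bundles the knobs shared by the figure-style experiments. Effective
#' noise levels are specified either absolutely (\code{deltas}) or as
#' fractions of the prior's critical noise (\code{delta_fractions}); the
#' channel noise sd is derived for each by inverting
#' \code{\link{effective_noise}} at the given threshold.
#'
#' @param prior a \code{\link{prior_spec}}.
#' @param tau channel threshold (default 0).
#' @param deltas absolute effective-noise levels (optional).
#' @param delta_fractions effective-noise levels as fractions of
#'   \code{\link{critical_delta}(prior)} (optional).
#' @param N network size (or vector of sizes for the scaling experiment).
#' @param P number of patterns (default 1).
#' @param n_runs independent seeded runs per condition (default 5; the
#'   capacity experiment uses 20).
#' @param success_fraction a capacity run succeeds when its aligned
#'   per-pattern error is below this fraction of the trivial error
#'   \eqn{m_2} (default 0.2).
#' @param mode message-passing mode, \code{"exact"} or \code{"meanfield"}.
#' @param seed base integer seed; all run seeds are derived from it.
#' @param p_min first P of the unit-step capacity scan; if NULL, a coarse
#'   doubling phase locates the transition region first.
#' @param fail_streak stop the capacity scan after this many consecutive
#'   majority-failure values of P (default 5).
#' @param max_iter,tol,damping,block_size passed to
#'   \code{\link{amp_options}} (the default block size of 8 trades nothing
#'   measurable for BLAS-level speed in the capacity scans).
#' @return an object of class \code{experiment_config} (a list; the full
#'   configuration is attached to every result for reproducibility).
#' @export
experiment_config <- function(prior, tau = 0, deltas = NULL,
                              delta_fractions = NULL, N, P = 1L,
                              n_runs = 5L, success_fraction = 0.2,
                              mode = c("exact", "meanfield"), seed = 1L,
                              p_min = NULL, fail_streak = 5L,
                              max_iter = 200L, tol = 1e-8, damping = 0,
                              block_size = 8L) {
  stopifnot(inherits(prior, "prior_spec"))
  mode <- match.arg(mode)
  if (is.null(deltas) && !is.null(delta_fractions))
    deltas <- delta_fractions * critical_delta(prior)
  if (!is.null(deltas) && is.null(delta_fractions))
    delta_fractions <- deltas / critical_delta(prior)
  structure(list(prior = prior, tau = tau, deltas = deltas,
                 delta_fractions = delta_fractions, N = N, P = as.integer(P),
                 n_runs = as.integer(n_runs),
                 success_fraction = success_fraction, mode = mode,
                 seed = as.integer(seed), p_min = p_min,
                 fail_streak = as.integer(fail_streak),
                 max_iter = as.integer(max_iter), tol = tol,
                 damping = damping, block_size = as.integer(block_size)),
            class = "experiment_config")
}

run_seed <- function(cfg, P, r) cfg$seed + 7919L * as.integer(P) + as.integer(r)

#' Reconstruction error versus effective noise
#'
#' For each requested effective-noise level: solves for the channel noise sd
#' at the configured threshold, generates \code{n_runs} seeded instances,
#' and records the reconstruction error of the requested algorithms --
#' message passing from random and/or informed initialisation, PCA on the
#' connectivity and on the Fisher score matrix, and the (deterministic,
#' seed-independent) state-evolution predictions from both initialisations.
#'
#' @param cfg an \code{\link{experiment_config}} with \code{deltas} or
#'   \code{delta_fractions} set.
#' @param algorithms subset of \code{c("amp_random", "amp_informed",
#'   "pca_j", "pca_s", "se_random", "se_informed")}.
#' @return data.frame with one row per (delta, algorithm, seed): columns
#'   \code{delta}, \code{delta_frac}, \code{nu}, \code{algorithm},
#'   \code{seed}, \code{mse_raw} (total, aligned), \code{mse_norm}
#'   (normalized per-pattern), \code{iterations}, \code{converged}. SE rows
#'   carry \code{seed = NA}. The configuration is attached as attribute
#'   \code{"config"}. Unreachable noise levels are skipped with a warning.
#' @export
mse_vs_delta <- function(cfg,
                         algorithms = c("amp_random", "amp_informed",
                                        "pca_j", "pca_s",
                                        "se_random", "se_informed")) {
  stopifnot(inherits(cfg, "experiment_config"), !is.null(cfg$deltas))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  prior <- cfg$prior
  m2 <- prior_moments(prior)[["m2"]]
  rows <- list()
  add <- function(delta, frac, nu, algorithm, seed, mse_raw, iterations = NA,
                  converged = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      delta = delta, delta_frac = frac, nu = nu, algorithm = algorithm,
      seed = seed, mse_raw = mse_raw,
      mse_norm = mse_raw / (cfg$P * m2),
      iterations = iterations, converged = converged)

  for (d in seq_along(cfg$deltas)) {
    delta <- cfg$deltas[d]
    frac <- cfg$delta_fractions[d]
    nu <- tryCatch(solve_nu_for_delta(delta, cfg$tau)[1],
                   error = function(e) NA_real_)
    if (is.na(nu)) {
      warning("skipping unreachable Delta = ", delta, " at tau = ", cfg$tau)
      next
    }
    ch <- channel_spec(cfg$tau, nu)
    for (init in c("random", "informed")) {
      alg <- paste0("se_", init)
      if (alg %in% algorithms) {
        se <- iterate_se(delta, prior, init = init)
        add(delta, frac, nu, alg, NA_integer_, se$mse_raw * cfg$P)
      }
    }
    need_inst <- any(c("amp_random", "amp_informed", "pca_j", "pca_s") %in%
                       algorithms)
    if (!need_inst) next
    for (r in seq_len(cfg$n_runs)) {
      seed <- run_seed(cfg, d, r)
      inst <- generate_instance(prior, ch, cfg$N, cfg$P, seed = seed,
                                keep_hebbian = FALSE)
      S <- NULL
      if (any(c("amp_random", "amp_informed", "pca_s") %in% algorithms))
        S <- fisher_score(inst$connectivity, ch)
      for (init in c("random", "informed")) {
        alg <- paste0("amp_", init)
        if (!alg %in% algorithms) next
        opt <- amp_options(mode = cfg$mode, init = init,
                           damping = cfg$damping, max_iter = cfg$max_iter,
                           tol = cfg$tol, seed = seed + 499979L)
        res <- run_amp(S, prior, P = cfg$P, options = opt,
                       ground_truth = inst$patterns)
        add(delta, frac, nu, alg, seed,
            reconstruction_error(res$estimate, inst$patterns, prior = prior),
            res$iterations, res$converged)
      }
      if ("pca_j" %in% algorithms) {
        pc <- pca_reconstruct(inst$connectivity, cfg$P)
        add(delta, frac, nu, "pca_j", seed,
            reconstruction_error(pc$estimate, inst$patterns, prior = prior))
      }
      if ("pca_s" %in% algorithms) {
        pc <- pca_reconstruct(S, cfg$P)
        add(delta, frac, nu, "pca_s", seed,
            reconstruction_error(pc$estimate, inst$patterns, prior = prior))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(delta = numeric(0), delta_frac = numeric(0),
               nu = numeric(0), algorithm = character(0),
               seed = integer(0), mse_raw = numeric(0),
               mse_norm = numeric(0), iterations = integer(0),
               converged = logical(0))
  attr(out, "config") <- cfg
  out
}

# One capacity cell: mean-field reconstructions at (N, P); returns the
# number of runs whose aligned per-pattern error beats the threshold. The
# cell stops as soon as the majority outcome is decided (each run is
# deterministic given its seed, so this cannot change the decision).
pcrit_cell <- function(cfg, N, P, ch) {
  m2 <- prior_moments(cfg$prior)[["m2"]]
  thr <- cfg$success_fraction * m2
  maj <- ceiling(cfg$n_runs / 2)
  succ <- 0L
  fail <- 0L
  used <- 0L
  for (r in seq_len(cfg$n_runs)) {
    used <- used + 1L
    seed <- run_seed(cfg, P, r) + N
    inst <- generate_instance(cfg$prior, ch, N, P, seed = seed,
                              keep_hebbian = FALSE)
    S <- fisher_score(inst$connectivity, ch)
    # the initialisation seed must differ from the instance seed, or the
    # "random" prior draw would reproduce the planted patterns themselves
    opt <- amp_options(mode = "meanfield", init = "random",
                       damping = cfg$damping, max_iter = cfg$max_iter,
                       tol = cfg$tol, seed = seed + 499979L,
                       block_size = cfg$block_size)
    res <- run_amp(S, cfg$prior, P = P, options = opt)
    mse_pp <- reconstruction_error(res$estimate, inst$patterns,
                                   prior = cfg$prior) / P
    if (mse_pp < thr) succ <- succ + 1L else fail <- fail + 1L
    if (succ >= maj || fail > cfg$n_runs - maj) break
  }
  list(successes = succ, runs_used = used)
}

#' Capacity scan: critical number of reconstructible patterns
#'
#' For increasing P, runs \code{n_runs} mean-field message-passing
#' reconstructions on fresh instances at effective noise
#' \code{delta_fractions[1] * critical_delta(prior)} and counts the runs
#' whose aligned per-pattern error falls below
#' \code{success_fraction * m2} (20\% of the trivial error by default).
#' P_crit is the largest P at which at least half the runs succeed. The
#' scan proceeds in unit steps from \code{p_min} (located by coarse
#' doubling when not given) and stops after \code{fail_streak} consecutive
#' majority-failure values of P past the last success. Errors are strongly
#' bimodal near the transition -- runs either track the single-pattern
#' state-evolution error or collapse to chance -- which is what makes the
#' majority criterion stable.
#'
#' @param cfg an \code{\link{experiment_config}} (set
#'   \code{delta_fractions} -- the first entry is used -- and
#'   \code{n_runs}; \code{success_fraction} defaults to 0.2).
#' @param N network size (defaults to \code{cfg$N[1]}).
#' @return list with \code{P_crit}, \code{counts} (data.frame: \code{P},
#'   \code{successes}, \code{runs_used} -- runs actually executed before
#'   the majority outcome was decided -- and \code{n_runs}), \code{N},
#'   \code{delta}, \code{nu}; config attached as attribute \code{"config"}.
#' @export
pcrit_scan <- function(cfg, N = cfg$N[1]) {
  stopifnot(inherits(cfg, "experiment_config"),
            length(cfg$delta_fractions) >= 1)
  delta <- cfg$delta_fractions[1] * critical_delta(cfg$prior)
  nu <- solve_nu_for_delta(delta, cfg$tau)[1]
  ch <- channel_spec(cfg$tau, nu)
  maj <- ceiling(cfg$n_runs / 2)
  counts <- data.frame(P = integer(0), successes = integer(0),
                       runs_used = integer(0))
  record <- function(P, cell)
    counts <<- rbind(counts,
                     data.frame(P = P, successes = cell$successes,
                                runs_used = cell$runs_used))

  p_start <- cfg$p_min
  if (is.null(p_start)) {
    # coarse doubling to bracket the transition
    P <- 1L
    last_ok <- 0L
    repeat {
      s <- pcrit_cell(cfg, N, P, ch)
      record(P, s)
      if (s$successes < maj || P > 4096L) break
      last_ok <- P
      P <- 2L * P
    }
    p_start <- max(last_ok, 1L)
  }

  last_success <- 0L
  streak <- 0L
  P <- as.integer(p_start)
  while (streak < cfg$fail_streak) {
    s <- if (P %in% counts$P) counts$successes[match(P, counts$P)] else {
      cell <- pcrit_cell(cfg, N, P, ch)
      record(P, cell)
      cell$successes
    }
    if (s >= maj) { last_success <- P; streak <- 0L } else
      streak <- streak + 1L
    P <- P + 1L
  }
  counts <- counts[order(counts$P), ]
  counts$n_runs <- cfg$n_runs
  rownames(counts) <- NULL
  out <- list(P_crit = last_success, counts = counts, N = N, delta = delta,
              nu = nu)
  attr(out, "config") <- cfg
  out
}

#' Power-law fit of capacity versus network size
#'
#' Least-squares fit of \eqn{\log P_{crit}} against \eqn{\log N}.
#'
#' @param N vector of network sizes (>= 3 values).
#' @param P_crit vector of critical pattern counts (all > 0).
#' @return list with \code{gamma} (the exponent), \code{se} (its standard
#'   error), \code{log_c} (intercept), \code{fit} (the \code{lm} object).
#' @export
fit_power_law <- function(N, P_crit) {
  stopifnot(length(N) >= 3, length(N) == length(P_crit))
  if (any(P_crit <= 0)) stop("degenerate fit: some P_crit is 0")
  fit <- stats::lm(log(P_crit) ~ log(N))
  # exact synthetic inputs give a perfect fit; summary.lm warns about it
  co <- suppressWarnings(summary(fit))$coefficients
  list(gamma = unname(co[2, 1]), se = unname(co[2, 2]),
       log_c = unname(co[1, 1]), fit = fit)
}

#' Scaling exponent of the reconstruction capacity
#'
#' Runs \code{\link{pcrit_scan}} at each network size in \code{cfg$N} and
#' fits \eqn{P_{crit} \sim N^\gamma}. The exponent is sensitive to the
#' noise level (higher noise inflates run-to-run fluctuations near the
#' transition); the configured default of 20\% of critical keeps the
#' success/failure separation sharp.
#'
#' @param cfg an \code{\link{experiment_config}} with \code{N} a vector of
#'   at least 3 sizes.
#' @return list with \code{gamma}, \code{se}, \code{table} (data.frame
#'   \code{N}, \code{P_crit}), \code{scans} (the per-N scan results);
#'   config attached as attribute \code{"config"}.
#' @export
pcrit_scaling <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"), length(cfg$N) >= 3)
  scans <- lapply(cfg$N, function(n) pcrit_scan(cfg, N = n))
  tab <- data.frame(N = cfg$N,
                    P_crit = vapply(scans, `[[`, integer(1), "P_crit"))
  fit <- fit_power_law(tab$N, tab$P_crit)
  out <- list(gamma = fit$gamma, se = fit$se, table = tab, scans = scans)
  attr(out, "config") <- cfg
  out
}
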