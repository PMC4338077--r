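#' @useDynLib quorumsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fitness lookup table for the simulator: tbl[u, v, k] = Omega of a
# u-individual when the population holds k u's and Z-k v's (k = 1..Z-1).
# Both orientations of each pair are filled from one profile computation.
build_omega_table <- function(space, params) {
  n <- nrow(space)
  Z <- params$Z
  gs <- lapply(space$label, parse_strategy)
  tbl <- array(0, dim = c(n, n, Z - 1L))
  k <- seq_len(Z - 1L)
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      pr <- pair_payoffs(gs[[a]], gs[[b]], params)
      om <- pair_fitness_profiles(pr, k, params)
      tbl[a, b, ] <- om$omega_U           # k copies of a among b's
      tbl[b, a, ] <- rev(om$omega_V)      # k copies of b among a's
    }
  }
  tbl
}

#' Stochastic birth-death simulation with mutation
#'
#' Explicit agent-based realization of the evolutionary process: at each step
#' two distinct individuals are drawn; the first imitates the second with the
#' Fermi probability given their current fitnesses, and then mutates to a
#' uniformly random strategy of the space with probability \code{mu}.
#' Fitness is the exact hypergeometric expectation of the group payoff
#' whenever at most two strategies are present (always, in the small-mutation
#' regime); if three or more coexist, or under
#' \code{fitness_mode = "sampled_groups"}, it is averaged over
#' \code{n_group_samples} randomly assembled groups of size \code{N}, with
#' majority-signal ties resolved by actual coin flips. This simulator shares
#' no code path with the embedded-chain analytics and serves as their
#' independent check, as well as the only route to \eqn{\mu > 0} dynamics
#' beyond the small-mutation limit.
#'
#' @param space a [strategy_space].
#' @param params a [game_params] object.
#' @param mu per-update-step mutation probability (applied to the focal
#'   individual; the replacement strategy is uniform over the space,
#'   including the current one).
#' @param steps total number of update steps.
#' @param burn_in steps discarded before averaging.
#' @param seed RNG seed; identical inputs give bit-identical results.
#' @param init initial population: a single strategy label (monomorphic
#'   start) or an integer vector of per-strategy counts summing to \code{Z}.
#' @param fitness_mode \code{"exact_bimorphic"} (default) or
#'   \code{"sampled_groups"}.
#' @param n_group_samples groups sampled per fitness evaluation in sampled
#'   mode.
#' @param thin if positive, record strategy counts every \code{thin} steps.
#' @return A list of class \code{simulation_result}:
#'   \code{time_averaged_frequencies} and \code{monomorphic_occupancy}
#'   (named per strategy; occupancy is the fraction of retained time spent
#'   monomorphic in that strategy), \code{monomorphic_fraction},
#'   \code{retained_steps}, \code{final_state}, the configuration, and
#'   optionally \code{trajectory} (matrix: step, one count column per
#'   strategy).
#' @export
run_simulation <- function(space, params, mu, steps, burn_in = 0,
                           seed = NULL, init = NULL,
                           fitness_mode = c("exact_bimorphic", "sampled_groups"),
                           n_group_samples = 100L, thin = 0) {
  fitness_mode <- match.arg(fitness_mode)
  stopifnot(mu >= 0, mu <= 1, steps > 0, burn_in >= 0, burn_in < steps,
            n_group_samples >= 1)
  n <- nrow(space)
  Z <- params$Z
  if (is.null(init)) init <- space$label[1L]
  if (is.character(init)) {
    idx <- match(init, space$label)
    if (is.na(idx)) stop("init strategy not in space: ", init, call. = FALSE)
    state0 <- rep.int(idx - 1L, Z)
  } else {
    stopifnot(length(init) == n, sum(init) == Z, all(init >= 0))
    state0 <- rep.int(seq_len(n) - 1L, times = init)
  }
  if (!is.null(seed)) set.seed(seed)
  geno <- as.matrix(space[, c("sigma_alpha", "sigma_beta", "a0", "a1")])
  storage.mode(geno) <- "integer"
  tbl <- if (fitness_mode == "exact_bimorphic") build_omega_table(space, params)
         else array(0, dim = c(n, n, Z - 1L))
  res <- cpp_run_simulation(geno, as.numeric(tbl), Z, params$N, params$M,
                            params$c, params$c_S, params$F, params$lambda,
                            params$gamma, params$shirker == "loner",
                            mu, steps, burn_in, state0,
                            as.integer(n_group_samples), thin,
                            fitness_mode == "exact_bimorphic")
  names(res$frequencies) <- space$label
  names(res)[names(res) == "frequencies"] <- "time_averaged_frequencies"
  names(res$monomorphic_occupancy) <- space$label
  res$final_state <- res$final_state + 1L
  res$config <- list(params = params, mu = mu, steps = steps,
                     burn_in = burn_in, seed = seed,
                     fitness_mode = fitness_mode,
                     n_group_samples = n_group_samples)
  if (!is.null(res$trajectory))
    colnames(res$trajectory) <- c("step", space$label)
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Birth-death simulation: %g retained steps, monomorphic %.1f%% of the time\n",
              x$retained_steps, 100 * x$monomorphic_fraction))
  top <- sort(x$time_averaged_frequencies, decreasing = TRUE)[1:4]
  cat("Top strategies by time-averaged frequency:\n")
  print(round(top, 4))
  invisible(x)
}

#' Empirical fixation probability of a single mutant
#'
#' Monte Carlo estimate of \eqn{\rho_{V,U}}: each trial starts with one
#' \code{U} mutant among \code{Z - 1} \code{V} residents and runs the
#' mutation-free birth-death process to absorption. Since only the identity
#' of the absorbing state matters, the embedded jump chain is simulated
#' (steps that change the mutant count, with up-probability
#' \eqn{T^+/(T^+ + T^-)}), which has the same absorption law as the lazy
#' walk but needs far fewer draws.
#'
#' @param U invading mutant genotype (object or label).
#' @param V resident genotype.
#' @param params a [game_params] object.
#' @param n_trials number of independent absorption runs.
#' @param seed RNG seed.
#' @return A list with \code{p_hat} (fixation fraction), \code{se} (binomial
#'   standard error), \code{n_trials}, \code{n_fixed}.
#' @export
estimate_fixation <- function(U, V, params, n_trials, seed = NULL) {
  stopifnot(n_trials >= 1)
  U <- as_strategy(U); V <- as_strategy(V)
  if (U$label == V$label)
    stop("invader and resident must be distinct strategies", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Z <- params$Z
  d <- fitness_difference_profile(U, V, params)
  # P(k -> k+1 | a move happens) = T+/(T+ + T-); the prefactors cancel and
  # the Fermi terms sum to 1, so this is just the Fermi probability itself
  p_up <- fermi_probability(d, params$gamma)
  n_fixed <- 0L
  for (trial in seq_len(n_trials)) {
    k <- 1L
    while (k > 0L && k < Z) {
      k <- if (stats::runif(1) < p_up[k]) k + 1L else k - 1L
    }
    if (k == Z) n_fixed <- n_fixed + 1L
  }
  p_hat <- n_fixed / n_trials
  list(p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_trials),
       n_trials = as.integer(n_trials), n_fixed = n_fixed)
}
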