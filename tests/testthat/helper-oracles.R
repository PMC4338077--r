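# Shared fixtures and independent oracles, built in code.

fig1_params <- function(...) {
  args <- list(Z = 100, N = 9, M = 5, c = 0.5, c_S = 0.2, F = 10,
               lambda = 0.5, gamma = 5)
  args[names(list(...))] <- list(...)
  do.call(game_params, args)
}

fig2_params <- function(...) {
  args <- list(Z = 100, N = 9, M = 5, c = 0.3, c_S = 0.06, F = 10,
               lambda = 0.8, gamma = 0.5)
  args[names(list(...))] <- list(...)
  do.call(game_params, args)
}

# Brute-force bimorphic fitness: enumerate every co-player subset of the
# population (distinct individuals), average the focal's expected payoff.
enumerate_fitness <- function(U, V, k, params) {
  N <- params$N; Z <- params$Z
  one_side <- function(focal, other, n_same_pool, n_other_pool, from_U) {
    pool <- c(rep(TRUE, n_same_pool), rep(FALSE, n_other_pool))
    combs <- utils::combn(length(pool), N - 1L)
    vals <- apply(combs, 2L, function(idx) {
      n_same_co <- sum(pool[idx])
      expected_group_payoff(focal, other, n_same_co + 1L, params)
    })
    mean(vals)
  }
  list(omega_U = one_side(U, V, k - 1L, Z - k, TRUE),
       omega_V = one_side(V, U, Z - k - 1L, k, FALSE))
}

# First-step-analysis absorption probability of the explicit (Z+1)-state
# birth-death chain: solve the tridiagonal linear system for fixation from
# a single mutant.
absorption_oracle <- function(U, V, params) {
  Z <- params$Z
  tp <- tm <- numeric(Z - 1L)
  for (k in seq_len(Z - 1L)) {
    r <- transition_rates(U, V, k, params)
    tp[k] <- r$t_plus; tm[k] <- r$t_minus
  }
  A <- matrix(0, Z - 1L, Z - 1L)
  b <- numeric(Z - 1L)
  for (k in seq_len(Z - 1L)) {
    A[k, k] <- tp[k] + tm[k]
    if (k > 1L) A[k, k - 1L] <- -tm[k]
    if (k < Z - 1L) A[k, k + 1L] <- -tp[k]
  }
  b[Z - 1L] <- tp[Z - 1L]
  solve(A, b)[1L]
}

# permutation of space indices induced by a per-strategy relabeling function
strategy_permutation <- function(space, f) {
  match(vapply(space$label, function(l) f(l)$label, ""), space$label)
}
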