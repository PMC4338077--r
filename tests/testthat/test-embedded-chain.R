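test_that("the embedded chain is row-stochastic with the prescribed normalization", {
  s <- strategy_space()
  p <- fig2_params(Z = 30)
  ch <- embedded_chain(s, p)
  expect_equal(ch$eta, 1 / 15)
  expect_equal(unname(rowSums(ch$T)), rep(1, 16), tolerance = 1e-10)
  expect_true(all(ch$T >= 0))
  off <- ch$T; diag(off) <- NA
  expect_equal(off[!is.na(off)], ch$eta * ch$rho[!is.na(ch$rho)])
})

test_that("the neutral chain is symmetric with a uniform stationary distribution", {
  s <- strategy_space()
  p <- fig1_params(gamma = 0, Z = 50)
  ch <- embedded_chain(s, p)
  off <- ch$T; diag(off) <- NA
  expect_equal(unique(off[!is.na(off)]), ch$eta / 50)
  pi <- stationary_distribution(ch)
  expect_equal(unname(pi), rep(1 / 16, 16), tolerance = 1e-10)
  expect_equal(unname(as.vector(pi %*% ch$T)), unname(pi), tolerance = 1e-12)
})

test_that("a chain with two closed classes is rejected with their names", {
  s <- strategy_space(reduced = TRUE)
  p <- fig2_params(Z = 20)
  n <- nrow(s)
  rho <- matrix(0, n, n, dimnames = list(s$label, s$label))
  diag(rho) <- NA
  # two internally-connected blocks with no cross flow
  rho[1:4, 1:4][!is.na(rho[1:4, 1:4])] <- 0.05
  rho[5:8, 5:8][!is.na(rho[5:8, 5:8])] <- 0.05
  ch <- embedded_chain(s, p, rho = rho)
  expect_error(stationary_distribution(ch), "closed communicating classes")
})

test_that("ERS membership requires strictly sub-neutral invasion by every mutant", {
  s <- strategy_space()
  p0 <- fig1_params(gamma = 0, Z = 40)
  rho0 <- fixation_matrix(s, p0)
  expect_length(ers_set(s, p0, rho0), 0)                       # all exactly 1/Z
  expect_length(stability_set(s, p0, "counter_invasion", rho = rho0), 16)
  p <- fig1_params(Z = 60)
  rho <- fixation_matrix(s, p)
  ers <- ers_set(s, p, rho)
  expect_true("(10|01)" %in% ers)
  # behaviorally identical mutants hold every silent-shirker strategy at 1/Z
  expect_false("(00|00)" %in% ers)
  # the fitness-augmented criterion can only shrink the set
  expect_true(all(stability_set(s, p, "ers_plus_fitness", rho = rho) %in% ers))
  expect_error(stability_set(s, p, "nonsense"), "arg")
})

test_that("invasion graph edges are the super-neutral transitions and sinks contain every ERS", {
  s <- strategy_space()
  p <- fig2_params(Z = 40)
  rho <- fixation_matrix(s, p)
  g <- invasion_graph(s, p, rho)
  thr <- 1 / p$Z
  for (i in seq_len(nrow(g$edges)))
    expect_gt(rho[g$edges$from[i], g$edges$to[i]], thr)
  n_above <- sum(rho > thr, na.rm = TRUE)
  expect_equal(nrow(g$edges), n_above)
  expect_true(all(ers_set(s, p, rho) %in% graph_sinks(g)))
  # neutral chain: no edge beats neutrality
  p0 <- fig1_params(gamma = 0, Z = 40)
  g0 <- invasion_graph(s, p0)
  expect_equal(nrow(g0$edges), 0L)
  expect_setequal(graph_sinks(g0), s$label)
})

test_that("restricting the chain reuses fixation probabilities and renormalizes", {
  s <- strategy_space()
  p <- fig2_params(Z = 30)
  ch <- embedded_chain(s, p)
  # two-state restriction has the closed-form stationary pair
  A <- "(10|01)"; B <- "(00|00)"
  ch2 <- restrict_chain(ch, c(A, B))
  expect_equal(ch2$eta, 1)
  pi2 <- stationary_distribution(ch2)
  rAB <- ch$rho[A, B]; rBA <- ch$rho[B, A]
  expect_equal(unname(pi2[A]), rBA / (rAB + rBA), tolerance = 1e-10)
  expect_equal(unname(pi2[B]), rAB / (rAB + rBA), tolerance = 1e-10)
  # restriction to the full label set is the identity
  chall <- restrict_chain(ch, s$label)
  expect_equal(chall$T, ch$T)
  expect_error(restrict_chain(ch, c(A, "(99|99)")), "unknown strategy")
  expect_error(restrict_chain(ch, A), "at least two")
})

test_that("stationary mass is invariant under the symmetries of the game", {
  s <- strategy_space()
  # costless signals: relabeling the two signals everywhere changes nothing
  p <- fig1_params(c_S = 0, Z = 50)
  pi <- stationary_distribution(embedded_chain(s, p))
  perm <- strategy_permutation(s, signal_flip)
  expect_equal(unname(pi), unname(pi[perm]), tolerance = 1e-8)
  # lambda = 1: the beta-state signal bit is never expressed
  p1 <- fig1_params(lambda = 1, Z = 50)
  pi1 <- stationary_distribution(embedded_chain(s, p1))
  flip_b <- function(l) {
    g <- as_strategy(l)
    as_strategy(list(sigma_alpha = g$sigma_alpha, sigma_beta = 1 - g$sigma_beta,
                     a0 = g$a0, a1 = g$a1))
  }
  expect_equal(unname(pi1), unname(pi1[strategy_permutation(s, flip_b)]),
               tolerance = 1e-8)
  # lambda = 0: the alpha-state signal bit is never expressed
  p0 <- fig1_params(lambda = 0, Z = 50)
  pi0 <- stationary_distribution(embedded_chain(s, p0))
  flip_a <- function(l) {
    g <- as_strategy(l)
    as_strategy(list(sigma_alpha = 1 - g$sigma_alpha, sigma_beta = g$sigma_beta,
                     a0 = g$a0, a1 = g$a1))
  }
  expect_equal(unname(pi0), unname(pi0[strategy_permutation(s, flip_a)]),
               tolerance = 1e-8)
})
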