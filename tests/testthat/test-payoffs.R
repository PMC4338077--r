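test_that("majority signal follows the strict-majority rule with ties only at even N", {
  expect_identical(majority_signal(5, 9), "1")
  expect_identical(majority_signal(0, 9), "0")
  expect_identical(majority_signal(4, 9), "0")
  expect_identical(majority_signal(9, 18), "tie")
  expect_error(majority_signal(10, 9), "\\[0, N\\]")
  expect_error(majority_signal(-1, 9), "\\[0, N\\]")
})

test_that("threshold public goods payoffs match direct evaluation", {
  p <- fig1_params()
  # defector in a group of 5 cooperators at the threshold: F k c / N
  expect_equal(base_payoff(FALSE, 5, "alpha", p), 10 * 5 * 0.5 / 9)
  # cooperator against loners at the threshold: F c - c
  pl <- fig1_params(shirker = "loner")
  expect_equal(base_payoff(TRUE, 5, "alpha", pl), 10 * 0.5 - 0.5)
  # below threshold nothing is produced
  expect_equal(base_payoff(FALSE, 4, "alpha", p), 0)
  expect_equal(base_payoff(TRUE, 4, "alpha", p), -0.5)
  # under beta the benefit factor is 0 in every variant
  for (k in 1:9) {
    expect_equal(base_payoff(TRUE, k, "beta", p), -p$c)
    expect_equal(base_payoff(FALSE, k, "beta", p), 0)
    expect_equal(base_payoff(TRUE, k, "beta", pl), -p$c)
    expect_equal(base_payoff(FALSE, k, "beta", pl), 0)
  }
  expect_error(base_payoff(FALSE, 10, "alpha", p), "\\[0, N\\]")
  expect_error(base_payoff(TRUE, 0, "alpha", p), "k >= 1")
})

test_that("group payoff plays signals, majority, actions and costs through", {
  p <- fig1_params()
  # homogeneous signalers cooperate at full quorum and pay both costs
  expect_equal(group_payoff("(10|01)", "(10|01)", 9, "alpha", p), 4.3)
  # silent shirkers: nothing happens, nothing is paid
  expect_equal(group_payoff("(00|00)", "(00|00)", 9, "alpha", p), 0)
  # the (10|01) signaler is silent under beta and the group shirks
  expect_equal(group_payoff("(10|01)", "(10|01)", 9, "beta", p), 0)
  expect_error(group_payoff("(10|01)", "(00|00)", 0, "alpha", p), "n_focal")
})

test_that("an exact signal tie is worth the even mixture of both readings", {
  p <- game_params(Z = 20, N = 4, M = 2, c = 0.5, c_S = 0.2, F = 10,
                   lambda = 0.5, gamma = 1)
  # 2 of (11|01) and 2 of (00|10) under alpha: ones = 2 = N/2, a tie.
  # reading "0": focal acts a0=0, others a0=1 -> k=2 -> defector share
  # reading "1": focal acts a1=1, others a1=0 -> k=2 -> cooperator
  r0 <- base_payoff(FALSE, 2, "alpha", p)
  r1 <- base_payoff(TRUE, 2, "alpha", p)
  expect_equal(group_payoff("(11|01)", "(00|10)", 2, "alpha", p),
               (r0 + r1) / 2 - p$c_S)
})

test_that("expected payoff mixes the states with lambda", {
  p <- fig1_params()
  expect_equal(expected_group_payoff("(10|01)", "(10|01)", 9, p), 2.15)
  p1 <- fig1_params(lambda = 1)
  expect_equal(expected_group_payoff("(10|01)", "(10|01)", 9, p1),
               group_payoff("(10|01)", "(10|01)", 9, "alpha", p1))
  p0 <- fig1_params(lambda = 0)
  expect_equal(expected_group_payoff("(10|01)", "(10|01)", 9, p0),
               group_payoff("(10|01)", "(10|01)", 9, "beta", p0))
})

test_that("cooperators earn exactly c less than defectors once quorum is met", {
  p <- fig2_params()
  for (state in c("alpha", "beta"))
    for (k in p$M:p$N)
      expect_equal(base_payoff(TRUE, k, state, p),
                   base_payoff(FALSE, k, state, p) - p$c)
})

test_that("loner-variant shirkers never earn a negative payoff", {
  p <- fig1_params(shirker = "loner")
  for (state in c("alpha", "beta"))
    for (k in 0:p$N)
      expect_gte(base_payoff(FALSE, k, state, p), 0)
})

test_that("bimorphic fitness equals exhaustive enumeration over co-player draws", {
  p <- game_params(Z = 20, N = 5, M = 3, c = 0.5, c_S = 0.2, F = 10,
                   lambda = 0.8, gamma = 1)
  cases <- list(c(10L, NA), c(1L, NA), c(19L, NA))
  for (k in c(1L, 10L, 19L)) {
    got <- bimorphic_fitness("(10|01)", "(00|00)", k, p)
    want <- enumerate_fitness("(10|01)", "(00|00)", k, p)
    expect_equal(got$omega_U, want$omega_U, tolerance = 1e-12)
    expect_equal(got$omega_V, want$omega_V, tolerance = 1e-12)
  }
  expect_error(bimorphic_fitness("(10|01)", "(00|00)", 0, p), "\\[1, Z-1\\]")
  expect_error(bimorphic_fitness("(10|01)", "(00|00)", 20, p), "\\[1, Z-1\\]")
})

test_that("when the group is the whole population the hypergeometric collapses", {
  p <- game_params(Z = 6, N = 6, M = 3, c = 0.5, c_S = 0.2, F = 10,
                   lambda = 0.7, gamma = 1)
  for (k in 1:5) {
    got <- bimorphic_fitness("(10|01)", "(01|10)", k, p)
    expect_equal(got$omega_U,
                 expected_group_payoff("(10|01)", "(01|10)", k, p))
    expect_equal(got$omega_V,
                 expected_group_payoff("(01|10)", "(10|01)", p$N - k, p))
  }
})

test_that("fitness respects the unused-signal symmetries", {
  # lambda = 1: flipping sigma_beta of both strategies changes nothing
  p1 <- fig1_params(lambda = 1, Z = 30)
  flip_b <- function(g) {
    g <- as_strategy(g)
    as_strategy(list(sigma_alpha = g$sigma_alpha, sigma_beta = 1 - g$sigma_beta,
                     a0 = g$a0, a1 = g$a1))
  }
  U <- "(10|01)"; V <- "(00|11)"
  for (k in c(1, 15, 29)) {
    a <- bimorphic_fitness(U, V, k, p1)
    b <- bimorphic_fitness(flip_b(U), flip_b(V), k, p1)
    expect_equal(a$omega_U, b$omega_U)
    expect_equal(a$omega_V, b$omega_V)
  }
  # c_S = 0: flipping the signal roles of both strategies changes nothing
  p0 <- fig1_params(c_S = 0, Z = 30)
  for (k in c(1, 15, 29)) {
    a <- bimorphic_fitness(U, V, k, p0)
    b <- bimorphic_fitness(signal_flip(U), signal_flip(V), k, p0)
    expect_equal(a$omega_U, b$omega_U, tolerance = 1e-12)
    expect_equal(a$omega_V, b$omega_V, tolerance = 1e-12)
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(game_params(Z = 1, N = 2, M = 1, c = 1, c_S = 0, F = 1,
                           lambda = 0.5, gamma = 1), "Z must")
  expect_error(fig1_params(M = 10), "M must")
  expect_error(fig1_params(lambda = 1.2), "lambda")
  expect_error(fig1_params(c = -1), "c must")
  expect_error(game_params(Z = 10, N = 20, M = 1, c = 1, c_S = 0, F = 1,
                           lambda = 0.5, gamma = 1), "N must")
})
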