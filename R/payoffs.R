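#' Majority signal in a group
#'
#' Each group member emits signal 0 or 1; the group acts on the most frequent
#' signal, with an exact split (possible only for even \code{N}) declared a
#' tie, to be resolved by a coin flip.
#'
#' @param ones number of members emitting signal 1.
#' @param N group size.
#' @return \code{"1"}, \code{"0"} or \code{"tie"}.
#' @export
majority_signal <- function(ones, N) {
  stopifnot(is.numeric(ones), is.numeric(N), length(ones) == 1L, length(N) == 1L)
  if (ones < 0 || ones > N) stop("ones must lie in [0, N]", call. = FALSE)
  if (ones > N / 2) "1" else if (ones < N / 2) "0" else "tie"
}

# Heaviside with theta(0) = 1
theta <- function(x) as.numeric(x >= 0)

#' State-dependent payoff of a single group member
#'
#' Payoff of one member of a group containing \code{k} cooperators, before
#' signaling costs. Under state \eqn{\alpha} the public good is worth having:
#' against defectors a cooperator earns \eqn{Fkc/N\,\theta(k-M) - c} and a
#' defector \eqn{Fkc/N\,\theta(k-M)}; against loners a cooperator earns
#' \eqn{Fc\,\theta(k-M) - c} and a loner 0. Under state \eqn{\beta} the same
#' expressions apply with \eqn{F = 0} (so cooperators lose \code{c}, shirkers
#' get 0). The Heaviside convention is \eqn{\theta(0) = 1}: exactly \code{M}
#' cooperators already produce the benefit.
#'
#' @param cooperates whether the focal member cooperates.
#' @param k number of cooperators in the group (including the focal one if it
#'   cooperates).
#' @param state \code{"alpha"} or \code{"beta"}.
#' @param params a [game_params] object.
#' @return The payoff (signaling cost not included).
#' @export
base_payoff <- function(cooperates, k, state, params) {
  state <- match.arg(state, c("alpha", "beta"))
  stopifnot(is.logical(cooperates), length(cooperates) == 1L)
  if (k < 0 || k > params$N) stop("k must lie in [0, N]", call. = FALSE)
  if (cooperates && k < 1) stop("a cooperating focal implies k >= 1", call. = FALSE)
  Feff <- if (state == "alpha") params$F else 0
  hit <- theta(k - params$M)
  if (params$shirker == "defector") {
    share <- Feff * k * params$c / params$N * hit
    if (cooperates) share - params$c else share
  } else {
    if (cooperates) Feff * params$c * hit - params$c else 0
  }
}

#' Focal payoff in a bimorphic group under one state of Nature
#'
#' Plays out the signaling game deterministically for a group composed of two
#' genotypes: every member emits its genotype's signal for the realized
#' state, the majority signal is determined, every member takes the action
#' its genotype prescribes for that majority, and the focal member collects
#' the resulting threshold public goods payoff minus the signaling cost
#' \code{c_S} if its own emitted signal was 1. An exact signal tie is valued
#' as the even mixture of the two majority readings (the expectation of the
#' coin flip), so the result is deterministic.
#'
#' @param focal,other the focal member's genotype and the other genotype
#'   present (strategy objects or labels).
#' @param n_focal number of group members (including the focal one) sharing
#'   the focal genotype; the remaining \code{N - n_focal} carry \code{other}.
#' @param state \code{"alpha"} or \code{"beta"}.
#' @param params a [game_params] object.
#' @return The focal member's payoff.
#' @examples
#' p <- game_params(Z = 100, N = 9, M = 5, c = 0.5, c_S = 0.2, F = 10,
#'                  lambda = 0.5, gamma = 5)
#' # homogeneous (10|01) group under alpha: all signal, all cooperate
#' group_payoff("(10|01)", "(10|01)", 9, "alpha", p)  # 4.3
#' @export
group_payoff <- function(focal, other, n_focal, state, params) {
  focal <- as_strategy(focal); other <- as_strategy(other)
  state <- match.arg(state, c("alpha", "beta"))
  N <- params$N
  if (n_focal < 1 || n_focal > N)
    stop("n_focal must lie in [1, N]", call. = FALSE)
  n_other <- N - n_focal
  sig <- if (state == "alpha") c(focal$sigma_alpha, other$sigma_alpha)
         else c(focal$sigma_beta, other$sigma_beta)
  ones <- n_focal * sig[1L] + n_other * sig[2L]
  maj <- majority_signal(ones, N)
  pay_under <- function(m) {
    a_f <- if (m == "1") focal$a1 else focal$a0
    a_o <- if (m == "1") other$a1 else other$a0
    k <- n_focal * a_f + n_other * a_o
    base_payoff(a_f == 1L, k, state, params)
  }
  pay <- if (maj == "tie") (pay_under("0") + pay_under("1")) / 2 else pay_under(maj)
  pay - params$c_S * sig[1L]
}

#' Expected focal payoff over the states of Nature
#'
#' Mixes the two state-conditional group payoffs with the state probabilities:
#' \eqn{\lambda \Pi^\alpha + (1-\lambda)\Pi^\beta}.
#'
#' @inheritParams group_payoff
#' @return The expected payoff.
#' @export
expected_group_payoff <- function(focal, other, n_focal, params) {
  lam <- params$lambda
  pa <- if (lam > 0) group_payoff(focal, other, n_focal, "alpha", params) else 0
  pb <- if (lam < 1) group_payoff(focal, other, n_focal, "beta", params) else 0
  lam * pa + (1 - lam) * pb
}

#' Expected fitness of both types in a bimorphic population
#'
#' In a well-mixed population of \code{Z} individuals holding \code{k} copies
#' of genotype \code{U} and \code{Z - k} of \code{V}, groups of size \code{N}
#' assemble uniformly at random, so the number of same-type co-players of a
#' focal individual is hypergeometric. Fitness is the expectation of the
#' focal payoff over that draw:
#' \deqn{\Omega_U(k) = \binom{Z-1}{N-1}^{-1} \sum_{j} \binom{k-1}{j}
#'   \binom{Z-k}{N-1-j}\,\pi_U(j),}
#' and analogously for \eqn{\Omega_V} with weights
#' \eqn{\binom{k}{j}\binom{Z-k-1}{N-1-j}} over its \code{j} U-type co-players.
#'
#' @param U,V the two genotypes (strategy objects or labels).
#' @param k number of U-strategists in the population (1 <= k <= Z-1).
#' @param params a [game_params] object.
#' @return A list with \code{k}, \code{omega_U} and \code{omega_V}.
#' @export
bimorphic_fitness <- function(U, V, k, params) {
  if (k < 1 || k > params$Z - 1)
    stop("k must lie in [1, Z-1]", call. = FALSE)
  pr <- pair_payoffs(as_strategy(U), as_strategy(V), params)
  om <- pair_fitness_profiles(pr, k, params)
  list(k = as.integer(k), omega_U = om$omega_U, omega_V = om$omega_V)
}

# Per-composition expected payoffs for an ordered genotype pair:
# pi_U[j+1] = payoff of a U focal with j U co-players (j = 0..N-1), pi_V likewise
# with j counting U co-players of the V focal.
pair_payoffs <- function(U, V, params) {
  N <- params$N
  j <- 0:(N - 1L)
  list(
    pi_U = vapply(j, function(x) expected_group_payoff(U, V, x + 1L, params), 0),
    pi_V = vapply(j, function(x) expected_group_payoff(V, U, N - x, params), 0)
  )
}

# Omega_U(k), Omega_V(k) for vector k via hypergeometric weights; terms with
# impossible draws have dhyper weight 0.
pair_fitness_profiles <- function(pr, k, params) {
  Z <- params$Z; N <- params$N
  j <- 0:(N - 1L)
  wU <- vapply(j, function(x) stats::dhyper(x, k - 1L, Z - k, N - 1L),
               numeric(length(k)))
  wV <- vapply(j, function(x) stats::dhyper(x, k, Z - k - 1L, N - 1L),
               numeric(length(k)))
  dim(wU) <- dim(wV) <- c(length(k), N)
  list(omega_U = as.vector(wU %*% pr$pi_U),
       omega_V = as.vector(wV %*% pr$pi_V))
}

# Omega_U(k) - Omega_V(k) for k = 1..Z-1 (k = number of U-strategists)
fitness_difference_profile <- function(U, V, params) {
  pr <- pair_payoffs(as_strategy(U), as_strategy(V), params)
  k <- seq_len(params$Z - 1L)
  om <- pair_fitness_profiles(pr, k, params)
  om$omega_U - om$omega_V
}
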