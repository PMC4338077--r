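#' Fermi imitation probability
#'
#' Probability that an individual imitates a partner whose fitness exceeds
#' its own by \code{delta_omega}, under the pairwise-comparison rule
#' \eqn{[1 + e^{-\gamma\,\Delta\Omega}]^{-1}}. Computed via
#' [stats::plogis()], which is overflow-safe for arbitrarily large
#' \eqn{|\gamma\,\Delta\Omega|}.
#'
#' @param delta_omega fitness difference (partner minus focal).
#' @param gamma selection intensity (>= 0).
#' @return The imitation probability.
#' @export
fermi_probability <- function(delta_omega, gamma) {
  stopifnot(gamma >= 0)
  stats::plogis(gamma * delta_omega)
}

#' Birth-death transition probabilities for a bimorphic population
#'
#' Probability that the number \code{k} of U-strategists increases
#' (\code{t_plus}) or decreases (\code{t_minus}) by one in a single update of
#' the pairwise-comparison process:
#' \eqn{T^\pm(k) = \frac{k}{Z}\frac{Z-k}{Z-1}
#' [1 + e^{\mp\gamma(\Omega_U(k)-\Omega_V(k))}]^{-1}}.
#' Both vanish at the monomorphic boundaries \code{k = 0} and \code{k = Z}.
#'
#' @param U,V the mutant and resident genotypes.
#' @param k current number of U-strategists (0 <= k <= Z).
#' @param params a [game_params] object.
#' @return A list with \code{k}, \code{t_plus}, \code{t_minus}.
#' @export
transition_rates <- function(U, V, k, params) {
  Z <- params$Z
  if (k < 0 || k > Z) stop("k must lie in [0, Z]", call. = FALSE)
  if (k == 0 || k == Z)
    return(list(k = as.integer(k), t_plus = 0, t_minus = 0))
  om <- bimorphic_fitness(U, V, k, params)
  d <- om$omega_U - om$omega_V
  pre <- (k / Z) * ((Z - k) / (Z - 1))
  list(k = as.integer(k),
       t_plus = pre * fermi_probability(d, params$gamma),
       t_minus = pre * fermi_probability(-d, params$gamma))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# rho from the fitness-difference profile d(k) = Omega_U(k) - Omega_V(k),
# k = 1..Z-1, evaluated in the log domain:
# rho = 1 / sum_{i=0}^{Z-1} exp(-gamma * sum_{j<=i} d_j)
# An exactly neutral profile returns 1/Z exactly, so that strict comparisons
# against the neutral rate are not decided by rounding in exp/log.
rho_from_profile <- function(d, gamma) {
  g <- gamma * d
  if (!any(g != 0)) return(1 / (length(d) + 1))
  L <- c(0, cumsum(-g))
  exp(-log_sum_exp(L))
}

#' Fixation probability of a single mutant
#'
#' Probability \eqn{\rho_{V,U}} that one mutant of genotype \code{U} takes
#' over a population of \code{Z - 1} residents of genotype \code{V} under the
#' pairwise-comparison birth-death process:
#' \deqn{\rho_{V,U} = \Big[\sum_{i=0}^{Z-1}\prod_{j=1}^{i}\phi_j\Big]^{-1},
#'   \qquad \phi_j = e^{-\gamma(\Omega_U(j) - \Omega_V(j))}.}
#' The sum is accumulated in the log domain (cumulative sums of
#' \eqn{-\gamma\,\Delta\Omega} followed by log-sum-exp), so the result stays
#' finite and accurate under strong selection. At \eqn{\gamma = 0} the result
#' is exactly the neutral value \eqn{1/Z}.
#'
#' @param U invading mutant genotype.
#' @param V resident genotype (must differ from \code{U}).
#' @param params a [game_params] object.
#' @return A list of class \code{fixation_result} with \code{invader},
#'   \code{resident}, \code{rho} and \code{neutral_rho} (\code{= 1/Z}).
#' @export
fixation_probability <- function(U, V, params) {
  U <- as_strategy(U); V <- as_strategy(V)
  if (U$label == V$label)
    stop("invader and resident must be distinct strategies", call. = FALSE)
  d <- fitness_difference_profile(U, V, params)
  structure(list(invader = U$label, resident = V$label,
                 rho = rho_from_profile(d, params$gamma),
                 neutral_rho = 1 / params$Z),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("rho[%s -> %s] = %.6g  (neutral 1/Z = %.6g)\n",
              x$resident, x$invader, x$rho, x$neutral_rho))
  invisible(x)
}

#' Pairwise fixation probability matrix
#'
#' Computes \eqn{\rho_{V,U}} for every ordered pair of strategies in a space.
#' Each unordered pair shares one fitness-profile computation: the reverse
#' direction reuses the negated, reversed profile.
#'
#' @param space a [strategy_space].
#' @param params a [game_params] object.
#' @return An \code{n x n} matrix with rows indexing the resident strategy
#'   and columns the invader; the diagonal is \code{NA}.
#' @export
fixation_matrix <- function(space, params) {
  n <- nrow(space)
  labs <- space$label
  gs <- lapply(labs, parse_strategy)
  rho <- matrix(NA_real_, n, n, dimnames = list(resident = labs, invader = labs))
  gamma <- params$gamma
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      d <- fitness_difference_profile(gs[[a]], gs[[b]], params)
      rho[labs[b], labs[a]] <- rho_from_profile(d, gamma)        # a invades b
      rho[labs[a], labs[b]] <- rho_from_profile(-rev(d), gamma)  # b invades a
    }
  }
  rho
}
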