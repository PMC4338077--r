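#' Model parameters for the N-person signaling game
#'
#' Bundles and validates all parameters of the threshold public goods game
#' with quorum signaling and its finite-population dynamics.
#'
#' @param Z population size (integer, at least 2).
#' @param N group size (integer, 2 <= N <= Z).
#' @param M coordination threshold: minimum number of cooperators in a group
#'   required to produce any benefit (integer, 1 <= M <= N).
#' @param c cost of cooperation (positive).
#' @param c_S cost of emitting signal 1; signal 0 is free (non-negative).
#' @param F enhancement factor of the public good: each cooperator adds
#'   \eqn{Fc/N} to the benefit pool once the threshold is met (non-negative).
#' @param lambda probability that Nature chooses state \eqn{\alpha} (the state
#'   in which collective action produces a benefit); state \eqn{\beta}
#'   (benefit factor 0) occurs with probability \code{1 - lambda}.
#' @param gamma selection intensity of the pairwise-comparison (Fermi) update
#'   rule (non-negative; 0 = neutral drift).
#' @param shirker role played by non-cooperators: a \code{"defector"} shares
#'   the benefit without paying the cost; a \code{"loner"} neither pays nor
#'   benefits.
#' @return A list of class \code{game_params}.
#' @examples
#' game_params(Z = 100, N = 9, M = 5, c = 0.5, c_S = 0.2, F = 10,
#'             lambda = 0.5, gamma = 5)
#' @export
game_params <- function(Z, N, M, c, c_S, F, lambda, gamma,
                        shirker = c("defector", "loner")) {
  shirker <- match.arg(shirker)
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(is.numeric(Z) && length(Z) == 1L && Z == round(Z) && Z >= 2,
      "Z must be an integer >= 2")
  chk(is.numeric(N) && length(N) == 1L && N == round(N) && N >= 2 && N <= Z,
      "N must be an integer with 2 <= N <= Z")
  chk(is.numeric(M) && length(M) == 1L && M == round(M) && M >= 1 && M <= N,
      "M must be an integer with 1 <= M <= N")
  chk(is.numeric(c) && length(c) == 1L && is.finite(c) && c > 0,
      "c must be a positive number")
  chk(is.numeric(c_S) && length(c_S) == 1L && is.finite(c_S) && c_S >= 0,
      "c_S must be non-negative")
  chk(is.numeric(F) && length(F) == 1L && is.finite(F) && F >= 0,
      "F must be non-negative")
  chk(is.numeric(lambda) && length(lambda) == 1L && lambda >= 0 && lambda <= 1,
      "lambda must lie in [0, 1]")
  chk(is.numeric(gamma) && length(gamma) == 1L && is.finite(gamma) && gamma >= 0,
      "gamma must be non-negative")
  structure(list(Z = as.integer(Z), N = as.integer(N), M = as.integer(M),
                 c = c, c_S = c_S, F = F, lambda = lambda, gamma = gamma,
                 shirker = shirker),
            class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf(
    "N-person signaling game: Z=%d, N=%d, M=%d, c=%g, c_S=%g, F=%g, lambda=%g, gamma=%g, shirkers are %ss\n",
    x$Z, x$N, x$M, x$c, x$c_S, x$F, x$lambda, x$gamma, x$shirker))
  invisible(x)
}

#' @export
format.game_params <- function(x, ...) {
  sprintf("Z=%d,N=%d,M=%d,c=%g,c_S=%g,F=%g,lambda=%g,gamma=%g,shirker=%s",
          x$Z, x$N, x$M, x$c, x$c_S, x$F, x$lambda, x$gamma, x$shirker)
}

# replace named fields, re-validating
modify_params <- function(p, ...) {
  upd <- list(...)
  stopifnot(all(names(upd) %in% names(unclass(p))))
  args <- unclass(p)
  args[names(upd)] <- upd
  do.call(game_params, args)
}
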