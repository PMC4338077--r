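#' Quorum-sensing strategy genotypes
#'
#' A strategy genotype is a 4-bit vector \eqn{(\sigma_\alpha \sigma_\beta \mid
#' A_0 A_1)}: the signal (0 or 1) emitted under each state of Nature
#' (\eqn{\alpha}, \eqn{\beta}) and the action taken under each majority group
#' signal (\eqn{A_0} when the majority signal is 0, \eqn{A_1} when it is 1;
#' action 1 = cooperate, 0 = shirk). Labels use the canonical string form,
#' e.g. \code{"(10|01)"}.
#'
#' @param reduced if \code{TRUE}, return only the constrained subspace in
#'   which individuals always shirk in the absence of a majority signal
#'   (\eqn{A_0 = 0}); 8 genotypes instead of 16.
#' @return A data.frame of class \code{strategy_space} with columns
#'   \code{sigma_alpha}, \code{sigma_beta}, \code{a0}, \code{a1},
#'   \code{label}, ordered lexicographically on
#'   \eqn{(\sigma_\alpha, \sigma_\beta, A_0, A_1)}.
#' @examples
#' strategy_space()           # all 16 genotypes
#' strategy_space(reduced = TRUE)  # the 8 genotypes with A0 = 0
#' @export
strategy_space <- function(reduced = FALSE) {
  stopifnot(is.logical(reduced), length(reduced) == 1L, !is.na(reduced))
  g <- expand.grid(a1 = 0:1, a0 = 0:1, sigma_beta = 0:1, sigma_alpha = 0:1,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("sigma_alpha", "sigma_beta", "a0", "a1")]
  if (reduced) g <- g[g$a0 == 0L, , drop = FALSE]
  rownames(g) <- NULL
  g$label <- sprintf("(%d%d|%d%d)", g$sigma_alpha, g$sigma_beta, g$a0, g$a1)
  structure(g, reduced = reduced, class = c("strategy_space", "data.frame"))
}

#' @export
print.strategy_space <- function(x, ...) {
  cat(sprintf("Strategy space: %d genotypes%s\n", nrow(x),
              if (isTRUE(attr(x, "reduced"))) " (reduced, A0 = 0)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Parse a strategy label
#'
#' @param label a string of the form \code{"(ss|aa)"} with each digit 0 or 1,
#'   e.g. \code{"(10|01)"}.
#' @return A list of class \code{strategy} with fields \code{sigma_alpha},
#'   \code{sigma_beta}, \code{a0}, \code{a1} and \code{label}.
#' @examples
#' parse_strategy("(10|01)")
#' @export
parse_strategy <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label, regexec("^\\(([01])([01])\\|([01])([01])\\)$", label))[[1L]]
  if (length(m) != 5L)
    stop("malformed strategy label: ", dQuote(label),
         " (expected \"(dd|dd)\" with binary digits)", call. = FALSE)
  b <- as.integer(m[2:5])
  new_strategy(b[1L], b[2L], b[3L], b[4L])
}

new_strategy <- function(sigma_alpha, sigma_beta, a0, a1) {
  structure(list(sigma_alpha = as.integer(sigma_alpha),
                 sigma_beta = as.integer(sigma_beta),
                 a0 = as.integer(a0), a1 = as.integer(a1),
                 label = sprintf("(%d%d|%d%d)", sigma_alpha, sigma_beta, a0, a1)),
            class = "strategy")
}

#' Coerce to a strategy genotype
#'
#' Accepts a \code{strategy} object, a label string, or a list / one-row
#' data.frame with the four bit fields.
#'
#' @param x object to coerce.
#' @return A \code{strategy} object.
#' @export
as_strategy <- function(x) {
  if (inherits(x, "strategy")) return(x)
  if (is.character(x)) return(parse_strategy(x))
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  if (is.list(x)) {
    need <- c("sigma_alpha", "sigma_beta", "a0", "a1")
    if (!all(need %in% names(x)))
      stop("cannot coerce to strategy: missing fields ",
           paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
    b <- as.integer(unlist(x[need]))
    if (!all(b %in% 0:1)) stop("strategy bits must be 0 or 1", call. = FALSE)
    return(new_strategy(b[1L], b[2L], b[3L], b[4L]))
  }
  stop("cannot coerce object of class ", class(x)[1L], " to strategy",
       call. = FALSE)
}

#' @export
print.strategy <- function(x, ...) {
  cat("Strategy", x$label, "\n")
  invisible(x)
}

#' Signal relabeling symmetry
#'
#' Flips both emitted signals (\eqn{\sigma \to 1 - \sigma}) and swaps the two
#' actions (\eqn{A_0 \leftrightarrow A_1}). This relabels which physical
#' signal plays which role: when signaling is costless (\eqn{c_S = 0}) the
#' game is invariant under applying it to every strategy, and it maps the two
#' signaling systems \code{(10|01)} and \code{(01|10)} onto each other.
#' It is an involution: applying it twice returns the input.
#'
#' @param g a strategy (object or label).
#' @return The flipped \code{strategy}.
#' @examples
#' signal_flip("(10|01)")$label  # "(01|10)"
#' @export
signal_flip <- function(g) {
  g <- as_strategy(g)
  new_strategy(1L - g$sigma_alpha, 1L - g$sigma_beta, g$a1, g$a0)
}
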