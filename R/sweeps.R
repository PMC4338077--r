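#' Parameter sweep over embedded-chain observables
#'
#' Evaluates stationary-distribution observables of the small-mutation chain
#' over a grid of one or two game parameters. Each grid point builds a fresh
#' chain; evaluation is deterministic and independent of grid order. Invalid
#' parameter combinations (e.g. \code{M > N}) produce a row with \code{NA}
#' value and the error message, and the sweep continues.
#'
#' @param space a [strategy_space].
#' @param params baseline [game_params]; swept fields are overridden.
#' @param vary named list of one or two numeric vectors; names must be
#'   \code{game_params} fields (e.g. \code{list(lambda = ..., c_S = ...)}).
#' @param outputs character vector of observables: \code{"signaling_prevalence"}
#'   (stationary mass of \code{(10|01)} plus \code{(01|10)}),
#'   \code{"prevalence:<label>"} (stationary mass of one strategy),
#'   \code{"ers:<label>"} (1 if that strategy is an ERS, else 0), or
#'   \code{"stationary"} (one row per strategy).
#' @return A long-format data.frame: one column per swept parameter, then
#'   \code{observable}, \code{strategy} (\code{NA} unless applicable),
#'   \code{value}, \code{error}.
#' @examples
#' \donttest{
#' p <- game_params(Z = 50, N = 5, M = 3, c = 0.5, c_S = 0.2, F = 10,
#'                  lambda = 0.5, gamma = 5)
#' run_sweep(strategy_space(), p, vary = list(c_S = c(0.1, 0.4)),
#'           outputs = "prevalence:(10|01)")
#' }
#' @export
run_sweep <- function(space, params, vary, outputs = "signaling_prevalence") {
  stopifnot(is.list(vary), length(vary) %in% 1:2,
            !is.null(names(vary)), all(nzchar(names(vary))))
  bad <- setdiff(names(vary), names(unclass(params)))
  if (length(bad))
    stop("unknown game parameters in vary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(vary)))
    stop("swept parameter names must be distinct", call. = FALSE)
  grid <- expand.grid(vary, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    point <- as.list(grid[i, , drop = FALSE])
    res <- tryCatch({
      p_i <- do.call(modify_params, c(list(params), point))
      chain <- embedded_chain(space, p_i)
      pi <- stationary_distribution(chain)
      do.call(rbind, lapply(outputs, function(obs) {
        eval_observable(obs, pi, chain)
      }))
    }, error = function(e) {
      data.frame(observable = outputs, strategy = NA_character_,
                 value = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- cbind(grid[rep(i, nrow(res)), , drop = FALSE], res,
                       row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

eval_observable <- function(obs, pi, chain) {
  ok <- function(value, strategy = NA_character_)
    data.frame(observable = obs, strategy = strategy, value = value,
               error = NA_character_, stringsAsFactors = FALSE)
  if (obs == "signaling_prevalence") return(ok(signaling_prevalence(pi)))
  if (obs == "stationary") return(ok(unname(pi), strategy = names(pi)))
  if (startsWith(obs, "prevalence:")) {
    lab <- sub("^prevalence:", "", obs)
    if (!lab %in% names(pi)) stop("unknown strategy label: ", lab, call. = FALSE)
    return(ok(unname(pi[lab]), strategy = lab))
  }
  if (startsWith(obs, "ers:")) {
    lab <- sub("^ers:", "", obs)
    if (!lab %in% chain$space$label)
      stop("unknown strategy label: ", lab, call. = FALSE)
    ers <- ers_set(chain$space, chain$params, rho = chain$rho)
    return(ok(as.numeric(lab %in% ers), strategy = lab))
  }
  stop("unknown observable: ", obs, call. = FALSE)
}
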