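#' Small-mutation-limit embedded Markov chain
#'
#' When mutations are rare the population is monomorphic except during brief
#' invasion episodes, and evolution reduces to a Markov chain over the
#' monomorphic states, one per strategy. Each off-diagonal transition
#' probability is \eqn{\eta\,\rho_{V,U}} with \eqn{\eta = (n_S-1)^{-1}} (a
#' mutant strategy is drawn uniformly among the others); the diagonal
#' completes each row to 1.
#'
#' @param space a [strategy_space].
#' @param params a [game_params] object.
#' @param rho optional precomputed [fixation_matrix()] for \code{space}
#'   (rows = resident, cols = invader); computed if missing.
#' @return A list of class \code{embedded_chain} with elements \code{space},
#'   \code{params}, \code{rho}, \code{T} (row-stochastic transition matrix)
#'   and \code{eta}.
#' @export
embedded_chain <- function(space, params, rho = NULL) {
  n <- nrow(space)
  if (is.null(rho)) rho <- fixation_matrix(space, params)
  stopifnot(identical(dim(rho), c(n, n)))
  off <- rho
  diag(off) <- 0
  if (any(off < 0 | off > 1))
    stop("internal consistency error: fixation probability outside [0, 1]",
         call. = FALSE)
  eta <- 1 / (n - 1)
  Tm <- eta * off
  diag(Tm) <- 1 - rowSums(Tm)
  if (any(diag(Tm) < -1e-12 | diag(Tm) > 1 + 1e-12))
    stop("internal consistency error: diagonal of T outside [0, 1]",
         call. = FALSE)
  dimnames(Tm) <- list(resident = space$label, invader = space$label)
  structure(list(space = space, params = params, rho = rho, T = Tm, eta = eta),
            class = "embedded_chain")
}

#' @export
print.embedded_chain <- function(x, ...) {
  cat(sprintf("Embedded Markov chain over %d monomorphic states (eta = 1/%d)\n",
              nrow(x$T), nrow(x$T) - 1L))
  print(x$params)
  invisible(x)
}

# strongly connected components (Kosaraju) of the directed graph given by an
# adjacency logical matrix
scc_components <- function(adj) {
  n <- nrow(adj)
  visited <- logical(n); order <- integer(0)
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    for (w in which(adj[v, ])) if (!visited[w]) dfs1(w)
    order <<- c(order, v)
  }
  for (v in seq_len(n)) if (!visited[v]) dfs1(v)
  comp <- integer(n); cur <- 0L
  seen <- logical(n)
  for (v in rev(order)) {
    if (seen[v]) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[u]) next
      seen[u] <- TRUE; comp[u] <- cur
      stack <- c(stack, which(adj[, u] & !seen))
    }
  }
  comp
}

#' Stationary distribution of the embedded chain
#'
#' Solves \eqn{\pi T = \pi,\ \sum_i \pi_i = 1} as an (overdetermined) linear
#' system rather than by eigendecomposition, for determinism. The stationary
#' mass of a state is the long-run fraction of time the population spends in
#' the corresponding monomorphic configuration (its prevalence). The
#' stationary vector is unique iff the chain has a single closed communicating
#' class; with several (disconnected neutral components, or transition
#' probabilities underflowing to zero under extreme selection) an error names
#' the classes rather than returning an arbitrary mixture. The solution is
#' additionally validated against the residual \eqn{\|\pi T - \pi\|_\infty}.
#'
#' @param chain an [embedded_chain].
#' @param tol acceptable residual for the linear solve.
#' @return A named numeric vector summing to 1.
#' @export
stationary_distribution <- function(chain, tol = 1e-8) {
  Tm <- chain$T
  n <- nrow(Tm)
  adj <- Tm > 0; diag(adj) <- FALSE
  comp <- scc_components(adj)
  closed <- vapply(unique(comp), function(cc) {
    inside <- comp == cc
    !any(adj[inside, !inside, drop = FALSE])
  }, logical(1))
  if (sum(closed) > 1L) {
    groups <- split(rownames(Tm), comp)[closed]
    stop("stationary distribution is not unique: the chain has ",
         sum(closed), " closed communicating classes: ",
         paste(vapply(groups, paste, "", collapse = " "), collapse = " | "),
         call. = FALSE)
  }
  A <- t(Tm) - diag(n)
  M <- rbind(A, rep(1, n))
  pi <- qr.coef(qr(M, LAPACK = TRUE), c(rep(0, n), 1))
  if (any(pi < -1e-9)) stop("stationary solve produced negative mass", call. = FALSE)
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  resid <- max(abs(pi %*% Tm - pi))
  if (resid > tol)
    stop(sprintf("stationary solve did not converge (residual %.3g)", resid),
         call. = FALSE)
  names(pi) <- rownames(Tm)
  pi
}

#' Evolutionarily robust strategies
#'
#' A strategy is evolutionarily robust (ERS) if natural selection opposes the
#' fixation of every possible mutant: for a resident \code{A},
#' \eqn{\rho_{A,B} < 1/Z} strictly for all \eqn{B \neq A}. A mutant that
#' fixes exactly at the neutral rate \eqn{1/Z} (e.g. a behaviorally
#' equivalent genotype) therefore disqualifies robustness.
#'
#' @param space a [strategy_space].
#' @param params a [game_params] object.
#' @param rho optional precomputed [fixation_matrix()].
#' @return Character vector of ERS labels (possibly empty).
#' @export
ers_set <- function(space, params, rho = NULL) {
  if (is.null(rho)) rho <- fixation_matrix(space, params)
  thr <- 1 / params$Z
  keep <- apply(rho, 1L, function(r) all(r[!is.na(r)] < thr))
  space$label[keep]
}

#' Alternative stability classifiers
#'
#' Three finite-population stability notions over the same fixation
#' probabilities: \code{"ers"} is [ers_set()]; \code{"ers_plus_fitness"}
#' additionally requires every single mutant to have lower fitness than the
#' resident (\eqn{\Omega_B(1) < \Omega_A(1)}), giving a subset of the ERS
#' set; \code{"counter_invasion"} requires that any mutant \code{B} favored
#' to invade (\eqn{\rho_{A,B} > 1/Z}) is counter-invaded with a larger
#' probability (\eqn{\rho_{B,A} > \rho_{A,B}}).
#'
#' @inheritParams ers_set
#' @param criterion one of \code{"ers"}, \code{"ers_plus_fitness"},
#'   \code{"counter_invasion"}.
#' @return Character vector of stable strategy labels.
#' @export
stability_set <- function(space, params,
                          criterion = c("ers", "ers_plus_fitness",
                                        "counter_invasion"),
                          rho = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(rho)) rho <- fixation_matrix(space, params)
  labs <- space$label
  thr <- 1 / params$Z
  switch(criterion,
    ers = ers_set(space, params, rho),
    ers_plus_fitness = {
      base <- ers_set(space, params, rho)
      keep <- vapply(base, function(A) {
        all(vapply(setdiff(labs, A), function(B) {
          om <- bimorphic_fitness(B, A, 1L, params)
          om$omega_U < om$omega_V
        }, logical(1)))
      }, logical(1))
      base[keep]
    },
    counter_invasion = {
      keep <- vapply(labs, function(A) {
        invaders <- labs[!is.na(rho[A, ]) & rho[A, ] > thr]
        all(vapply(invaders, function(B) rho[B, A] > rho[A, B], logical(1)))
      }, logical(1))
      labs[keep]
    })
}

#' Invasion graph
#'
#' Directed graph over monomorphic states with an edge \eqn{V \to U} whenever
#' selection favors the transition, i.e. \eqn{\rho_{V,U} > 1/Z}. Nodes with
#' no outgoing edge cannot be invaded above the neutral rate.
#'
#' @inheritParams ers_set
#' @return A list of class \code{invasion_graph} with \code{nodes},
#'   \code{edges} (data.frame: from, to, rho, neutral_threshold) and
#'   \code{neutral_threshold}.
#' @export
invasion_graph <- function(space, params, rho = NULL) {
  if (is.null(rho)) rho <- fixation_matrix(space, params)
  thr <- 1 / params$Z
  idx <- which(!is.na(rho) & rho > thr, arr.ind = TRUE)
  edges <- data.frame(from = rownames(rho)[idx[, 1L]],
                      to = colnames(rho)[idx[, 2L]],
                      rho = rho[idx],
                      neutral_threshold = rep(thr, nrow(idx)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = space$label, edges = edges, neutral_threshold = thr),
            class = "invasion_graph")
}

#' @export
print.invasion_graph <- function(x, ...) {
  cat(sprintf("Invasion graph: %d nodes, %d selection-favored transitions (threshold 1/Z = %.4g)\n",
              length(x$nodes), nrow(x$edges), x$neutral_threshold))
  sinks <- graph_sinks(x)
  if (length(sinks)) cat("Sink nodes:", paste(sinks, collapse = " "), "\n")
  invisible(x)
}

#' Sink nodes of an invasion graph
#'
#' @param graph an [invasion_graph].
#' @return Labels of nodes without outgoing edges.
#' @export
graph_sinks <- function(graph) {
  setdiff(graph$nodes, unique(graph$edges$from))
}

#' Restrict an embedded chain to a strategy subset
#'
#' Rebuilds the small-mutation chain over a subset of strategies, reusing the
#' already-computed pairwise fixation probabilities and renormalizing with
#' \eqn{\eta = (|S| - 1)^{-1}}.
#'
#' @param chain an [embedded_chain].
#' @param subset character vector of at least two strategy labels.
#' @return An [embedded_chain] over the subset.
#' @export
restrict_chain <- function(chain, subset) {
  labs <- chain$space$label
  if (!all(subset %in% labs))
    stop("unknown strategy labels: ",
         paste(setdiff(subset, labs), collapse = ", "), call. = FALSE)
  if (length(subset) < 2L || anyDuplicated(subset))
    stop("subset must contain at least two distinct strategies", call. = FALSE)
  sub_space <- chain$space[match(subset, labs), , drop = FALSE]
  class(sub_space) <- class(chain$space)
  attr(sub_space, "reduced") <- attr(chain$space, "reduced")
  embedded_chain(sub_space, chain$params,
                 rho = chain$rho[subset, subset, drop = FALSE])
}

#' Combined prevalence of the two signaling systems
#'
#' Sum of the stationary masses of the two discriminating strategies
#' \code{(10|01)} (costly signal marks the cooperative state) and
#' \code{(01|10)} (the free signal does, a collective "secret handshake").
#'
#' @param pi a stationary distribution (named vector).
#' @return The summed prevalence.
#' @export
signaling_prevalence <- function(pi) {
  sum(pi[intersect(c("(10|01)", "(01|10)"), names(pi))])
}
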