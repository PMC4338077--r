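#' Write a stationary distribution to CSV and JSON
#'
#' The CSV holds one row per strategy (label, mass); the JSON additionally
#' echoes the full parameter set for provenance.
#'
#' @param pi named stationary vector.
#' @param params the [game_params] used.
#' @param csv,json output paths (either may be \code{NULL} to skip).
#' @return Invisibly, the data.frame written.
#' @export
write_stationary <- function(pi, params, csv = NULL, json = NULL) {
  df <- data.frame(strategy = names(pi), mass = unname(pi),
                   stringsAsFactors = FALSE)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(params = unclass(params), stationary = df),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(df)
}

#' Export an invasion graph
#'
#' Writes the selection-favored transition structure as a Graphviz DOT file
#' and/or an edge-list CSV (columns from, to, rho, neutral_threshold).
#'
#' @param graph an [invasion_graph].
#' @param dot,csv output paths (either may be \code{NULL} to skip).
#' @return Invisibly, the edge data.frame.
#' @export
write_invasion_graph <- function(graph, dot = NULL, csv = NULL) {
  if (!is.null(csv)) utils::write.csv(graph$edges, csv, row.names = FALSE)
  if (!is.null(dot)) {
    q <- function(x) paste0('"', x, '"')
    lines <- c("digraph invasion {",
               paste0("  ", q(graph$nodes), ";"),
               sprintf("  %s -> %s [label=\"%.3g\"];",
                       q(graph$edges$from), q(graph$edges$to),
                       graph$edges$rho),
               "}")
    writeLines(lines, dot)
  }
  invisible(graph$edges)
}
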