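#' Build a protein-interaction network from an edge list
#'
#' Filters edges by confidence score, canonicalizes duplicates (A-B equals
#' B-A), drops self-loops, and keeps requested query nodes as isolated
#' degree-0 vertices even when all their edges fall below the cutoff.
#'
#' @param edges A tibble/data frame with columns `node_a`, `node_b`,
#'   `score` (score in \[0, 1\]).
#' @param min_score Minimum confidence to retain an edge (default 0.4,
#'   the conventional medium-confidence cutoff for STRING-style scores).
#' @param keep_nodes Nodes to retain even if isolated (e.g. the query
#'   gene set).
#' @return A list of class `ppi_network`: `graph` (igraph), `nodes`
#'   tibble (`gene`, `degree`, `component`), `n_edges`.
#' @export
build_network <- function(edges, min_score = 0.4, keep_nodes = NULL) {
  req <- c("node_a", "node_b", "score")
  if (!all(req %in% names(edges))) {
    stop("edge list needs columns node_a, node_b, score", call. = FALSE)
  }
  bad <- which(!is.finite(edges$score) | edges$score < 0 | edges$score > 1 |
                 is.na(edges$node_a) | is.na(edges$node_b))
  if (length(bad) > 0) {
    stop("malformed edge row(s) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  kept <- edges |>
    dplyr::filter(.data$score >= min_score,
                  .data$node_a != .data$node_b) |>
    dplyr::mutate(
      lo = ifelse(.data$node_a < .data$node_b, .data$node_a, .data$node_b),
      hi = ifelse(.data$node_a < .data$node_b, .data$node_b, .data$node_a)
    ) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(score = suppressWarnings(max(.data$score)),
                     .groups = "drop") |>
    dplyr::filter(is.finite(.data$score))
  all_nodes <- sort(unique(c(kept$lo, kept$hi, keep_nodes)))
  g <- igraph::graph_from_data_frame(
    kept[, c("lo", "hi", "score")],
    directed = FALSE,
    vertices = data.frame(name = all_nodes)
  )
  nodes <- tibble::tibble(
    gene = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    component = as.integer(igraph::components(g)$membership)
  )
  structure(list(graph = g, nodes = nodes, n_edges = igraph::ecount(g)),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), x$n_edges, max(x$nodes$component)))
  invisible(x)
}

#' Rank hub genes by connectivity
#'
#' Hubs are the most connected nodes; ties break alphabetically so the
#' ranking is invariant to input row order. Betweenness centrality is
#' available as an alternative criterion.
#'
#' @param net A [build_network()] result.
#' @param top_n Number of hubs to return (default 10).
#' @param by `"degree"` (default) or `"betweenness"`.
#' @return A tibble `gene`, `degree`, `component` (plus `betweenness`
#'   when requested), ordered by the criterion descending.
#' @export
rank_hubs <- function(net, top_n = 10, by = c("degree", "betweenness")) {
  by <- match.arg(by)
  stopifnot(inherits(net, "ppi_network"))
  nodes <- net$nodes
  if (by == "betweenness") {
    nodes$betweenness <- igraph::betweenness(net$graph)
    nodes <- dplyr::arrange(nodes, dplyr::desc(.data$betweenness),
                            .data$gene)
  } else {
    nodes <- dplyr::arrange(nodes, dplyr::desc(.data$degree), .data$gene)
  }
  utils::head(nodes, top_n)
}

#' Read a STRING-style edge list TSV
#'
#' Columns `node_a`, `node_b`, `score`.
#' @param path File path.
#' @return A tibble.
#' @export
read_edgelist <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    node_a = readr::col_character(),
                    node_b = readr::col_character(),
                    score = readr::col_double()
                  ))
}
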