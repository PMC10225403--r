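# Simple undirected graph layer over igraph: construction from a
# deduplicated edge list plus the neighborhood/subgraph queries the
# downstream statistics need. Edge scores are dropped here on purpose --
# every statistic in the pipeline (degree, neighborhood counts, MCODE
# weighting, hub calls) is purely topological; scores stay in the
# edge_list for export.

#' Build a PPI network from a deduplicated edge list
#'
#' @param edges A deduplicated `edge_list` (see [deduplicate()]). Passing a
#'   non-deduplicated list is an error: duplicate records would silently
#'   double edge counts and every downstream degree statistic.
#' @return An undirected, simple `igraph` graph whose vertex names are the
#'   protein IDs.
#' @export
build_graph <- function(edges) {
  stopifnot(inherits(edges, "edge_list"))
  assert_that(is_deduplicated(edges),
              "edges must be deduplicated before building a graph (see deduplicate())")
  df <- as.data.frame(edges)
  if (nrow(df) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(df[, c("protein_a", "protein_b")],
                                     directed = FALSE)
  stopifnot(!igraph::any_multiple(g), !any(igraph::which_loop(g)))
  g
}

#' Neighborhood of a node
#'
#' All nodes at path distance 1..`radius` from `u`; `u` itself is excluded.
#'
#' @param network An `igraph` network.
#' @param u Node ID (vertex name).
#' @param radius Maximum path distance (>= 1).
#' @return Sorted character vector of neighbor IDs.
#' @export
ppi_neighborhood <- function(network, u, radius = 1L) {
  assert_that(radius >= 1, "`radius` must be >= 1")
  assert_that(u %in% igraph::V(network)$name,
              sprintf("unknown node: %s", u))
  nb <- igraph::ego(network, order = radius, nodes = u, mindist = 1L)[[1L]]
  sort(nb$name)
}

#' Induced subgraph on a node set
#'
#' @param network An `igraph` network.
#' @param keep Character vector of node IDs to keep. IDs absent from the
#'   network are ignored with a warning.
#' @return The induced `igraph` subgraph (all edges with both endpoints in
#'   `keep`).
#' @export
induced_ppi_subgraph <- function(network, keep) {
  keep <- unique(as.character(keep))
  nodes <- igraph::V(network)$name
  unknown <- setdiff(keep, nodes)
  if (length(unknown) > 0L) {
    warning(sprintf("%d node ID(s) not in network ignored", length(unknown)),
            call. = FALSE)
  }
  igraph::induced_subgraph(network, intersect(keep, nodes))
}

#' Write a graph in GraphML format
#'
#' Cytoscape-importable export of a network, module or sub-module.
#'
#' @param network An `igraph` network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
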