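#' Directed acyclic graph helpers for path models
#'
#' Small internal toolkit for the causal graphs used by both the synthetic
#' generator and the piecewise SEM fitter.  Edges are stored as a data frame
#' with columns `from` and `to` (and optionally `coef`).
#'
#' @name dag-helpers
#' @keywords internal
NULL

dag_nodes <- function(edges) {
  unique(c(edges$from, edges$to))
}

dag_parents <- function(edges, node) {
  edges$from[edges$to == node]
}

#' Topologically sort the nodes of an edge list
#'
#' Kahn's algorithm; errors if the graph has a directed cycle, which also
#' serves as the acyclicity check for path-model specifications.
#'
#' @param edges data frame with `from`/`to` columns.
#' @param nodes optional character vector of nodes (isolated nodes allowed).
#' @return character vector of nodes in topological order.
#' @keywords internal
dag_topo_sort <- function(edges, nodes = NULL) {
  nodes <- unique(c(nodes, dag_nodes(edges)))
  indeg <- vapply(nodes, function(v) sum(edges$to == v), integer(1))
  order <- character(0)
  avail <- nodes[indeg == 0]
  while (length(avail) > 0) {
    v <- avail[1]            # stable: keep declaration order
    avail <- avail[-1]
    order <- c(order, v)
    for (w in edges$to[edges$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) != length(nodes)) {
    stop("path model contains a directed cycle among: ",
         paste(setdiff(nodes, order), collapse = ", "), call. = FALSE)
  }
  order
}

#' Enumerate all directed paths between two nodes
#'
#' Depth-first enumeration of simple directed paths; used by the effect
#' decomposition, where the effect along a path is the product of the
#' standardized coefficients of its edges.
#'
#' @return list of character vectors (node sequences from `from` to `to`).
#' @keywords internal
dag_all_paths <- function(edges, from, to) {
  paths <- list()
  walk <- function(node, trail) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- trail
      return(invisible())
    }
    for (nxt in edges$to[edges$from == node]) {
      if (!(nxt %in% trail)) walk(nxt, c(trail, nxt))
    }
  }
  walk(from, from)
  paths
}
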