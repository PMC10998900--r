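#' Degree and strength table
#'
#' Per-node accounting on a directed weighted graph: the undirected skeleton
#' degree `k` (number of distinct neighbors, ignoring direction and
#' multiplicity), the weighted in-strength `s_in`, out-strength `s_out`, and
#' total strength `s = s_in + s_out`. The strengths satisfy the conservation
#' identity `sum(s_out) == sum(s_in) == total edge weight`.
#'
#' @param g Directed weighted graph.
#' @return A data frame with columns `node`, `k`, `s_in`, `s_out`, `s`.
#' @examples
#' g <- igraph::make_ring(3, directed = TRUE)
#' igraph::E(g)$weight <- 1
#' degree_table(g)
#' @export
degree_table <- function(g) {
  .check_dwgraph(g)
  if (igraph::vcount(g) == 0L) stop("graph has no nodes", call. = FALSE)
  skel <- igraph::as_undirected(g, mode = "collapse")
  data.frame(
    node = .node_names(g),
    k = as.integer(igraph::degree(skel)),
    s_in = igraph::strength(g, mode = "in"),
    s_out = igraph::strength(g, mode = "out"),
    s = igraph::strength(g, mode = "all"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Single-source shortest-path distances over edge lengths
#'
#' Dijkstra distances from (`direction = "out"`) or to (`direction = "in"`)
#' a source node, using the `length` edge attribute assigned by
#' [compute_lengths()]. `direction = "in"` traverses the transposed graph,
#' i.e. returns `d(node, source)` for every node.
#'
#' @param g Directed weighted graph with edge lengths.
#' @param source A single node identifier (name or index).
#' @param direction `"out"` for `d(source, node)`, `"in"` for
#'   `d(node, source)`.
#' @param cutoff Optional length; nodes farther than `cutoff` are omitted.
#' @return Named numeric vector of finite distances for reachable nodes
#'   (always includes `d(source, source) = 0`).
#' @export
shortest_paths_from <- function(g, source, direction = c("out", "in"),
                                cutoff = NULL) {
  direction <- match.arg(direction)
  .check_dwgraph(g, need_lengths = TRUE)
  v <- .resolve_nodes(g, source)
  if (length(v) != 1L) stop("`source` must be a single node", call. = FALSE)
  d <- igraph::distances(g, v = v, mode = direction,
                         weights = igraph::E(g)$length,
                         algorithm = "dijkstra")[1L, ]
  names(d) <- .node_names(g)
  d <- d[is.finite(d)]
  if (!is.null(cutoff)) d <- d[d <= cutoff]
  d
}

#' Graph diameter over edge lengths
#'
#' The maximum over all ordered node pairs of the finite shortest-path
#' distances (unreachable pairs are ignored). Computed exactly from one
#' single-source run per node. A single-node or edgeless graph has
#' diameter 0.
#'
#' @param g Directed weighted graph with edge lengths.
#' @return A single non-negative number.
#' @export
graph_diameter <- function(g) {
  .check_dwgraph(g, need_lengths = TRUE)
  if (igraph::vcount(g) <= 1L || igraph::ecount(g) == 0L) return(0)
  d <- igraph::distances(g, mode = "out", weights = igraph::E(g)$length,
                         algorithm = "dijkstra")
  m <- suppressWarnings(max(d[is.finite(d)]))
  if (!is.finite(m)) 0 else m
}

#' Minimum edge length
#'
#' Smallest assigned edge length; the lower end of the radius bracket used
#' by [optimize_radius()].
#'
#' @param g Directed weighted graph with edge lengths.
#' @return A single non-negative number.
#' @export
min_edge_length <- function(g) {
  .check_dwgraph(g, need_lengths = TRUE)
  if (igraph::ecount(g) == 0L) return(0)
  min(igraph::E(g)$length)
}
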