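#' Edge-length recipe
#'
#' Declarative specification mapping edge weights (and, for
#' `transform = "distance"`, per-edge geometric distances) to the positive
#' edge lengths used for shortest paths. The length of the edge
#' \eqn{i \to j} is \eqn{l_{ij} = f(x) / C_{ij}} when `use_ecc = TRUE` and
#' \eqn{f(x)} otherwise, where \eqn{C_{ij}} is the edge clustering
#' coefficient and
#' \itemize{
#'   \item `neglog`: \eqn{f(w) = -\ln w} — weights in `(0, 1]` interpreted
#'     as transmission probabilities, so path lengths add as
#'     log-probabilities;
#'   \item `inverse`: \eqn{f(w) = 1/w} — weights interpreted as connection
#'     strengths;
#'   \item `distance`: \eqn{f(d) = d} — the geometric edge distance is the
#'     length;
#'   \item `identity`: \eqn{f(w) = w} — weights already are lengths.
#' }
#' Any exact zero raw length (e.g. `neglog` at `w = 1`) is replaced by the
#' small positive floor `epsilon`, keeping all lengths strictly positive.
#'
#' @param transform One of `"neglog"`, `"inverse"`, `"distance"`,
#'   `"identity"`.
#' @param use_ecc Divide by the edge clustering coefficient (default
#'   `TRUE`).
#' @param normalize Pre-divide all weights by the maximum weight (required
#'   for `neglog` when weights exceed 1).
#' @param epsilon Zero-length floor; `NULL` (default) means
#'   `1e-12 * median(positive raw lengths)`.
#' @return An object of class `voronoi_length_spec`.
#' @seealso [compute_lengths()]
#' @export
length_spec <- function(transform = c("neglog", "inverse", "distance", "identity"),
                        use_ecc = TRUE, normalize = FALSE, epsilon = NULL) {
  transform <- match.arg(transform)
  if (!is.null(epsilon) && (!is.numeric(epsilon) || epsilon <= 0))
    stop("`epsilon` must be a positive number", call. = FALSE)
  structure(list(transform = transform, use_ecc = isTRUE(use_ecc),
                 normalize = isTRUE(normalize), epsilon = epsilon),
            class = "voronoi_length_spec")
}

#' @export
print.voronoi_length_spec <- function(x, ...) {
  cat("Edge-length spec: f =", x$transform,
      if (x$use_ecc) "/ ECC" else "(no ECC)",
      if (x$normalize) ", weights normalized" else "",
      "\n")
  invisible(x)
}

# Edge clustering coefficients for all edges, on the undirected simple
# skeleton: C = (z + 1) / max(1, min(k_i - 1, k_j - 1)) where z counts
# common skeleton neighbors. The denominator is clamped to 1 for pendant
# endpoints (skeleton degree 1), keeping C finite and positive.
.edge_ecc_all <- function(g) {
  skel <- igraph::as_undirected(g, mode = "collapse")
  A <- igraph::as_adjacency_matrix(skel, sparse = TRUE)
  A@x[] <- 1
  k <- Matrix::rowSums(A)
  Z <- A %*% A
  el <- igraph::as_edgelist(g, names = FALSE)
  z <- Z[el]
  denom <- pmax(1, pmin(k[el[, 1L]] - 1, k[el[, 2L]] - 1))
  as.numeric((z + 1) / denom)
}

#' Edge clustering coefficient
#'
#' The edge clustering coefficient (ECC) of the edge \eqn{(n_i, n_j)} on
#' the undirected simple skeleton of the graph:
#' \deqn{C_{ij} = \frac{z(n_i, n_j) + 1}{\min[k(n_i) - 1,\, k(n_j) - 1]},}
#' where \eqn{z} is the number of common neighbors (triangles through the
#' edge) and \eqn{k} the skeleton degree. Edge weights and directions are
#' ignored. When an endpoint has skeleton degree 1 the denominator is
#' clamped to 1, so pendant edges get \eqn{C = z + 1 = 1}.
#'
#' @param g Directed weighted graph.
#' @param from,to Endpoints of an existing edge (either direction of a
#'   reciprocal pair gives the same value). If both are `NULL`, the ECC of
#'   every edge is returned in edge order.
#' @return A positive number, or a vector over all edges.
#' @export
edge_clustering_coefficient <- function(g, from = NULL, to = NULL) {
  .check_dwgraph(g)
  cc <- .edge_ecc_all(g)
  if (is.null(from) && is.null(to)) return(cc)
  vi <- .resolve_nodes(g, from)
  vj <- .resolve_nodes(g, to)
  eid <- suppressWarnings(igraph::get_edge_ids(g, c(vi, vj), error = FALSE))
  if (eid == 0L)
    eid <- suppressWarnings(igraph::get_edge_ids(g, c(vj, vi), error = FALSE))
  if (eid == 0L)
    stop("no edge between ", from, " and ", to, call. = FALSE)
  cc[eid]
}

#' Normalize edge weights to (0, 1]
#'
#' Divides every edge weight by the global maximum, so the largest weight
#' becomes exactly 1 and the weight ordering is preserved. Required before
#' the `neglog` transform when raw weights exceed 1.
#'
#' @param g Directed weighted graph with at least one edge.
#' @return The graph with rescaled `weight` edge attribute.
#' @export
normalize_weights <- function(g) {
  .check_dwgraph(g)
  if (igraph::ecount(g) == 0L) stop("graph has no edges", call. = FALSE)
  w <- igraph::E(g)$weight
  igraph::E(g)$weight <- w / max(w)
  g
}

#' Compute edge lengths from weights and local topology
#'
#' Fills the `length` edge attribute according to a [length_spec()]:
#' \eqn{l_{ij} = f(x)/C_{ij}} (or \eqn{f(x)} without the ECC), with zero
#' raw lengths floored at `epsilon`. See [length_spec()] for the available
#' transforms.
#'
#' @param g Directed weighted graph.
#' @param spec A [length_spec()]; the default is the inverse-weight
#'   transform with ECC.
#' @return The graph with a strictly positive `length` edge attribute.
#' @examples
#' g <- igraph::make_ring(4, directed = TRUE)
#' igraph::E(g)$weight <- c(1, 2, 4, 8)
#' igraph::E(compute_lengths(g, length_spec("inverse")))$length
#' @export
compute_lengths <- function(g, spec = length_spec("inverse")) {
  .check_dwgraph(g)
  if (!inherits(spec, "voronoi_length_spec"))
    stop("`spec` must be a length_spec()", call. = FALSE)
  if (igraph::ecount(g) == 0L) {
    igraph::E(g)$length <- numeric(0)
    return(g)
  }
  if (spec$normalize) g <- normalize_weights(g)
  w <- igraph::E(g)$weight
  x <- switch(spec$transform,
    neglog = {
      if (any(w > 1))
        stop("neglog transform requires weights in (0, 1]; ",
             "use length_spec(..., normalize = TRUE) or normalize_weights()",
             call. = FALSE)
      -log(w)
    },
    inverse = 1 / w,
    identity = w,
    distance = {
      d <- igraph::E(g)$distance
      if (is.null(d))
        stop("distance transform requires a `distance` edge attribute ",
             "(read_edge_list(..., has_distance = TRUE))", call. = FALSE)
      d
    })
  if (spec$use_ecc) x <- x / .edge_ecc_all(g)
  eps <- spec$epsilon
  if (is.null(eps)) {
    pos <- x[x > 0]
    eps <- if (length(pos)) 1e-12 * median(pos) else 1e-12
  }
  x[x == 0] <- eps
  if (any(!is.finite(x)) || any(x <= 0))
    stop("computed lengths must be finite and positive", call. = FALSE)
  igraph::E(g)$length <- x
  g
}
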