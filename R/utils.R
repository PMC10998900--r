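# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.node_names <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else nm
}

.check_dwgraph <- function(g, need_lengths = FALSE) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object", call. = FALSE)
  if (!igraph::is_directed(g)) stop("`g` must be a directed graph", call. = FALSE)
  w <- igraph::E(g)$weight
  if (igraph::ecount(g) > 0) {
    if (is.null(w)) stop("`g` must carry a positive `weight` edge attribute", call. = FALSE)
    if (any(!is.finite(w)) || any(w <= 0))
      stop("all edge weights must be finite and strictly positive", call. = FALSE)
    if (any(igraph::which_loop(g)))
      stop("`g` must not contain self-loops (read_edge_list() drops them)", call. = FALSE)
    if (igraph::any_multiple(g))
      stop("`g` must not contain parallel edges (read_edge_list() aggregates them)", call. = FALSE)
  }
  if (need_lengths) {
    l <- igraph::E(g)$length
    if (igraph::ecount(g) > 0 && is.null(l))
      stop("edge lengths are missing: run compute_lengths() first", call. = FALSE)
    if (igraph::ecount(g) > 0 && (any(!is.finite(l)) || any(l < 0)))
      stop("edge lengths must be finite and non-negative", call. = FALSE)
  }
  invisible(g)
}

# Resolve node identifiers (names or indices) to vertex indices.
.resolve_nodes <- function(g, nodes) {
  nm <- .node_names(g)
  if (is.numeric(nodes)) {
    idx <- as.integer(nodes)
    if (any(idx < 1L | idx > igraph::vcount(g)))
      stop("node index out of range", call. = FALSE)
    return(idx)
  }
  idx <- match(as.character(nodes), nm)
  if (anyNA(idx))
    stop("unknown node(s): ", paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

# Run `code` under a temporary RNG seed without disturbing the caller's RNG
# stream; a NULL seed leaves the RNG alone.
.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
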