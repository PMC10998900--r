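# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: literal formulas, exhaustive enumeration, and the
# cubic all-pairs recursion, never the code paths they certify.

# All-pairs shortest-path matrix by the Floyd-Warshall recursion over the
# `length` edge attribute.
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  len <- igraph::E(g)$length
  for (e in seq_len(nrow(el))) {
    D[el[e, 1L], el[e, 2L]] <- min(D[el[e, 1L], el[e, 2L]], len[e])
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  nm <- igraph::V(g)$name
  if (!is.null(nm)) dimnames(D) <- list(nm, nm)
  D
}

# Nearest-generator membership from a full distance matrix, earliest
# generator winning ties; 0 marks nodes with no finite generator distance.
fw_argmin_membership <- function(D, gvids) {
  Dg <- D[, gvids, drop = FALSE]
  owner <- max.col(-Dg, ties.method = "first")
  owner[!is.finite(Dg[cbind(seq_len(nrow(Dg)), owner)])] <- 0L
  owner
}

# Edge clustering coefficient by exhaustive common-neighbor enumeration on
# the undirected simple skeleton.
ecc_brute <- function(g, vi, vj) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    igraph::as_undirected(g, mode = "collapse"))) > 0
  z <- sum(A[vi, ] & A[vj, ])
  k <- rowSums(A)
  (z + 1) / max(1, min(k[vi] - 1, k[vj] - 1))
}

# Literal double sum over all ordered node pairs.
modularity_double_sum <- function(g, memb) {
  nm <- igraph::V(g)$name
  memb <- memb[nm]
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  m <- sum(W)
  s_out <- rowSums(W)
  s_in <- colSums(W)
  q <- 0
  n <- length(memb)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) q <- q + W[i, j] - s_out[i] * s_in[j] / m
    }
  }
  unname(q) / m
}

# Maximum-overlap accuracy by brute force over all one-to-one matchings.
accuracy_brute <- function(a, truth) {
  tab <- unclass(table(a[names(truth)], truth))
  n <- max(dim(tab))
  sq <- matrix(0, n, n)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- max(vapply(perms(seq_len(n)), function(p)
    sum(sq[cbind(seq_len(n), p)]), numeric(1)))
  best / sum(tab)
}

# Random weighted digraph reduced to its largest strongly connected
# component, with inverse-weight lengths attached.
random_sc_graph <- function(n, p = NULL, spec = length_spec("inverse")) {
  if (is.null(p)) p <- min(1, 3 / n + 0.05)
  g <- igraph::sample_gnp(n, p, directed = TRUE)
  comp <- igraph::components(g, "strong")
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 1)
  compute_lengths(g, spec)
}
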