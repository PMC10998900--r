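# Hand-built graphs reused across test files.

# Two unit-weight directed 4-cliques joined by one reciprocal bridge (d-e):
# the planted two-community toy.
two_cliques <- function() {
  clique_edges <- function(v) {
    e <- c()
    for (i in v) for (j in v) if (i != j) e <- c(e, i, j)
    e
  }
  g <- igraph::make_graph(c(clique_edges(1:4), clique_edges(5:8), 4, 5, 5, 4),
                          directed = TRUE)
  igraph::V(g)$name <- letters[1:8]
  igraph::E(g)$weight <- 1
  g
}

# Larger planted toy: two 6-node unit-weight directed cliques plus two
# bridge edges, for radius optimization.
two_cliques6 <- function() {
  clique_edges <- function(v) {
    e <- c()
    for (i in v) for (j in v) if (i != j) e <- c(e, i, j)
    e
  }
  g <- igraph::make_graph(c(clique_edges(1:6), clique_edges(7:12),
                            6, 7, 7, 6), directed = TRUE)
  igraph::V(g)$name <- letters[1:12]
  igraph::E(g)$weight <- 1
  g
}

# Star-of-neighbors construction whose center has exactly m = 24 edges
# inside its closed first-order neighborhood and k = 12 boundary edges:
# center <-> 6 neighbors (12), a double ring among the neighbors (12),
# and one incoming plus one outgoing pendant edge per neighbor (12).
density_example_graph <- function() {
  e <- c()
  for (i in 1:6) e <- c(e, "c", paste0("u", i), paste0("u", i), "c")
  nxt <- function(i, s) paste0("u", (i + s - 1) %% 6 + 1)
  for (i in 1:6) e <- c(e, paste0("u", i), nxt(i, 1), paste0("u", i), nxt(i, 2))
  for (i in 1:6) e <- c(e, paste0("x", 2 * i - 1), paste0("u", i),
                        paste0("u", i), paste0("x", 2 * i))
  g <- igraph::make_graph(e, directed = TRUE)
  igraph::E(g)$weight <- 1
  g
}

# Tie fixture: node t is exactly equidistant from the two generators a, b.
tie_graph <- function() {
  g <- igraph::make_graph(c("t", "a", "t", "b", "a", "t", "b", "t"),
                          directed = TRUE)
  igraph::E(g)$weight <- 1
  compute_lengths(g, length_spec("identity", use_ecc = FALSE))
}

# Small benchmark instance shared by unit tests (cached per session).
.small_bench_env <- new.env(parent = emptyenv())
small_bench <- function() {
  if (is.null(.small_bench_env$inst)) {
    spec <- benchmark_spec(N = 300L, k_mean = 20, k_max = 60L, mu = 0.3,
                           c_min = 20L, c_max = 75L, seed = 11L)
    bench <- generate_planted_digraph(spec)
    g <- sample_weights(bench$graph, bench$membership,
                        weight_dist_spec("truncpower", alpha = 0.7),
                        weight_dist_spec("truncpower", alpha = 0.3),
                        seed = 12L)
    g <- compute_lengths(g, length_spec("inverse"))
    .small_bench_env$inst <- list(g = g, truth = bench$membership,
                                  spec = spec)
  }
  .small_bench_env$inst
}
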