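test_that("degenerate generator sets: everyone or a single anchor", {
  g <- compute_lengths(two_cliques(), length_spec("inverse"))
  all_gens <- user_generators(g, igraph::V(g)$name)
  p <- voronoi_assign(g, all_gens)
  expect_equal(p$n_clusters, igraph::vcount(g))
  expect_equal(unname(p$distances), rep(0, igraph::vcount(g)))

  one <- user_generators(g, "a")
  p1 <- voronoi_assign(g, one)
  expect_equal(p1$n_clusters, 1L)
  expect_error(voronoi_assign(g, structure(list(vids = integer(0)),
                                           class = "generator_set")),
               "empty")
})

test_that("assignment equals the Floyd-Warshall argmin oracle", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      g <- random_sc_graph(40)
      D <- fw_distances(g)
      nm <- igraph::V(g)$name
      gvids <- sort(sample(igraph::vcount(g), 4))
      gens <- user_generators(g, nm[gvids])
      p <- voronoi_assign(g, gens, method = "naive")
      expect_equal(unname(p$membership), fw_argmin_membership(D, gvids))
      expect_equal(unname(p$distances),
                   unname(apply(D[, gvids, drop = FALSE], 1, min)),
                   tolerance = 1e-12)
    }
  })
})

test_that("pruned search reproduces the naive assignment exactly", {
  withr::with_seed(29, {
    for (rep in 1:30) {
      n <- sample(10:120, 1)
      g <- random_sc_graph(n)
      ng <- sample(seq_len(min(8, igraph::vcount(g))), 1)
      gens <- user_generators(g, sample(igraph::V(g)$name, ng))
      p1 <- voronoi_assign(g, gens, method = "naive")
      p2 <- voronoi_assign(g, gens, method = "pruned")
      expect_identical(p1$membership, p2$membership)
      expect_equal(p1$distances, p2$distances, tolerance = 1e-12)
    }
  })
})

test_that("assignment agrees with the independent igraph implementation", {
  withr::with_seed(37, {
    for (rep in 1:5) {
      g <- random_sc_graph(60)
      gvids <- sort(sample(igraph::vcount(g), 5))
      gens <- user_generators(g, igraph::V(g)$name[gvids])
      p <- voronoi_assign(g, gens)
      vc <- igraph::voronoi_cells(g, gvids, weights = igraph::E(g)$length,
                                  mode = "in", tiebreaker = "first")
      expect_equal(unname(p$membership), as.integer(vc$membership) + 1L)
    }
  })
})

test_that("nearest-generator optimality certificate holds post hoc", {
  withr::with_seed(41, {
    g <- random_sc_graph(50)
    gens <- user_generators(g, sample(igraph::V(g)$name, 5))
    p <- voronoi_assign(g, gens)
    for (b in seq_along(gens$vids)) {
      d_b <- shortest_paths_from(g, gens$nodes[b], "in")[names(p$distances)]
      expect_true(all(p$distances <= d_b + 1e-9, na.rm = TRUE))
    }
    # generators own their cells at distance zero
    expect_equal(unname(p$membership[gens$nodes]), seq_along(gens$vids))
    expect_equal(unname(p$distances[gens$nodes]), rep(0, 5))
  })
})

test_that("equidistant nodes are flagged as ties and resolved deterministically", {
  g <- tie_graph()
  gens <- user_generators(g, c("a", "b"))
  p <- voronoi_assign(g, gens)
  expect_equal(p$tie_count, 1L)
  expect_true(p$ties[["t"]])
  expect_equal(p$membership[["t"]], 1L)  # earliest generator wins
  ck <- contiguity_check(g, p)
  expect_length(ck$violations, 0L)
  p_rand <- voronoi_assign(g, gens, ties = "random", seed = 4L)
  expect_true(p_rand$membership[["t"]] %in% c(1L, 2L))
})

test_that("nodes reaching no generator become singleton clusters", {
  # c -> d is separate; generator a is unreachable from c, d
  g <- igraph::make_graph(c("a", "b", "b", "a", "c", "d"), directed = TRUE)
  igraph::E(g)$weight <- 1
  g <- compute_lengths(g, length_spec("identity", use_ecc = FALSE))
  gens <- user_generators(g, "a")
  expect_warning(p <- voronoi_assign(g, gens), "singleton")
  expect_equal(p$n_clusters, 3L)
  expect_setequal(p$extra_singletons, c("c", "d"))
  expect_equal(p$membership[["b"]], 1L)
})

test_that("tie-free partitions are contiguous", {
  withr::with_seed(43, {
    for (rep in 1:5) {
      g <- random_sc_graph(50)
      gens <- select_generators(g, runif(1, min_edge_length(g),
                                         graph_diameter(g)))
      p <- voronoi_assign(g, gens)
      ck <- contiguity_check(g, p)
      expect_length(ck$violations, 0L)
    }
  })
})
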