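test_that("ECC on forced topologies: triangle and square", {
  tri <- igraph::make_ring(3, directed = TRUE)
  igraph::V(tri)$name <- c("a", "b", "c")
  igraph::E(tri)$weight <- 1
  # z = 1 common neighbor, degrees 2: C = (1+1)/1 = 2
  expect_equal(edge_clustering_coefficient(tri, "a", "b"), 2)

  sq <- igraph::make_ring(4, directed = TRUE)
  igraph::E(sq)$weight <- 1
  expect_equal(edge_clustering_coefficient(sq), rep(1, 4))  # triangle-free
})

test_that("ECC equals exhaustive common-neighbor enumeration", {
  withr::with_seed(5, {
    g <- igraph::sample_gnp(20, 0.3, directed = TRUE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- paste0("n", 1:20)
    igraph::E(g)$weight <- 1
    cc <- edge_clustering_coefficient(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    brute <- vapply(seq_len(nrow(el)), function(e)
      ecc_brute(g, el[e, 1L], el[e, 2L]), numeric(1))
    expect_equal(cc, brute, tolerance = 1e-12)
  })
})

test_that("ECC is symmetric on reciprocal edges and clamps pendant edges", {
  g <- igraph::make_graph(c("a", "b", "b", "a", "b", "c"), directed = TRUE)
  igraph::E(g)$weight <- 1
  expect_equal(edge_clustering_coefficient(g, "a", "b"),
               edge_clustering_coefficient(g, "b", "a"))
  # b-c is pendant (k_c = 1): denominator clamped, C = z + 1 = 1
  expect_equal(edge_clustering_coefficient(g, "b", "c"), 1)
})

test_that("length arithmetic matches the transform definitions", {
  # directed triangle: the a-b edge has z = 1 and endpoint degrees 2, so
  # C(a,b) = 2
  g <- igraph::make_graph(c("a", "b", "b", "c", "c", "a"), directed = TRUE)
  igraph::E(g)$weight <- c(0.5, 1, 1)
  gl <- compute_lengths(g, length_spec("neglog"))
  eid <- igraph::get_edge_ids(g, c("a", "b"))
  expect_equal(igraph::E(gl)$length[eid], log(2) / 2, tolerance = 1e-9)

  # w = 1 with neglog gives raw 0, floored at a tiny positive epsilon
  expect_true(all(igraph::E(gl)$length > 0))
  eps <- igraph::E(gl)$length[-eid]
  expect_true(all(eps < 1e-9))

  g2 <- g
  igraph::E(g2)$weight <- c(4, 1, 1)
  gl2 <- compute_lengths(g2, length_spec("inverse"))
  expect_equal(igraph::E(gl2)$length[eid], (1 / 4) / 2, tolerance = 1e-12)
})

test_that("neglog refuses weights above 1 unless normalized", {
  g <- two_cliques()
  igraph::E(g)$weight <- 2
  expect_error(compute_lengths(g, length_spec("neglog")), "normalize")
  gl <- compute_lengths(g, length_spec("neglog", normalize = TRUE))
  expect_true(all(igraph::E(gl)$length > 0))
})

test_that("distance transform needs the distance attribute", {
  g <- two_cliques()
  expect_error(compute_lengths(g, length_spec("distance")), "distance")
  igraph::E(g)$distance <- 3
  gl <- compute_lengths(g, length_spec("distance", use_ecc = FALSE))
  expect_equal(igraph::E(gl)$length, rep(3, igraph::ecount(g)))
})

test_that("weight normalization maps onto (0, 1] and preserves order", {
  g <- igraph::make_graph(c("a", "b", "b", "c", "c", "a"), directed = TRUE)
  igraph::E(g)$weight <- c(2, 4, 8)
  gn <- normalize_weights(g)
  expect_equal(igraph::E(gn)$weight, c(0.25, 0.5, 1))
  expect_identical(igraph::E(normalize_weights(gn))$weight,
                   igraph::E(gn)$weight)  # idempotent at the fixed point
  withr::with_seed(8, {
    w <- runif(100, 0.01, 50)
    g2 <- igraph::sample_gnp(25, 0.2, directed = TRUE)
    g2 <- igraph::simplify(g2)
    igraph::E(g2)$weight <- w[seq_len(igraph::ecount(g2))]
    wn <- igraph::E(normalize_weights(g2))$weight
    expect_equal(max(wn), 1)
    expect_equal(order(wn), order(igraph::E(g2)$weight))
  })
})

test_that("lengths are antitone in weight at equal ECC", {
  withr::with_seed(21, {
    g <- random_sc_graph(30)
    for (tr in c("neglog", "inverse")) {
      spec <- length_spec(tr, use_ecc = TRUE, normalize = (tr == "neglog"))
      gl <- compute_lengths(g, spec)
      cc <- edge_clustering_coefficient(gl)
      w <- igraph::E(gl)$weight
      l <- igraph::E(gl)$length
      for (cval in unique(cc)) {
        idx <- which(cc == cval)
        if (length(idx) >= 2) {
          o <- order(w[idx])
          expect_true(all(diff(l[idx][o]) <= 1e-12))
        }
      }
    }
  })
})

test_that("identity transform with unit weights reproduces hop distances", {
  withr::with_seed(13, {
    g <- random_sc_graph(20)
    igraph::E(g)$weight <- 1
    g <- compute_lengths(g, length_spec("identity", use_ecc = FALSE))
    hops <- igraph::distances(g, v = 1, mode = "out", weights = NA)[1L, ]
    d <- shortest_paths_from(g, igraph::V(g)$name[1L], "out")
    expect_equal(unname(d[names(hops)]), unname(hops))
  })
})
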