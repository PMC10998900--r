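#' Weighted local relative density
#'
#' For each node \eqn{i}, let the (closed) first-order neighborhood be
#' \eqn{\{i\}} together with all skeleton neighbors of \eqn{i} (direction
#' ignored). With \eqn{m} the number of directed edges whose two endpoints
#' both lie in the neighborhood (edges between two neighbors count as
#' inside), and \eqn{k} the number of directed edges crossing the
#' neighborhood boundary, the weighted local relative density is
#' \deqn{\rho_i = s_i \frac{m}{m + k},}
#' where \eqn{s_i} is the node's total (in + out) strength. Isolated nodes
#' (\eqn{m + k = 0}) get \eqn{\rho = 0}.
#'
#' Generator (seed) nodes for the Voronoi partition are chosen as local
#' maxima of \eqn{\rho} — see [select_generators()].
#'
#' @param g Directed weighted graph.
#' @param nodes Optional node identifiers to restrict the result to.
#' @return A data frame with columns `node`, `rho`, `m`, `k`, `s`.
#' @export
local_relative_density <- function(g, nodes = NULL) {
  .check_dwgraph(g)
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph has no nodes", call. = FALSE)
  skel <- igraph::as_undirected(g, mode = "collapse")
  A <- igraph::as_adjacency_matrix(skel, sparse = TRUE)
  A@x[] <- 1
  B <- A + Matrix::Diagonal(n)                 # closed-neighborhood indicator
  Ad <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  Ad@x[] <- 1
  # m_i = number of directed edges with both endpoints in the neighborhood:
  # sum_{u,v} B[i,u] Ad[u,v] B[i,v]
  m <- Matrix::rowSums((B %*% Ad) * B)
  # each directed edge with >=1 endpoint in the neighborhood contributes its
  # endpoint count to t_i; boundary edges contribute exactly once
  degs <- igraph::degree(g, mode = "out") + igraph::degree(g, mode = "in")
  t_i <- as.numeric(B %*% degs)
  k <- t_i - 2 * m
  s <- igraph::strength(g, mode = "all")
  rho <- ifelse(m + k > 0, s * m / (m + k), 0)
  out <- data.frame(node = .node_names(g), rho = rho,
                    m = as.integer(round(m)), k = as.integer(round(k)),
                    s = s, row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(nodes)) out <- out[.resolve_nodes(g, nodes), , drop = FALSE]
  out
}

.generator_set <- function(g, vids, R, provenance) {
  structure(list(nodes = .node_names(g)[vids], vids = as.integer(vids),
                 R = R, provenance = provenance),
            class = "generator_set")
}

#' @export
print.generator_set <- function(x, ...) {
  cat("Generator set:", length(x$vids), "node(s) [", x$provenance, "]",
      if (!is.null(x$R) && is.finite(x$R)) paste0("R = ", signif(x$R, 6)) else "",
      "\n")
  cat(" ", paste(head(x$nodes, 10L), collapse = ", "),
      if (length(x$nodes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.generator_set <- function(x) length(x$vids)

#' Select generator nodes by density peaks within radius R
#'
#' Iteratively picks the not-yet-excluded node with the highest weighted
#' local relative density as the next generator, then excludes every
#' remaining node within shortest-path distance `R` of it (distances taken
#' along outgoing paths from the generator by default). The procedure stops
#' when every node is selected or excluded, so any two generators are more
#' than `R` apart. Density ties are broken toward the earlier node index
#' for determinism.
#'
#' @param g Directed weighted graph with edge lengths.
#' @param R Exclusion radius, `R > 0`. Larger `R` means fewer, larger
#'   Voronoi cells.
#' @param direction `"out"` (default): the exclusion ball around a
#'   generator \eqn{\gamma} is \eqn{\{j : d(\gamma, j) \le R\}}; `"in"`
#'   uses \eqn{d(j, \gamma)} instead.
#' @param density Optional precomputed [local_relative_density()] table
#'   (avoids recomputation in radius sweeps).
#' @return A `generator_set` with nodes in selection order (decreasing
#'   density) and the `R` used.
#' @export
select_generators <- function(g, R, direction = c("out", "in"),
                              density = NULL) {
  direction <- match.arg(direction)
  .check_dwgraph(g, need_lengths = TRUE)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("`R` must be a single positive number", call. = FALSE)
  n <- igraph::vcount(g)
  if (is.null(density)) density <- local_relative_density(g)
  rho <- density$rho
  len <- igraph::E(g)$length

  # below the minimum edge length every exclusion ball is its own center:
  # every node becomes a generator, in decreasing-density order
  if (igraph::ecount(g) == 0L || R < min(len)) {
    ord <- order(-rho, seq_len(n))
    return(.generator_set(g, ord, R, "selected"))
  }

  alive <- rep(TRUE, n)
  gens <- integer(0)
  ord <- order(-rho, seq_len(n))  # ties -> smaller node index
  while (any(alive)) {
    pick <- ord[alive[ord]][1L]
    gens <- c(gens, pick)
    d <- igraph::distances(g, v = pick, mode = direction, weights = len,
                           algorithm = "dijkstra")[1L, ]
    alive[d <= R] <- FALSE
    alive[pick] <- FALSE
  }
  .generator_set(g, gens, R, "selected")
}

#' Use a predefined generator set
#'
#' Wraps user-chosen nodes (e.g. known hubs) as the generator set, in the
#' given order, bypassing density-based selection.
#'
#' @param g Directed weighted graph.
#' @param nodes Distinct node identifiers; at least one.
#' @return A `generator_set` with provenance `"user_supplied"`.
#' @export
user_generators <- function(g, nodes) {
  .check_dwgraph(g)
  if (length(nodes) == 0L)
    stop("at least one generator node is required", call. = FALSE)
  vids <- .resolve_nodes(g, nodes)
  if (anyDuplicated(vids))
    stop("duplicated generator node(s): ",
         paste(unique(nodes[duplicated(vids)]), collapse = ", "),
         call. = FALSE)
  .generator_set(g, vids, NA_real_, "user_supplied")
}
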