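#' Optimize the radius R by directed modularity
#'
#' Evaluates the full pipeline (density-peak generator selection at radius
#' `R`, Voronoi assignment, directed modularity `Q`) over a log-spaced grid
#' of `R` values bracketed between the smallest edge length and the graph
#' diameter, then refines the best bracket with Brent's derivative-free
#' maximization. `Q(R)` is piecewise constant (it only changes when the
#' generator set changes), so the grid pre-scan supplies a reliable bracket
#' and the recorded trace is itself the primary artifact; `grid_size = 0`
#' skips the pre-scan and runs pure Brent over the whole bracket.
#' Evaluations are memoized on the generator set, and equal-`Q` radii
#' resolve toward the smaller `R` (the finer partition).
#'
#' @param g Directed weighted graph with edge lengths.
#' @param grid_size Number of log-spaced grid points (default 32; minimum 3
#'   unless 0).
#' @param tol Brent stopping tolerance on `R`; default
#'   `1e-3 * (R_max - R_min)`.
#' @param direction Seed-selection ball direction, see
#'   [select_generators()].
#' @param assign_direction Assignment direction, see [voronoi_assign()].
#' @param keep_memberships Keep the membership vector of every distinct
#'   evaluation in the trace (needed for NMI-vs-R curves).
#' @return A `radius_sweep`: `trace` data frame with columns `R`,
#'   `n_clusters`, `Q` and (per-row) generator keys, `best_R`, `best_Q`,
#'   `best` (the best `voronoi_partition`), the bracket, and optionally
#'   `memberships` (list parallel to the trace rows).
#' @export
optimize_radius <- function(g, grid_size = 32L, tol = NULL,
                            direction = "out", assign_direction = "in",
                            keep_memberships = TRUE) {
  .check_dwgraph(g, need_lengths = TRUE)
  if (grid_size != 0 && grid_size < 3)
    stop("`grid_size` must be 0 or at least 3", call. = FALSE)
  r_min <- min_edge_length(g)
  r_max <- graph_diameter(g)
  density <- local_relative_density(g)

  memo <- new.env(parent = emptyenv())
  trace <- list()
  eval_R <- function(R) {
    gens <- select_generators(g, R, direction = direction, density = density)
    key <- paste(gens$vids, collapse = ",")
    if (is.null(memo[[key]])) {
      p <- suppressWarnings(
        voronoi_assign(g, gens, direction = assign_direction))
      memo[[key]] <- list(Q = directed_modularity(g, p), p = p)
    }
    rec <- memo[[key]]
    trace[[length(trace) + 1L]] <<- list(R = R, key = key,
                                         n_clusters = rec$p$n_clusters,
                                         Q = rec$Q)
    rec$Q
  }

  if (r_min >= r_max || igraph::ecount(g) == 0L) {
    warning("degenerate radius bracket (R_min >= R_max); ",
            "returning the single evaluable partition", call. = FALSE)
    R1 <- max(r_max, r_min)
    if (R1 <= 0) R1 <- 1
    eval_R(R1)
  } else {
    if (is.null(tol)) tol <- 1e-3 * (r_max - r_min)
    if (grid_size >= 3) {
      grid <- exp(seq(log(r_min), log(r_max), length.out = grid_size))
      qs <- vapply(grid, eval_R, numeric(1))
      best_i <- which.max(qs)  # first max -> smaller R on ties
      lo <- grid[max(1L, best_i - 1L)]
      hi <- grid[min(length(grid), best_i + 1L)]
    } else {
      lo <- r_min; hi <- r_max
    }
    if (hi > lo) optimize(eval_R, interval = c(lo, hi), maximum = TRUE, tol = tol)
  }

  tr <- data.frame(R = vapply(trace, `[[`, numeric(1), "R"),
                   n_clusters = vapply(trace, `[[`, integer(1), "n_clusters"),
                   Q = vapply(trace, `[[`, numeric(1), "Q"),
                   key = vapply(trace, `[[`, character(1), "key"),
                   stringsAsFactors = FALSE)
  o <- order(tr$R)
  tr <- tr[o, , drop = FALSE]
  keep <- !duplicated(tr$R)
  tr <- tr[keep, , drop = FALSE]
  rownames(tr) <- NULL
  # best Q, ties toward the smallest R
  best_row <- which(tr$Q == max(tr$Q))[1L]
  best <- memo[[tr$key[best_row]]]
  out <- list(trace = tr, best_R = tr$R[best_row], best_Q = tr$Q[best_row],
              best = best$p, bracket = c(R_min = r_min, R_max = r_max))
  if (keep_memberships)
    out$memberships <- lapply(tr$key, function(k) memo[[k]]$p$membership)
  structure(out, class = "radius_sweep")
}

#' @export
print.radius_sweep <- function(x, ...) {
  cat("Radius sweep:", nrow(x$trace), "evaluations in [",
      signif(x$bracket[1L], 4), ",", signif(x$bracket[2L], 4), "]\n")
  cat("  best R =", signif(x$best_R, 6), "-> Q =", signif(x$best_Q, 6),
      "with", x$best$n_clusters, "cluster(s)\n")
  invisible(x)
}

#' Find a radius yielding a requested number of clusters
#'
#' Bisects on `R` between the smallest edge length and the diameter seeking
#' a partition with exactly `target_g` clusters. Because the cluster count
#' need not be strictly monotone in `R`, a failed bisection falls back to
#' scanning midpoints of the sorted pairwise-distance multiset inside the
#' final bracket. If no radius achieves `target_g` exactly, the closest
#' achievable partition is returned with a warning.
#'
#' @param g Directed weighted graph with edge lengths.
#' @param target_g Requested number of clusters, between 1 and the node
#'   count.
#' @param max_iter Bisection iterations before falling back to the scan.
#' @param max_scan Cap on the number of fallback candidate radii evaluated.
#' @inheritParams optimize_radius
#' @return A `voronoi_partition` (with the achieved cluster count).
#' @export
fixed_cluster_count <- function(g, target_g, direction = "out",
                                assign_direction = "in",
                                max_iter = 60L, max_scan = 256L) {
  .check_dwgraph(g, need_lengths = TRUE)
  n <- igraph::vcount(g)
  if (target_g < 1 || target_g > n)
    stop("`target_g` must be between 1 and the node count", call. = FALSE)
  density <- local_relative_density(g)
  part_at <- function(R) {
    gens <- select_generators(g, R, direction = direction, density = density)
    suppressWarnings(voronoi_assign(g, gens, direction = assign_direction))
  }
  r_min <- min_edge_length(g)
  r_max <- graph_diameter(g)
  lo <- r_min / 2             # below every edge length -> all singletons
  hi <- max(r_max, r_min) * (1 + 1e-12)
  if (hi <= 0) hi <- 1
  best <- NULL
  consider <- function(p) {
    if (is.null(best) ||
        abs(p$n_clusters - target_g) < abs(best$n_clusters - target_g))
      best <<- p
    p
  }
  p <- consider(part_at(hi))
  if (p$n_clusters == target_g) return(p)
  p <- consider(part_at(lo))
  if (p$n_clusters == target_g) return(p)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p <- consider(part_at(mid))
    if (p$n_clusters == target_g) return(p)
    if (p$n_clusters > target_g) lo <- mid else hi <- mid
  }
  # non-monotone g(R): scan distance-multiset midpoints within the bracket
  if (n <= 2000L) {
    d <- igraph::distances(g, mode = "out", weights = igraph::E(g)$length,
                           algorithm = "dijkstra")
    vals <- sort(unique(d[is.finite(d) & d > 0]))
    cand <- (vals[-1L] + vals[-length(vals)]) / 2
    cand <- cand[cand >= lo & cand <= hi]
    if (length(cand) > max_scan)
      cand <- cand[unique(round(seq(1L, length(cand), length.out = max_scan)))]
    for (R in cand) {
      p <- consider(part_at(R))
      if (p$n_clusters == target_g) return(p)
    }
  }
  warning("no radius yields exactly ", target_g, " clusters; returning ",
          best$n_clusters, call. = FALSE)
  best
}

#' One-call Voronoi community detection
#'
#' Convenience pipeline: computes edge lengths, selects (or accepts)
#' generators, and assigns Voronoi cells, choosing the radius by modularity
#' maximization when `radius = "auto"`.
#'
#' @param g Directed weighted graph.
#' @param spec A [length_spec()] describing the weight-to-length transform.
#' @param radius `"auto"` (maximize modularity), a fixed positive number,
#'   or `NULL` when `generators` are supplied.
#' @param generators Optional node identifiers to use as predefined
#'   generators (bypasses selection).
#' @param ... Passed on to [optimize_radius()].
#' @return A `voronoi_partition`; for `radius = "auto"` the `radius_sweep`
#'   is attached as attribute `"sweep"`.
#' @export
voronoi_communities <- function(g, spec = length_spec("inverse"),
                                radius = "auto", generators = NULL, ...) {
  g <- compute_lengths(g, spec)
  if (!is.null(generators)) {
    gens <- user_generators(g, generators)
    return(voronoi_assign(g, gens))
  }
  if (identical(radius, "auto")) {
    sw <- optimize_radius(g, ...)
    p <- sw$best
    attr(p, "sweep") <- sw
    return(p)
  }
  gens <- select_generators(g, radius)
  voronoi_assign(g, gens)
}
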