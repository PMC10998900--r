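#' Directed weighted modularity
#'
#' The directed, weighted generalization of Newman modularity:
#' \deqn{Q = \frac{1}{m} \sum_{i,j \in V}
#'   \left[w_{ij} - \frac{s_i^{out} s_j^{in}}{m}\right]
#'   \delta_{c_i, c_j},}
#' where \eqn{m} is the total edge weight and \eqn{s^{out}}, \eqn{s^{in}}
#' are weighted out- and in-degrees. Computed by iterating edges for the
#' first term and per-cluster strength sums for the null term, so it is
#' linear in the number of edges. The single-cluster partition always has
#' \eqn{Q = 0}.
#'
#' @param g Directed weighted graph.
#' @param p Partition: a `voronoi_partition` or named membership vector
#'   covering every node of `g`.
#' @return A single number in \eqn{[-1, 1)}.
#' @export
directed_modularity <- function(g, p) {
  .check_dwgraph(g)
  memb <- as_membership(p)
  nm <- .node_names(g)
  idx <- match(nm, names(memb))
  if (anyNA(idx))
    stop("partition does not cover every node of the graph", call. = FALSE)
  memb <- memb[idx]
  w <- igraph::E(g)$weight
  m <- sum(w)
  if (igraph::ecount(g) == 0L || m == 0)
    stop("modularity is undefined on a graph with zero total weight",
         call. = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  intra <- sum(w[memb[el[, 1L]] == memb[el[, 2L]]])
  s_out <- igraph::strength(g, mode = "out")
  s_in <- igraph::strength(g, mode = "in")
  f <- factor(memb)
  null_term <- sum(tapply(s_out, f, sum) * tapply(s_in, f, sum)) / m
  (intra - null_term) / m
}

# Contingency table of two membership vectors over the same node set.
.contingency <- function(a, b) {
  a <- as_membership(a); b <- as_membership(b)
  if (length(a) != length(b) || !setequal(names(a), names(b)))
    stop("partitions must cover the same node set", call. = FALSE)
  b <- b[names(a)]
  table(a, b)
}

#' Normalized mutual information between two partitions
#'
#' NMI with mean-entropy normalization,
#' \eqn{2 I(A;B) / (H(A) + H(B))}, computed from the contingency table
#' with natural logarithms. Identical partitions (up to cluster
#' relabeling) give 1; a non-trivial partition compared against the
#' single-cluster partition gives 0. If both partitions are single-cluster
#' (\eqn{H(A) + H(B) = 0}) the value is defined as 1.
#'
#' @param a,b Partitions (`voronoi_partition` or named membership vectors)
#'   over the same node set.
#' @return A number in \eqn{[0, 1]}.
#' @export
partition_nmi <- function(a, b) {
  tab <- .contingency(a, b)
  N <- sum(tab)
  pa <- rowSums(tab) / N
  pb <- colSums(tab) / N
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  pj <- tab / N
  pe <- outer(pa, pb)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / pe[nz]))
  2 * mi / (ha + hb)
}

# Hungarian algorithm (min-cost square assignment, O(n^3), potentials +
# augmenting paths). Returns the column matched to each row.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)  # p[j]: row assigned to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L  # columns are offset by 1: j0 = 1 is the virtual start column
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 1L + seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j] + 1L] <- u[p[j] + 1L] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_col <- integer(n)
  for (j in 1L + seq_len(n)) if (p[j] > 0L) match_col[p[j]] <- j - 1L
  match_col
}

#' Best-match accuracy between a partition and a ground truth
#'
#' Matches predicted clusters one-to-one to ground-truth clusters so as to
#' maximize the total overlap (the optimal assignment on the contingency
#' table; surplus clusters on either side stay unmatched and contribute
#' nothing), then reports the matched overlap divided by the number of
#' nodes. Equals 1 exactly when the partitions coincide up to relabeling.
#'
#' @param a Predicted partition.
#' @param truth Ground-truth partition over the same node set.
#' @return A fraction in \eqn{[0, 1]}.
#' @export
partition_accuracy <- function(a, truth) {
  tab <- unclass(.contingency(a, truth))
  n <- max(dim(tab))
  sq <- matrix(0, n, n)                       # pad to square with zeros
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  match_col <- .hungarian(max(sq) - sq)       # maximize overlap
  sum(sq[cbind(seq_len(n), match_col)]) / sum(tab)
}
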