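#' Benchmark specification for planted-community digraphs
#'
#' Parameters of the LFR-style directed benchmark: power-law in-degrees
#' (exponent `tau1`) rescaled to mean `k_mean` and capped at `k_max`,
#' power-law community sizes (exponent `tau2`) in `[c_min, c_max]`, and a
#' mixing parameter `mu` giving the fraction of each node's in-links that
#' cross community boundaries (a fraction `1 - mu` stays inside). The
#' generated graph is binary (all weights 1); weights are sampled in a
#' separate pass by [sample_weights()].
#'
#' The defaults mirror the evaluation conditions used throughout this
#' package's benchmark experiments: `N = 1000`, `k_mean = 100`,
#' `k_max = 300`, with conventional LFR exponents `tau1 = 2`, `tau2 = 1`
#' and community sizes in `[20, N/4]`.
#'
#' @param N Node count.
#' @param k_mean Target mean degree (mean in-degree = mean out-degree).
#' @param k_max Maximum in-degree, `k_max < N`.
#' @param mu Mixing parameter in `(0, 1)`.
#' @param tau1 In-degree power-law exponent.
#' @param tau2 Community-size power-law exponent.
#' @param c_min,c_max Community size bounds, `c_min >= 2`.
#' @param seed RNG seed (integer); the generator is fully deterministic
#'   given the spec.
#' @return A `benchmark_spec` object.
#' @export
benchmark_spec <- function(N = 1000L, k_mean = 100, k_max = 300L, mu = 0.3,
                           tau1 = 2, tau2 = 1, c_min = 20L,
                           c_max = max(c_min, floor(N / 4)), seed = 1L) {
  if (mu <= 0 || mu >= 1) stop("`mu` must be in (0, 1)", call. = FALSE)
  if (k_max >= N) stop("`k_max` must be smaller than N", call. = FALSE)
  if (c_min < 2) stop("`c_min` must be at least 2", call. = FALSE)
  if (c_max < c_min || c_max > N)
    stop("`c_max` must lie in [c_min, N]", call. = FALSE)
  if (k_mean >= k_max) stop("`k_mean` must be below `k_max`", call. = FALSE)
  # feasibility: the largest community must host the internal in-links of
  # the highest-degree node
  if (round((1 - mu) * k_max) > c_max - 1)
    stop("infeasible spec: a node of in-degree k_max needs ",
         round((1 - mu) * k_max), " intra-community sources but the ",
         "largest community holds only ", c_max - 1, call. = FALSE)
  structure(list(N = as.integer(N), k_mean = k_mean,
                 k_max = as.integer(k_max), mu = mu, tau1 = tau1,
                 tau2 = tau2, c_min = as.integer(c_min),
                 c_max = as.integer(c_max), seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' @export
print.benchmark_spec <- function(x, ...) {
  cat("Benchmark spec: N =", x$N, ", k_mean =", x$k_mean,
      ", k_max =", x$k_max, ", mu =", x$mu, "\n")
  cat("  tau1 =", x$tau1, ", tau2 =", x$tau2,
      ", community sizes in [", x$c_min, ",", x$c_max, "], seed =",
      x$seed, "\n")
  invisible(x)
}

# Inverse-CDF sample from a continuous power law p(x) ~ x^(-tau) truncated
# to [lo, hi].
.rpower_trunc <- function(n, tau, lo, hi) {
  u <- runif(n)
  if (abs(tau - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    a <- 1 - tau
    (lo^a + u * (hi^a - lo^a))^(1 / a)
  }
}

# Mean of the continuous truncated power law p(x) ~ x^(-tau) on [lo, hi].
# The exponent integrals degenerate to logarithms at tau = 1 and tau = 2.
.power_trunc_mean <- function(tau, lo, hi) {
  a <- 1 - tau
  num <- if (abs(a + 1) < 1e-12) log(hi / lo) else (hi^(a + 1) - lo^(a + 1)) / (a + 1)
  den <- if (abs(a) < 1e-12) log(hi / lo) else (hi^a - lo^a) / a
  num / den
}

#' Generate a planted-community directed benchmark graph
#'
#' LFR-style construction: community sizes are drawn from the `tau2` power
#' law until they sum to `N` (the last community is trimmed, tiny
#' remainders are redistributed); in-degrees are drawn from the `tau1`
#' power law whose lower bound is solved so the mean equals `k_mean`,
#' capped at `k_max`; nodes are placed into communities that can host their
#' internal in-links (largest in-degrees first, sampled with probability
#' proportional to free capacity); finally each node receives
#' `round((1 - mu) * k_in)` in-links from uniformly drawn distinct members
#' of its own community and the rest from uniformly drawn outside nodes.
#' No self-loops or duplicate ordered pairs are created, and all edge
#' weights are 1.
#'
#' @param spec A [benchmark_spec()].
#' @return A list with `graph` (binary directed [igraph::igraph], weights
#'   1), `membership` (named ground-truth cluster vector), and `spec`.
#' @export
generate_planted_digraph <- function(spec) {
  if (!inherits(spec, "benchmark_spec"))
    stop("`spec` must be a benchmark_spec()", call. = FALSE)
  .with_seed(spec$seed, {
    N <- spec$N

    # --- in-degrees ---
    lo <- tryCatch(
      uniroot(function(l) .power_trunc_mean(spec$tau1, l, spec$k_max) - spec$k_mean,
              interval = c(1, spec$k_max - 1e-6), tol = 1e-9)$root,
      error = function(e) stop("cannot match k_mean with the given tau1/k_max",
                               call. = FALSE))
    k_in <- pmin(spec$k_max, pmax(1L, round(.rpower_trunc(N, spec$tau1, lo, spec$k_max))))
    n_intra <- round((1 - spec$mu) * k_in)

    # a size sequence is feasible iff, for every internal-link requirement
    # r, the nodes needing >= r internal sources fit into the communities
    # of size >= r + 1 (largest-first packing is optimal here)
    req_sorted <- sort(unique(n_intra))
    feasible <- function(sizes) {
      for (r in req_sorted) {
        if (sum(n_intra >= r) > sum(sizes[sizes >= r + 1L])) return(FALSE)
      }
      TRUE
    }

    # --- community sizes, rejection-sampled until they can pack the
    # --- degree sequence ---
    sizes <- NULL
    for (attempt in seq_len(500L)) {
      cand <- integer(0)
      while (sum(cand) < N) {
        s <- round(.rpower_trunc(1L, spec$tau2, spec$c_min, spec$c_max))
        cand <- c(cand, min(max(s, spec$c_min), spec$c_max))
      }
      excess <- sum(cand) - N
      last <- length(cand)
      if (cand[last] - excess >= spec$c_min) {
        cand[last] <- cand[last] - excess
      } else {
        # drop the last draw and spread the remainder over the others
        rem <- N - sum(cand[-last])
        cand <- cand[-last]
        i <- 0L
        while (rem > 0L && any(cand < spec$c_max)) {
          i <- i %% length(cand) + 1L
          if (cand[i] < spec$c_max) { cand[i] <- cand[i] + 1L; rem <- rem - 1L }
        }
      }
      if (sum(cand) == N && feasible(cand)) { sizes <- cand; break }
    }
    if (is.null(sizes))
      stop("infeasible draw: no community size sequence can host a node ",
           "needing ", max(n_intra), " intra-community sources", call. = FALSE)

    # --- node placement: big in-degrees first, into communities that fit ---
    membership <- integer(N)
    free <- sizes
    for (i in order(-k_in)) {
      ok <- which(free > 0L & sizes - 1L >= n_intra[i])
      if (length(ok) == 0L)
        stop("infeasible draw: no community can host a node with ",
             n_intra[i], " internal in-links", call. = FALSE)
      c_i <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = free[ok])
      membership[i] <- c_i
      free[c_i] <- free[c_i] - 1L
    }
    comm_members <- split(seq_len(N), membership)

    # --- in-link sampling ---
    src <- vector("list", N)
    all_nodes <- seq_len(N)
    for (i in seq_len(N)) {
      own <- comm_members[[membership[i]]]
      ni <- min(n_intra[i], length(own) - 1L)
      ne <- k_in[i] - ni
      intra_pool <- own[own != i]
      s_in <- if (ni > 0L) sample(intra_pool, ni) else integer(0)
      if (ne > 0L) {
        outside <- all_nodes[-own]
        s_in <- c(s_in, sample(outside, min(ne, length(outside))))
      }
      src[[i]] <- s_in
    }
    tgt <- rep.int(seq_len(N), lengths(src))
    src <- unlist(src, use.names = FALSE)

    nm <- sprintf("v%04d", seq_len(N))
    g <- igraph::make_graph(as.vector(rbind(src, tgt)), n = N, directed = TRUE)
    igraph::V(g)$name <- nm
    igraph::E(g)$weight <- 1
    list(graph = g, membership = setNames(membership, nm), spec = spec)
  })
}

#' Weight distribution specification
#'
#' Parameterizes the per-edge weight distributions used by
#' [sample_weights()]:
#' \itemize{
#'   \item `"truncnormal"`: density \eqn{\propto e^{-(w-m)^2/2\sigma^2}}
#'     on \eqn{(0, \infty)}, sampled by rejection of non-positive normal
#'     draws;
#'   \item `"truncpower"`: density \eqn{\propto \alpha w^{\alpha-1}} on
#'     \eqn{[w_{min}, 1]} with \eqn{0 < \alpha \le 1}, sampled by inverse
#'     CDF. Either `alpha` or a target `mean` (inverted through
#'     [solve_alpha()]) may be given.
#' }
#'
#' @param family `"truncnormal"` or `"truncpower"`.
#' @param mean Mean parameter: the normal location `m`, or the target mean
#'   of the truncated power law.
#' @param sigma Normal spread (default 0.1).
#' @param alpha Power exponent in `(0, 1]`.
#' @param w_min Lower truncation of the power support (default 0.01).
#' @return A `weight_dist_spec` object with the implied distribution mean
#'   in `$mean`.
#' @export
weight_dist_spec <- function(family = c("truncnormal", "truncpower"),
                             mean = NULL, sigma = 0.1, alpha = NULL,
                             w_min = 0.01) {
  family <- match.arg(family)
  if (family == "truncnormal") {
    if (is.null(mean)) stop("truncnormal requires `mean`", call. = FALSE)
    if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
    out <- list(family = family, mean = mean, sigma = sigma)
  } else {
    if (is.null(alpha) && is.null(mean))
      stop("truncpower requires `alpha` or `mean`", call. = FALSE)
    if (is.null(alpha)) alpha <- solve_alpha(mean, w_min)
    if (alpha <= 0 || alpha > 1)
      stop("`alpha` must be in (0, 1]", call. = FALSE)
    out <- list(family = family, alpha = alpha, w_min = w_min,
                mean = truncpower_mean(alpha, w_min))
  }
  structure(out, class = "weight_dist_spec")
}

#' Mean of the truncated power distribution
#'
#' For the density \eqn{p(w) \propto \alpha w^{\alpha - 1}} restricted to
#' \eqn{[w_{min}, 1]}, the correctly normalized mean is
#' \deqn{m(\alpha) = \frac{\alpha}{\alpha + 1} \,
#'   \frac{1 - w_{min}^{\alpha + 1}}{1 - w_{min}^{\alpha}},}
#' obtained by integrating the normalized density (and validated against
#' adaptive quadrature in the test suite). At \eqn{\alpha = 1} the
#' distribution is uniform on \eqn{[w_{min}, 1]} and the mean is the
#' midpoint, 0.505 for \eqn{w_{min} = 0.01}. `m(alpha)` increases strictly
#' with \eqn{\alpha}.
#'
#' @param alpha Exponent in `(0, 1]`.
#' @param w_min Lower truncation (default 0.01).
#' @return The distribution mean.
#' @export
truncpower_mean <- function(alpha, w_min = 0.01) {
  if (any(alpha <= 0) || any(alpha > 1))
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  alpha / (alpha + 1) * (1 - w_min^(alpha + 1)) / (1 - w_min^alpha)
}

#' Invert the truncated-power mean for alpha
#'
#' Root-finds `truncpower_mean(alpha) == target_mean` by monotone
#' bisection. The attainable range for \eqn{\alpha \in (0, 1]} is
#' \eqn{((1 - w_{min}) / (-\ln w_{min}),\; m(1)]} — about
#' \eqn{(0.215, 0.505]} for \eqn{w_{min} = 0.01}; targets outside it raise
#' an error stating the attainable interval.
#'
#' @param target_mean Desired distribution mean.
#' @param w_min Lower truncation (default 0.01).
#' @param tol Root tolerance (default 1e-8).
#' @return The exponent `alpha` in `(0, 1]`.
#' @export
solve_alpha <- function(target_mean, w_min = 0.01, tol = 1e-8) {
  lo_lim <- (1 - w_min) / (-log(w_min))  # alpha -> 0+ limit of the mean
  hi_lim <- truncpower_mean(1, w_min)
  if (target_mean <= lo_lim || target_mean > hi_lim)
    stop(sprintf("target mean %.4g unattainable; attainable interval is (%.6g, %.6g]",
                 target_mean, lo_lim, hi_lim), call. = FALSE)
  uniroot(function(a) truncpower_mean(a, w_min) - target_mean,
          interval = c(1e-12, 1), tol = tol)$root
}

.sample_dist <- function(n, spec) {
  if (n == 0L) return(numeric(0))
  if (spec$family == "truncnormal") {
    w <- rnorm(n, spec$mean, spec$sigma)
    while (any(w <= 0)) {
      bad <- which(w <= 0)
      w[bad] <- rnorm(length(bad), spec$mean, spec$sigma)
    }
    w
  } else {
    u <- runif(n)
    a <- spec$alpha; wm <- spec$w_min
    (wm^a + u * (1 - wm^a))^(1 / a)
  }
}

#' Sample intra/inter-community edge weights
#'
#' Second stage of the benchmark construction: every intra-community edge
#' of a binary planted graph receives an independent draw from the `intra`
#' distribution and every inter-community edge from the `inter`
#' distribution. The intra mean must exceed the inter mean (communities
#' are bound by heavier weights).
#'
#' @param g Binary directed graph (weights ignored/overwritten).
#' @param truth Ground-truth partition (named membership vector or
#'   `voronoi_partition`).
#' @param intra,inter [weight_dist_spec()] objects for intra- and
#'   inter-community edges.
#' @param seed RNG seed.
#' @return The graph with sampled positive `weight` edge attribute.
#' @export
sample_weights <- function(g, truth, intra, inter, seed = NULL) {
  .check_dwgraph(g)
  if (!inherits(intra, "weight_dist_spec") || !inherits(inter, "weight_dist_spec"))
    stop("`intra` and `inter` must be weight_dist_spec() objects", call. = FALSE)
  if (!(intra$mean > inter$mean))
    stop("intra-community mean weight must exceed the inter-community mean",
         call. = FALSE)
  memb <- as_membership(truth)
  idx <- match(.node_names(g), names(memb))
  if (anyNA(idx)) stop("`truth` does not cover every node", call. = FALSE)
  memb <- memb[idx]
  el <- igraph::as_edgelist(g, names = FALSE)
  is_intra <- memb[el[, 1L]] == memb[el[, 2L]]
  .with_seed(seed, {
    w <- numeric(igraph::ecount(g))
    w[is_intra] <- .sample_dist(sum(is_intra), intra)
    w[!is_intra] <- .sample_dist(sum(!is_intra), inter)
    igraph::E(g)$weight <- w
  })
  g
}
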