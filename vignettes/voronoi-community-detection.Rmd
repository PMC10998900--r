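---
title: "Voronoi community detection in directed weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi community detection in directed weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voronoicd)
library(igraph)
set.seed(1)
```

## The problem and the approach

Community detection in networks whose links carry both a direction and a
weight is awkward for much of the standard toolbox: dense graphs (inter-areal
brain connectomes reach 60–95% density) make the mere presence or absence of
links uninformative, and methods built around connection *strengths* force
ad-hoc transformations on data whose weights are naturally *lengths*
(distances, travel times, log-probabilities).

`voronoicd` partitions the vertex set into **graph Voronoi cells**. Given a
directed graph $G=(V,E)$ with positive edge lengths $l_{ij}$ and a set of
generator ("seed") nodes $\gamma_1,\dots,\gamma_g$, the cell $V_b$ collects
every node whose shortest-path distance to $\gamma_b$ is no larger than its
distance to any other generator. The cells are disjoint, cover $V$, and are
contiguous: some shortest path from each node to its generator stays inside
the cell (verified post hoc by `contiguity_check()`). Distances are directed;
by default a node is assigned along paths *leaving* it (`direction = "in"`
runs the search on the transposed graph), matching the intuition that a
generator with strong incoming connectivity acts as a point of attraction.
The opposite convention is one flag away, and comparing the two is itself
informative.

## From weights to lengths

Two ingredients define the length of $i \to j$:

1. **Local topology.** The edge clustering coefficient on the undirected
   simple skeleton,
   $$C_{ij} = \frac{z(n_i,n_j) + 1}{\min[k(n_i)-1,\; k(n_j)-1]},$$
   with $z$ the number of common neighbors and $k$ the skeleton degree.
   Edges embedded in many triangles are "inside" edges and should be short.
   When an endpoint has skeleton degree 1 the denominator would vanish; we
   clamp it to 1, so pendant edges get $C = z+1$. This keeps every length
   finite and agrees with how leaf edges are conventionally handled for this
   coefficient.

2. **The weight transform** $f(\cdot)$, chosen by the user from the meaning
   of the data:

   | transform  | $f(x)$     | when |
   |------------|------------|------|
   | `neglog`   | $-\ln w$   | weights in $(0,1]$ are transmission probabilities; lengths add like log-probabilities |
   | `inverse`  | $1/w$      | weights are connection strengths |
   | `distance` | $d_{ij}$   | a geometric per-edge distance is available |
   | `identity` | $w$        | weights already are lengths |

The length is $l_{ij} = f(x)/C_{ij}$ (or $f(x)$ with `use_ecc = FALSE`).
`neglog` requires weights in $(0,1]$; `normalize = TRUE` divides by the
maximum weight first. There is deliberately no automatic transform
selection — the right choice depends on what the weights measure, and the
four recipes together with user-supplied generators cover the length
constructions we have needed in practice (e.g. `distance` with or without
ECC for spatially embedded flows).

**Zero-length floor.** $-\ln w = 0$ at $w = 1$, but Voronoi assignment wants
strictly positive lengths. Exact zeros are replaced by
$\varepsilon = 10^{-12} \times \mathrm{median}(\text{positive raw lengths})$
— far below data resolution, while keeping Dijkstra's tie handling sane.
`epsilon` is exposed for users who prefer a fixed value.

```{r lengths}
g <- make_graph(c("a","b", "b","c", "c","a"), directed = TRUE)
E(g)$weight <- c(0.5, 1, 1)
E(compute_lengths(g, length_spec("neglog")))$length
```

## Selecting generators: density peaks at scale R

Communities concentrate around density peaks. For node $i$ with closed
first-order neighborhood $\mathcal N(i)$ (itself plus all skeleton
neighbors), let $m$ count directed edges with both endpoints in
$\mathcal N(i)$ — links between two neighbors count as inside — and $k$
count edges crossing the boundary. The **weighted local relative density**
is
$$\rho_i = s_i \frac{m}{m+k},$$
with $s_i$ the total strength. Isolated nodes get $\rho = 0$ and end up as
late singleton generators rather than being hidden.

`select_generators(g, R)` repeatedly takes the highest-$\rho$ node still in
play and excludes every remaining node within outgoing shortest-path
distance $R$ of it. Any two generators are therefore more than $R$ apart:
$R$ is an interpretable resolution knob, in the same units as the lengths.
Above the graph diameter one generator survives; below the smallest edge
length every node is its own generator. Density ties break toward the
earlier node index so runs are reproducible. The exclusion ball uses
*outgoing* distances $d(\gamma, j) \le R$, consistent with the outgoing-path
convention used throughout; `direction = "in"` flips it.

When domain knowledge identifies the anchors (the busiest airports, primary
sensory areas), `user_generators()` bypasses selection entirely.

## Assignment: naive and pruned, one contract

`voronoi_assign()` offers two routes that must — and in the test suite do —
produce bitwise-identical partitions:

* **naive**: one full reverse Dijkstra per generator, then a per-node
  argmin (vectorized, C-backed via igraph; the default);
* **pruned**: generators processed in selection order, each search pruned
  at nodes already owned at a strictly smaller distance. Later searches
  explore successively smaller regions, giving roughly
  $O(\log g \, |E| \log |V|)$ total work — the scalable sequential
  algorithm, implemented here with a binary heap.

Ties (a node exactly equidistant from two generators) resolve toward the
earlier-selected generator by default; `ties = "random"` restores the
classical random choice under a seed. The tie census is exact on the naive
route and a lower bound on the pruned route (a pruned search cannot observe
a tie it never reached). Nodes that reach no generator — possible on
disconnected inputs, which we accept rather than silently restricting to a
strongly connected component — become fresh singleton clusters, with a
warning, so the cover-and-disjoint invariant survives.

## Choosing R: modularity over a piecewise-constant objective

Partition quality is scored by the directed, weighted modularity
$$Q = \frac{1}{m}\sum_{i,j\in V}\left[w_{ij} -
  \frac{s_i^{\mathrm{out}} s_j^{\mathrm{in}}}{m}\right]
  \delta_{c_i,c_j},$$
computed in $O(|E|)$ by iterating edges and per-cluster strength sums (the
literal $O(N^2)$ double sum serves as a test oracle). $Q = 0$ exactly for
the single-cluster partition.

$Q(R)$ only changes when the generator set changes, so it is piecewise
constant, and a derivative-free optimizer alone can stall on a flat piece.
`optimize_radius()` therefore first scans a log-spaced grid (default 32
points) between the smallest edge length and the graph diameter, then runs
Brent's method inside the best grid bracket (tolerance
$10^{-3}(R_{\max}-R_{\min})$); `grid_size = 0` gives pure Brent for the
purist. Evaluations are memoized on the generator set, equal-$Q$ radii
resolve toward the smaller $R$ (the finer partition), and the full
$(R, g, Q)$ trace is returned — on benchmark instances the maximal-NMI
radii form a plateau, so the trace is worth plotting, not just its argmax.
`fixed_cluster_count()` instead bisects on $R$ for a requested number of
clusters, with a distance-multiset scan as fallback since $g(R)$ need not
be monotone; this is how the 2–7-cluster hierarchy views of a network are
produced.

```{r toy}
# two directed 6-cliques joined by a reciprocal bridge
clique <- function(v) {
  e <- expand.grid(from = v, to = v)
  e <- e[e$from != e$to, ]
  as.vector(rbind(e$from, e$to))
}
g2 <- make_graph(c(clique(1:6), clique(7:12), 6,7, 7,6), directed = TRUE)
V(g2)$name <- letters[1:12]; E(g2)$weight <- 1
part <- voronoi_communities(g2, length_spec("inverse"), radius = "auto",
                            grid_size = 8)
part
```

## The benchmark generator

Because real directed weighted ground truths are scarce, the package ships
its evaluation apparatus. `generate_planted_digraph()` builds an LFR-style
directed graph with planted communities:

* community sizes from a power law (exponent $\tau_2 = 1$) on
  $[c_{\min}, c_{\max}] = [20, N/4]$, resampled until the size sequence can
  pack the degree sequence (for every requirement $r$, the nodes needing
  $\ge r$ internal sources must fit into communities of size $\ge r+1$);
* in-degrees from a power law (exponent $\tau_1 = 2$) whose lower bound is
  solved so the mean equals $\bar k$, capped at $k_{\max}$;
* each node draws $\mathrm{round}((1-\mu)k^{\mathrm{in}})$ in-links from
  distinct members of its own community and the rest from outside — the
  mixing parameter $\mu$ is the fraction of links crossing communities.
  Out-degrees emerge from this matching rather than being controlled
  separately.

Weights are sampled in a second, independent stage (`sample_weights()`),
with separate intra- and inter-community distributions so that weight
contrast can be varied on a fixed topology: a normal truncated to
$(0,\infty)$ (rejection sampling; $\sigma = 0.1$ by default), or a power
density $p(w) \propto \alpha w^{\alpha-1}$ on $[w_{\min}, 1]$,
$w_{\min} = 0.01$, sampled by inverse CDF. Integrating the normalized power
density gives its mean
$$m(\alpha) = \frac{\alpha}{\alpha+1}\,
  \frac{1 - w_{\min}^{\alpha+1}}{1 - w_{\min}^{\alpha}},$$
strictly increasing in $\alpha$, equal to $0.505$ (the uniform midpoint) at
$\alpha = 1$ and validated against adaptive quadrature in the tests; note
that dropping the normalization term $1 - w_{\min}^{\alpha}$ yields a
dimensionally inconsistent expression, which is why the package derives the
mean rather than shortcutting it. `solve_alpha()` inverts $m(\alpha)$ by
bisection, refusing targets outside the attainable
$\bigl((1-w_{\min})/(-\ln w_{\min}),\, 0.505\bigr]$.

The default conditions — $N = 1000$, $\bar k = 100$, $k_{\max} = 300$,
$\mu = 0.3$, power weights with $\alpha_{\mathrm{intra}} = 0.7$,
$\alpha_{\mathrm{inter}} = 0.3$ — are the evaluation conditions used by the
acceptance script and the heavyweight tests. What the generator does *not*
emulate: degree–community-size correlations beyond the feasibility packing,
overlapping communities, weight–topology correlations within a class, or
byte-compatibility with the reference LFR code. Passing tests on these
benchmarks show the pipeline recovers planted, well-separated,
weight-contrasted communities; they do not certify behavior on data whose
communities are encoded in ways the generator cannot express.

## Robustness experiments

`randomize_generators()` probes how much the partition depends on exact
generator placement: *intra* mode replaces each generator by a random node
of its own cluster, *uniform* mode draws the same number of generators
anywhere. Each draw re-runs assignment and scores $Q$ and NMI against a
baseline. On the default benchmark, intra randomization barely moves the
result (median NMI against the planted partition stays above 0.95 in the
acceptance suite) while uniform placement is clearly worse — the value of
the density-based selection lies almost entirely in getting one generator
per community, not in which node it is.

## Partition comparison metrics

`partition_nmi()` is normalized mutual information with mean-entropy
normalization, $2I(A;B)/(H(A)+H(B))$, natural logarithms; this is the
convention under which perfect recovery reads 1, and two single-cluster
partitions compare as 1 by continuity. `partition_accuracy()` is the
maximum-overlap one-to-one matching of clusters (Hungarian algorithm on the
contingency table, surplus clusters unmatched) divided by $N$ — there being
no single standard definition, this optimal-matching reading is stated
here prominently.

## Numerical choices and problem sizes

* Dijkstra runs on a binary heap; zero-length edges are legal (they arise
  only through the floor $\varepsilon$), negative lengths are a hard error.
* Duplicate ordered edges aggregate by weight summation at ingestion
  (weights are volumes in every intended use), self-loops are dropped —
  both with warnings.
* The diameter is computed exactly from $|V|$ single-source runs;
  acceptable at the $N \le 10^4$ desk scale this package targets.
* Determinism everywhere by default: density ties, distance ties, and
  equal-$Q$ radii all have fixed resolutions; all sampling goes through
  explicit seeds.
* The test suite exercises the full pipeline at $N = 1000$, $\bar k = 100$
  (one instance, shared across tests) and the property suites at
  $n \le 200$ over ~100 random strongly connected digraphs; these sizes
  keep a full run around two minutes while still covering the regime the
  method is meant for.

## Known limitations

* Exact recovery of a planted partition is typical but not guaranteed: a
  handful of boundary nodes can be genuinely closer (in the constructed
  length) to a neighboring community's generator, in which case NMI lands
  slightly below 1 with no bug involved.
* On knife-edge inputs the deterministic tie-breaks can differ from a
  random-tie convention by whole tie orbits; `ties = "random"` exists for
  sensitivity checks.
* Hierarchies are explored by varying $R$ (or `fixed_cluster_count()`);
  the package does not build a dendrogram.
* No overlapping or fuzzy memberships, no negative weights (absolute-value
  correlation weights upstream), no multigraph preservation.
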