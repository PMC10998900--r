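# voronoicd

Community detection for **directed, weighted networks** by graph Voronoi
partitioning — for network scientists working with data where link weights
(and their direction) carry most of the structure: inter-areal brain
connectivity, migration and passenger flows, weighted friendship nominations,
and dense graphs in general, where the mere presence of links says little.

## Method

Given a directed graph $G=(V,E)$ with weights $w_{ij}>0$, the pipeline is:

1. **Edge lengths.** Each edge gets a length
   $l_{ij} = f(w_{ij})/C_{ij}$, combining a user-chosen weight transform
   $f$ (−ln w for probability-like weights, $1/w$ for strengths, a
   geometric distance $d_{ij}$, or the identity) with the edge clustering
   coefficient
   $C_{ij} = \dfrac{z(n_i,n_j)+1}{\min[k(n_i)-1,\,k(n_j)-1]}$
   on the undirected skeleton, so triangle-embedded edges are short.
2. **Generator selection.** The weighted local relative density
   $\rho_i = s_i\,\frac{m}{m+k}$ (strength × fraction of first-order
   neighborhood edges that are internal) identifies density peaks; nodes
   are picked greedily as generators, each excluding everything within
   shortest-path radius $R$.
3. **Voronoi assignment.** Every node joins the cell of its nearest
   generator along directed shortest paths (a pruned multi-source Dijkstra
   with an exactly-equivalent naive route), giving disjoint, covering,
   contiguous communities.
4. **Scale selection.** $R$ is chosen by maximizing the directed weighted
   modularity
   $Q = \frac{1}{m}\sum_{i,j}\bigl[w_{ij}-\frac{s_i^{out}s_j^{in}}{m}\bigr]\delta_{c_i,c_j}$
   over a log-spaced grid refined by Brent's method; or ask for a fixed
   number of clusters.

The package also ships an LFR-style directed benchmark generator with
planted communities and two-stage intra/inter weight sampling (truncated
normal or truncated power), partition metrics (directed modularity, NMI,
optimal-matching accuracy), generator-randomization robustness experiments,
and a CLI. See the vignette `voronoi-community-detection` for the full
methods account.

## Worked example

Generate a planted benchmark (1000 nodes, mean degree 100, mixing
$\mu = 0.3$, truncated-power weights), detect communities, compare with the
planted truth (about a minute on one core):

```r
library(voronoicd)

spec  <- benchmark_spec(N = 1000, k_mean = 100, k_max = 300, mu = 0.3, seed = 1)
bench <- generate_planted_digraph(spec)
g <- sample_weights(bench$graph, bench$membership,
                    intra = weight_dist_spec("truncpower", alpha = 0.7),
                    inter = weight_dist_spec("truncpower", alpha = 0.3),
                    seed = 104730)
g  <- compute_lengths(g, length_spec("inverse"))   # l = (1/w) / ECC
sw <- optimize_radius(g, grid_size = 32)
sw
#> Radius sweep: 42 evaluations in [ 1.191 , 16.97 ]
#>   best R = 8.40764 -> Q = 0.586641 with 7 cluster(s)
partition_nmi(sw$best, bench$membership)
#> [1] 0.9944091
```

Reading the output: the sweep brackets $R$ between the smallest edge length
and the graph diameter; the modularity-optimal radius ($R \approx 8.4$,
$Q \approx 0.587$) yields 7 Voronoi cells, and their normalized mutual
information with the planted partition is 0.994 — near-exact recovery, with
a handful of boundary nodes genuinely closer to a neighboring generator.
`sw$trace` holds the full $(R, g, Q)$ curve; its NMI maximum typically forms
a plateau across a range of radii.

For real data, start from an edge list instead:

```r
g <- read_edge_list("flows.tsv")                  # source \t target \t weight
p <- voronoi_communities(g, length_spec("neglog", normalize = TRUE))
write_partition(p, "communities.tsv")
```

A command-line interface wraps the same steps
(`inst/scripts/voronoicd detect|sweep|benchmark|weights|evaluate|robustness`).

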