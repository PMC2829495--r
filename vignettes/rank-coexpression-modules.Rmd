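---
title: "Rank-based co-expression networks and Qcut: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based co-expression networks and Qcut: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Clustering genes (or samples) by expression similarity hides the
neighborhood structure that a network makes explicit, while full
regulatory-network inference demands more data than most experiments
provide. Co-expression networks sit between the two: nodes are genes (or
samples), edges mark strong expression similarity, and functional modules
appear as dense subgraphs. This package implements a complete pipeline —
network construction, module detection, topology diagnostics, and module
evaluation — with the deliberate property that no step requires the user
to guess a cluster count or a similarity cutoff.

## Rank-based construction

`compute_similarity()` supports Pearson correlation and negative
Euclidean distance, both oriented so larger means more similar.
`rank_network(sim, d)` connects each entity to its `d` most similar
partners and takes the undirected union of these top-`d` lists. Ranking
is asymmetric, which is the method's point: gene *i* may list gene *j*
without *j* listing *i*, so the union has minimum degree exactly `d`,
mean degree in `[d, 2d]`, and an unbounded maximum degree. Each gene
effectively receives its own similarity threshold, so weakly
co-expressed modules stay internally connected at the same small `d`
at which strongly co-expressed modules are already sparse.

The underlying assumption is geometric: profiles from one module are
draws from a common distribution, so the module's subgraph is a
nearest-neighbor graph on random points, which connects with high
probability at very small `d`. The test suite reproduces this on
1000-point standard-Gaussian clouds: at dimension 20 the `d = 2` network
is typically a single component, and even at dimensions 2–5 a majority
of replicates connect by `d = 4`. In practice `d` between 3 and 5 is a
good default; `d = 4` is used in the clustered benchmark below.

Two details are deliberate:

* **Tie-breaking** sorts candidates by (similarity descending, node
  index ascending) and takes exactly `d` — deterministic, and exact ties
  in real-valued similarities are measure-zero anyway.
* **Flat profiles** under Pearson have no defined correlation; they are
  ranked last (similarity `-Inf`) with a warning rather than erroring,
  since real matrices contain flat genes.

`value_network(sim, t)` implements the conventional global-threshold
construction for comparison, with a *closed* comparison (edge iff
similarity ≥ t). Closed rather than strict was chosen so that
`threshold_for_mean_degree()` is exact: the largest `t` achieving mean
degree ≥ k is precisely the `⌈nk/2⌉`-th largest off-diagonal similarity.
`rank_network(..., floor =)` combines the two: rank selection followed by
a value floor, the recommended construction for *sample* networks (a
floor of 0.2 on Pearson correlation removes edges computed from
high-dimensional but weakly related profiles).

## Modularity and Qcut

`modularity_score()` evaluates

> Q = Σᵢ (eᵢᵢ − aᵢ²)

with eᵢᵢ the fraction of total edge weight internal to module *i* and
aᵢ = Sᵢ/(2W) the module's half share of weighted degree. This is the
standard normalization, under which a single-module partition scores
exactly 0 and Q ∈ [−1, 1] always — both properties are exhaustively
verified in the tests over all partitions of small graphs. Weighted
networks substitute edge weights for counts throughout.

`qcut_partition()` maximizes Q without a module-count parameter:

1. **Initial modules** are the connected components (merging components
   can never increase Q, so they are never rejoined).
2. **Recursive spectral splitting.** For each module,
   `spectral_split()` embeds the induced subgraph with the top-k
   eigenvectors of the symmetric normalized adjacency
   D^(−1/2) A D^(−1/2), row-normalizes, and runs k-means with 10
   restarts for k ∈ {2, 3, 4}; the candidate maximizing the global Q
   change is accepted only if ΔQ > 10⁻¹⁰ (strict increase up to
   floating-point noise). Accepted parts are pushed back on the queue.
   The Q change of replacing one module by a split depends only on the
   module's internal edges and its nodes' global strengths, so no
   surrounding context is needed.
3. **Greedy refinement.** `refine_partition()` cycles three operation
   families until a full cycle brings no improvement: node moves to
   neighboring modules (full sweeps in fixed node order, Louvain-style
   incremental ΔQ), best-first merges of connected module pairs, and
   per-module spectral re-splits. Cheap operations run first; the number
   of merge/split rounds is uncapped, since each accepted operation
   strictly increases a bounded objective and therefore terminates.

All randomness (the k-means restarts) flows from one `seed` argument;
the result is deterministic given the seed and invariant to node
relabeling. Exact maximization of Q is NP-hard, so the tests check the
heuristic against a brute-force enumeration over all set partitions on
graphs of up to 10 nodes, requiring the optimum to be attained in at
least 90% of instances and never exceeded.

One definitional point: a verbal description of aᵢ as "the fraction of
edges with one or both nodes in cluster i" circulates alongside Eq.
above, but it contradicts the stated properties (single cluster ⇒ Q = 0,
Σaᵢ = 1). The half-degree-share definition is the one under which those
properties hold, and is what this package implements.

## Topology diagnostics and null models

`topology_summary()` reports node/edge/singleton counts, component
sizes, degree statistics, the clustering coefficient
Cᵢ = 2nᵢ/(kᵢ(kᵢ−1)) averaged over non-singleton nodes (Cᵢ := 0 for
degree-1 nodes, where the formula is 0/0), mean shortest path and
diameter over reachable pairs only, the degree histogram f(k) and the
mean clustering per degree C(k). Distances come from breadth-first
search from every node (O(n·|E|)).

`fit_power_law()` fits f(k) = c·k^(−γ) by least squares on
(log₁₀ k, log₁₀ f(k)) over degrees with positive frequency, without
binning — the simplest reproducible choice; rank networks on clustered
data typically give γ between 2 and 3, value networks below 1.

Two null models isolate what the clustering coefficient and degree
distribution owe to chance:

* `rewire_preserving_degrees()` — double-edge swaps rejecting self-loops
  and duplicates (delegated to `igraph::rewire(keeping_degseq)`),
  keeping every node's degree while destroying triangles;
* `permute_expression_rows()` — independent uniform permutation of each
  row's values, destroying co-expression while preserving each gene's
  value distribution; rebuild the rank network from the result.

A real clustered network should beat both nulls on clustering
coefficient; the suite asserts this on synthetic clustered data.

## Reference-network evaluation

GO-enrichment counting rewards many small modules; the
reference-network score does not. Given a binary gene × attribute
matrix (from `read_attribute_table()`, optionally closed over an
ontology and filtered by `propagate_and_filter()` — ancestors inherited,
duplicate attribute columns collapsed to the lexicographically smallest
id, attributes covering < 5 or > 500 genes dropped), `idf_weight()`
forms wᵢⱼ = aᵢⱼ·log(n/coverageⱼ) and `build_reference_network()` links
genes sharing at least one attribute with edge weight the cosine of
their weighted attribute vectors, dropping edges below a cutoff
(weights are kept, not binarized — the cutoff removes noise edges, it
does not discretize). Natural log is used for the IDF; the cosine is
invariant to the base, which a test asserts numerically.

`score_partition_on_reference()` imposes the co-expression partition's
labels on the reference network and returns the reference network's
weighted modularity. Entities absent from the reference contribute
nothing (the metric is a property of the reference graph's edges).
`shuffle_partition_preserving_sizes()` provides the calibration: the
mean score of size-preserving random shuffles is ≈ 0, so any positive
score is signal, and scores are comparable across algorithms regardless
of how many or how large their modules are.

## Evaluation statistics

`adjusted_rand_index()` is the Hubert–Arabie chance-corrected form
computed from the contingency table; it is checked against brute-force
pair counting and against `mclust::adjustedRandIndex`.
`hypergeometric_enrichment()` returns the cumulative tail
P(X ≥ k) (via `phyper`) and fold enrichment;
`enrichment_summary()` tests every (module, attribute) pair whose
attribute overlaps the partitioned universe, Bonferroni-corrects by the
number of tests performed (modules × attributes tested — untestable
zero-overlap attributes would only inflate the multiplier), and reports,
per significance level, the number of enriched pairs and the fraction of
modules with at least one enriched attribute.

## Synthetic data: what it does and does not emulate

`simulate_clustered_expression()` reproduces the structure of the
classic simulated-microarray benchmark: 15 clusters over 600 genes and
50 conditions, each cluster a template profile drawn i.i.d. standard
normal per condition (log-scale values, hence log-normal raw
intensities), each gene its template plus i.i.d. N(0, sd²) noise. The
benchmark's exact template parameters and size distribution are not
published, so equal sizes (15 × 40) and unit template variance are the
declared defaults, with `cluster_sizes` available for heterogeneity.
The noise grid of interest is {0, 0.2, 0.4, 0.8, 1.2}: at SD ≤ 0.4 the
planted structure is cleanly separable, at 1.2 clusters blur together.
The generator does *not* emulate microarray technical artifacts — dye
bias, missing values, intensity-dependent variance, correlated noise —
so passing benchmarks here demonstrate correctness of the algorithms on
their stated model, not robustness to platform noise.

`gaussian_cloud()` (1000 points, any dimension) drives the connectivity
experiment; `planted_partition_graph()` gives graph-level ground truth
(within-group probability p_in, between-group p_out) for testing the
module detector independently of network construction.

The test suite runs the clustered benchmark at 20 replicates per noise
level with the d = 4 rank network on Euclidean distance, the
connectivity experiment at 20 replicates per dimension, and brute-force
modularity enumeration on graphs up to 10 nodes — sizes chosen so the
full suite completes in a few minutes while keeping the medians stable.

## Known limitations

* Q maximization is heuristic; optimality is only guaranteed empirically
  on small graphs, and modularity itself has a resolution limit — very
  small, well-separated modules can be absorbed when the network is
  large.
* The spectral step densifies each module's adjacency for the eigen
  decomposition; networks beyond ~10⁴ nodes need a sparse eigensolver
  this package does not include.
* The value-network path and CLR-style z-scoring refinements are
  provided only as comparators; topological-overlap or shortest-path
  similarity refinement is out of scope.
* TSV (optionally gzipped) is the only I/O dialect: no OBO/GAF/SOFT/GML
  parsing, no missing-value imputation — inputs must be complete.
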