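# rankcoex

Co-expression network analysis for expression matrices — genes × conditions
or samples × conditions — built around three ideas:

1. **Rank-based network construction.** Instead of thresholding similarity
   values globally, connect every entity to its *d* most similar partners
   (Pearson correlation or negative Euclidean distance) and take the
   undirected union. Because ranking is asymmetric, the minimum degree is
   *d*, the mean degree lies in [*d*, 2*d*], and hubs can still emerge —
   so both strongly and weakly co-expressed modules stay connected at very
   small *d*, where a global value threshold either floods the strong
   modules with edges or strands the weak ones as singletons.
2. **Qcut module detection.** Modules are found by maximizing
   Newman–Girvan modularity

   Q = Σᵢ (eᵢᵢ − aᵢ²),

   where eᵢᵢ is the fraction of edge weight inside module *i* and aᵢ is
   module *i*'s share of edge endpoints (half the weighted-degree share).
   Qcut recursively applies spectral 2/3/4-way splitting, accepting a
   split only when global Q strictly increases, then greedily refines with
   node moves, module merges and re-splits. The number of modules is an
   output, not an input.
3. **Reference-network module evaluation.** A partition is scored by
   imposing it on an independent *reference network* — e.g. genes linked
   by the cosine of their IDF-weighted annotation vectors
   (w = a·log(n/coverage)) — and reading off the reference network's
   modularity. Size-preserving random shuffles score ≈ 0, so the metric is
   unbiased by module number and size distribution.

The package also ships topology diagnostics with two null models
(degree-preserving rewiring, independent per-row expression permutation),
power-law degree-distribution fits, the adjusted Rand index, cumulative
hypergeometric enrichment with Bonferroni correction, plain-text TSV I/O
for every artifact, and seeded synthetic-data generators (clustered
expression with a planted truth, Gaussian point clouds,
planted-partition graphs) so everything is testable without downloads.

## Worked example

Simulate the clustered benchmark (600 genes, 15 planted clusters, 50
conditions, noise SD 0.4), build the *d* = 4 rank network on Euclidean
distance, detect modules, and compare with the planted truth:

```r
library(rankcoex)

ds  <- simulate_clustered_expression(n_genes = 600, n_clusters = 15,
                                     n_conditions = 50, noise_sd = 0.4,
                                     seed = 11)
sim <- compute_similarity(ds$expr, "negative_euclidean")
net <- rank_network(sim, d = 4)
topology_summary(net)
#> Network: 600 nodes, 1854 edges (0 singletons)
#>   largest component 40, mean degree 6.18, max degree 24
#>   C = 0.3007, <l> = 2.130, diameter 4

res <- qcut_partition(net, seed = 1)
res$modularity
#> Modularity Q = 0.93325 over 15 module(s)
adjusted_rand_index(res$partition, ds$truth)
#> [1] 1
```

Qcut recovers all 15 planted clusters exactly (adjusted Rand index 1)
without being told how many there are; the mean degree 6.18 sits inside
the guaranteed [4, 8] band. Shuffling the detected module labels while
preserving module sizes and re-scoring against a reference network built
from the same edges gives a mean score of −0.002 — the chance baseline
the reference-network metric is calibrated to.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/rankcoex.R`, with subcommands `simulate`, `build-net`, `qcut`,
`topology`, `score-ref`, `enrich` and `ari`; every output file records
the tool version, subcommand, parameters and seed in a `#` header line.

```sh
Rscript inst/cli/rankcoex.R simulate --kind clusters --seed 1 --out bench
Rscript inst/cli/rankcoex.R build-net --expr bench_expr.tsv --method rank \
    --similarity euclidean --d 4 --out edges.tsv
Rscript inst/cli/rankcoex.R qcut --edges edges.tsv --seed 1 --out part.tsv
Rscript inst/cli/rankcoex.R ari --true bench_truth.tsv --pred part.tsv
```

## Documentation

The methods vignette (`vignettes/rank-coexpression-modules.Rmd`) covers
the model and its assumptions, the parameters that matter and their
defaults, what the synthetic generators do and do not emulate, and the
numerical choices (tie-breaking, tolerances, null models).
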