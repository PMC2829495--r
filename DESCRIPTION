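Package: rankcoex
Title: Rank-Based Co-Expression Networks, Qcut Module Detection and
    Reference-Network Module Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for co-expression network analysis of expression
    matrices (genes or samples by conditions): rank-based
    nearest-neighbor and value-based network construction, the
    parameter-free Qcut module detector (recursive spectral splitting
    with greedy merge/move/split refinement of Newman-Girvan
    modularity), network topology diagnostics with degree-preserving
    rewiring and expression-permutation null models, IDF-weighted
    cosine reference networks for unbiased module scoring, clustering
    evaluation statistics (adjusted Rand index, cumulative
    hypergeometric enrichment with Bonferroni correction), and seeded
    synthetic-data generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
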