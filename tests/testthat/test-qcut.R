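test_that("modularity matches hand-derived values on the bridged triangles", {
  g <- make_network_df(c("a", "b", "c", "c", "d", "e"),
                       c("b", "c", "a", "d", "e", "f"))
  g <- igraph::add_edges(g, c("f", "d"))
  part <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  ms <- modularity_score(g, part)
  expect_equal(ms$q, 5 / 14)
  expect_equal(ms$per_module$e_ii, c(3 / 7, 3 / 7))
  expect_equal(ms$per_module$a_i, c(1 / 2, 1 / 2))

  expect_equal(modularity_score(g, setNames(1:6, letters[1:6]))$q, -34 / 196)
  expect_equal(modularity_score(g, setNames(rep(1, 6), letters[1:6]))$q, 0)
})

test_that("modularity errors on edgeless networks and partial partitions", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  expect_error(modularity_score(g, c(a = 1, b = 1, c = 1)), "edgeless")
  tri <- make_network_df(c("a", "b", "c"), c("b", "c", "a"))
  expect_error(modularity_score(tri, c(a = 1, b = 1)), "cover")
})

test_that("modularity agrees with igraph on random weighted graphs", {
  for (seed in 1:10) {
    g <- random_gnp(12, 0.3, seed)
    withr::with_seed(seed + 100, {
      igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 3)
      p <- random_partition_of(igraph::V(g)$name, 4, seed)
    })
    expect_equal(modularity_score(g, p)$q,
                 igraph::modularity(g, p[igraph::V(g)$name],
                                    weights = igraph::E(g)$weight))
  }
})

test_that("weighted modularity with equal weights reduces to unweighted", {
  g <- random_gnp(10, 0.4, 5)
  p <- random_partition_of(igraph::V(g)$name, 3, 5)
  q0 <- modularity_score(g, p)$q
  igraph::E(g)$weight <- rep(2.5, igraph::ecount(g))
  expect_equal(modularity_score(g, p)$q, q0)
})

test_that("spectral split separates cliques and refuses to cut one", {
  g2 <- cliques_graph(5, 2)
  sp <- spectral_split(g2, seed = 1)
  expect_equal(sp$delta_q, 20 / 21 - 1 / 2)
  expect_equal(unname(partition_sizes(as_partition(sp$split))), c(5, 5))
  split_groups <- unname(split(names(sp$split), sp$split))
  truth_groups <- unname(split(names(clique_truth(5, 2)), clique_truth(5, 2)))
  expect_setequal(lapply(split_groups, sort), lapply(truth_groups, sort))

  k5 <- cliques_graph(5, 1)
  expect_null(spectral_split(k5, seed = 1)$split)

  g3 <- cliques_graph(5, 3, ring = TRUE)
  sp3 <- spectral_split(g3, seed = 1)
  expect_equal(max(sp3$split), 3)  # 3-way beats any 2-way on the clique ring
  expect_setequal(unname(lapply(split(names(sp3$split), sp3$split), sort)),
                  unname(lapply(split(names(clique_truth(5, 3)),
                                      clique_truth(5, 3)), sort)))
})

test_that("spectral split reports no split for edgeless subsets", {
  g <- cliques_graph(3, 2)
  sp <- spectral_split(g, nodes = c("v1", "v4"))  # no edge inside subset
  expect_null(sp$split)
  expect_equal(sp$delta_q, 0)
})

test_that("qcut finds the exact optimum on the toy graphs", {
  res <- qcut_partition(cliques_graph(5, 2), seed = 1)
  expect_equal(res$modularity$q, 20 / 21 - 1 / 2)
  expect_equal(max(res$partition), 2)

  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- letters[1:6]
  res6 <- qcut_partition(k6, seed = 1)
  expect_equal(max(res6$partition), 1)
  expect_equal(res6$modularity$q, 0)
})

test_that("qcut recovers planted partitions", {
  aris <- sapply(1:10, function(seed) {
    pp <- planted_partition_graph(rep(8, 4), 0.9, 0.05, seed = seed)
    res <- qcut_partition(pp$network, seed = seed + 1)
    adjusted_rand_index(res$partition, pp$partition)
  })
  expect_gte(median(aris), 0.9)
})

test_that("qcut is deterministic given a seed and relabel-invariant", {
  pp <- planted_partition_graph(rep(6, 3), 0.8, 0.1, seed = 2)
  r1 <- qcut_partition(pp$network, seed = 7)
  r2 <- qcut_partition(pp$network, seed = 7)
  expect_identical(r1, r2)

  perm <- withr::with_seed(3, sample(igraph::vcount(pp$network)))
  g2 <- igraph::permute(pp$network, perm)
  r3 <- qcut_partition(g2, seed = 7)
  expect_equal(adjusted_rand_index(r1$partition, r3$partition), 1)
})

test_that("qcut keeps disconnected components in separate modules", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- paste0("v", 1:8)
  res <- qcut_partition(g, seed = 1)
  expect_equal(max(res$partition), 2)
  expect_equal(res$modularity$q, 0.5)
})

test_that("refinement repairs a misassigned node and respects fixed points", {
  g <- cliques_graph(5, 2)
  truth <- clique_truth(5, 2)
  bad <- truth; bad["v3"] <- 2L
  fixed <- refine_partition(g, bad)
  expect_equal(adjusted_rand_index(fixed, truth), 1)

  again <- refine_partition(g, truth)
  expect_equal(adjusted_rand_index(again, truth), 1)
})

test_that("refinement merges a bad bisection of a clique back to Q = 0", {
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- letters[1:6]
  halves <- setNames(rep(1:2, each = 3), letters[1:6])
  expect_lt(modularity_score(k6, halves)$q, 0)
  merged <- refine_partition(k6, halves)
  expect_equal(max(merged), 1)
  expect_equal(modularity_score(k6, merged)$q, 0)
})

test_that("refinement never decreases Q on random inputs", {
  for (seed in 1:10) {
    g <- random_gnp(15, 0.25, seed)
    p <- random_partition_of(igraph::V(g)$name, 5, seed + 50)
    q0 <- modularity_score(g, p)$q
    withr::with_seed(seed, {
      q1 <- modularity_score(g, refine_partition(g, p))$q
    })
    expect_gte(q1, q0 - 1e-12)
  }
})

test_that("Q stays within [-1, 1] over exhaustive partitions of small graphs", {
  for (seed in 1:10) {
    g <- random_gnp(6, 0.5, seed)
    qs <- q_all_partitions(g)
    expect_true(all(qs >= -1 & qs <= 1))
    # spot-check the oracle itself against the implementation
    L <- all_partitions(6)
    pick <- withr::with_seed(seed, sample(nrow(L), 5))
    for (r in pick) {
      p <- as_partition(setNames(L[r, ], igraph::V(g)$name))
      expect_equal(modularity_score(g, p)$q, qs[r])
    }
  }
})
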