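toy_attrs <- function() {
  m <- matrix(0, 6, 3, dimnames = list(paste0("g", 1:6), c("T1", "T2", "T3")))
  m[c("g1", "g2"), "T1"] <- 1
  m["g1", "T2"] <- 1
  m[paste0("g", 1:6), "T3"] <- 1
  m
}

test_that("annotations propagate to ancestors and filters apply in order", {
  m <- matrix(0, 6, 3, dimnames = list(paste0("g", 1:6),
                                       c("T1", "T2", "T3")))
  m[c("g1", "g2"), "T1"] <- 1
  m["g3", "T2"] <- 1
  m[paste0("g", 1:5), "T3"] <- 1
  dag <- data.frame(child = "T1", parent = "T2")
  out <- propagate_and_filter(m, dag, min_size = 1, max_size = 100)
  expect_true(all(out[c("g1", "g2"), "T2"] == 1))  # ancestors inherited
  expect_equal(sum(out[, "T2"]), 3)                # g3's direct hit kept

  # identical entity sets collapse to the lexicographically smallest id
  m2 <- m[, c("T1", "T3")]
  out2 <- propagate_and_filter(m2, dag, min_size = 1, max_size = 100)
  expect_true("T1" %in% colnames(out2))   # T2 ends identical to T1: dropped
  expect_false("T2" %in% colnames(out2))

  # size filter runs after closure and dedup
  out3 <- propagate_and_filter(m, dag, min_size = 5, max_size = 500)
  expect_identical(colnames(out3), "T3")
  out4 <- propagate_and_filter(m, dag, min_size = 1, max_size = 4)
  expect_false("T3" %in% colnames(out4))
  expect_true(all(c("T1", "T2") %in% colnames(out4)))
})

test_that("IDF weighting follows log(n / coverage)", {
  m <- toy_attrs()[1:4, ]
  m["g3", "T1"] <- 0
  w <- idf_weight(m[, colSums(m) > 0])
  idf <- attr(w, "idf")
  expect_equal(unname(idf["T3"]), 0)          # covers all 4 entities
  expect_equal(unname(idf["T1"]), log(2))     # 2 of 4
  expect_equal(unname(idf["T2"]), log(4))     # 1 of 4 -> maximal
  expect_equal(unname(w["g1", "T2"]), log(4))
  expect_equal(unname(w["g3", "T1"]), 0)

  bad <- cbind(m, T0 = 0)
  expect_error(idf_weight(bad), "zero coverage")
})

test_that("reference network edges are cosines of IDF vectors", {
  m <- matrix(0, 4, 3, dimnames = list(paste0("g", 1:4), c("A", "B", "C")))
  m["g1", c("A", "B")] <- 1
  m["g2", c("B", "C")] <- 1
  w <- idf_weight(m)
  ref <- build_reference_network(w, weight_cutoff = 0)
  e <- igraph::get_edge_ids(ref, c("g1", "g2"))
  expect_equal(igraph::E(ref)$weight[e], 0.2)  # (ln2)^2 / (5 (ln2)^2)
  expect_equal(igraph::vcount(ref), 4)         # all-zero rows stay singletons
  expect_equal(igraph::ecount(ref), 1)

  ident <- matrix(c(1, 1, 1, 0, 1, 1, 0, 0), 4, 2,
                  dimnames = list(c("x", "y", "z", "u"), c("P", "Q")))
  wi <- idf_weight(ident)
  refi <- build_reference_network(wi, 0)
  exy <- igraph::get_edge_ids(refi, c("x", "y"))
  expect_equal(igraph::E(refi)$weight[exy], 1)  # identical nonzero rows
  expect_equal(igraph::ecount(refi), 3)         # u (all-zero) stays singleton
  expect_equal(unname(igraph::degree(refi)["u"]), 0)
})

test_that("cosine weights are invariant to the idf logarithm base", {
  m <- toy_attrs()
  w_nat <- idf_weight(m)
  w_log2 <- sweep(m, 2, log2(nrow(m) / colSums(m)), `*`)
  cosine <- function(w) {
    nrm <- sqrt(rowSums(w^2))
    tcrossprod(w / ifelse(nrm > 0, nrm, 1))
  }
  expect_equal(cosine(w_nat), cosine(w_log2), tolerance = 1e-12)
})

test_that("reference edge set shrinks as the weight cutoff rises", {
  withr::with_seed(21, {
    m <- matrix(rbinom(30 * 8, 1, 0.3), 30, 8,
                dimnames = list(paste0("g", 1:30), paste0("T", 1:8)))
  })
  m <- m[, colSums(m) > 0]
  w <- idf_weight(m)
  counts <- sapply(seq(0, 1, 0.1), function(ct)
    igraph::ecount(build_reference_network(w, ct)))
  expect_true(all(diff(counts) <= 0))
})

test_that("imposed-partition scoring reduces to modularity and hits 0.75", {
  g <- cliques_graph(4, 3)
  part <- clique_truth(4, 3)
  expect_equal(score_partition_on_reference(g, part)$q,
               modularity_score(g, part)$q)

  # reference with all edges internal to 4 equal-weight modules
  ref <- make_network_df(paste0("m", 1:4, "a"), paste0("m", 1:4, "b"),
                         w = rep(1, 4))
  part4 <- setNames(rep(1:4, 2), c(paste0("m", 1:4, "a"), paste0("m", 1:4, "b")))
  expect_equal(score_partition_on_reference(ref, part4)$q, 0.75)

  # entities in the partition but absent from the reference are ignored
  part4x <- c(part4, extra = 9)
  expect_equal(score_partition_on_reference(ref, part4x)$q, 0.75)

  empty <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(empty)$name <- c("a", "b")
  expect_error(score_partition_on_reference(empty, c(a = 1, b = 1)),
               "zero total edge weight")
})

test_that("size-preserving shuffles keep sizes and are uniform", {
  part <- as_partition(setNames(rep(1:3, c(3, 5, 7)), paste0("n", 1:15)))
  s1 <- shuffle_partition_preserving_sizes(part, seed = 4)
  s2 <- shuffle_partition_preserving_sizes(part, seed = 4)
  expect_identical(s1, s2)
  expect_equal(sort(partition_sizes(s1)), c(3, 5, 7))
  expect_setequal(names(s1), names(part))

  two <- c(a = 1L, b = 2L)
  swapped <- sapply(1:1000, function(seed)
    shuffle_partition_preserving_sizes(two, seed = seed)[["a"]] == 2L)
  expect_gt(mean(swapped), 0.44)
  expect_lt(mean(swapped), 0.56)
})

test_that("planted partitions outscore their shuffles by a growing margin", {
  margins <- sapply(c(0.4, 0.8), function(p_in) {
    pp <- planted_partition_graph(rep(10, 4), p_in, 0.05, seed = 31)
    igraph::E(pp$network)$weight <- rep(1, igraph::ecount(pp$network))
    true_q <- score_partition_on_reference(pp$network, pp$partition)$q
    null_q <- mean(sapply(1:30, function(s)
      score_partition_on_reference(
        pp$network,
        shuffle_partition_preserving_sizes(pp$partition, seed = s))$q))
    true_q - null_q
  })
  expect_true(all(margins > 0))
  expect_gt(margins[2], margins[1])
})
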