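# Independent oracles: brute-force modularity over all set partitions,
# pair-counting adjusted Rand index, exhaustive hypergeometric tail.

.partition_cache <- new.env(parent = emptyenv())
cached_partitions <- function(n) {
  key <- as.character(n)
  if (is.null(.partition_cache[[key]]))
    .partition_cache[[key]] <- all_partitions(n)
  .partition_cache[[key]]
}

# Q for every set partition of the graph's nodes, from first principles:
# Q = (internal weight)/W - (sum_c S_c^2)/(4 W^2), with
# sum_c S_c^2 = sum_u s_u^2 + 2 sum_{u<v} s_u s_v [label_u = label_v].
q_all_partitions <- function(net) {
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(net))
    igraph::E(net)$weight else rep.int(1, nrow(el))
  n <- igraph::vcount(net)
  s <- numeric(n)
  for (k in seq_len(nrow(el))) {
    s[el[k, 1L]] <- s[el[k, 1L]] + w[k]
    s[el[k, 2L]] <- s[el[k, 2L]] + w[k]
  }
  W <- sum(w)
  L <- cached_partitions(n)
  inner <- numeric(nrow(L))
  for (k in seq_len(nrow(el)))
    inner <- inner + w[k] * (L[, el[k, 1L]] == L[, el[k, 2L]])
  sumS2 <- rep(sum(s^2), nrow(L))
  pr <- combn(n, 2L)
  for (k in seq_len(ncol(pr))) {
    u <- pr[1L, k]; v <- pr[2L, k]
    sumS2 <- sumS2 + 2 * s[u] * s[v] * (L[, u] == L[, v])
  }
  inner / W - sumS2 / (4 * W^2)
}

# chance-corrected pair-counting ARI (closed form on the 2x2 pair table)
ari_pair_counting <- function(x, y) {
  y <- y[names(x)]
  pr <- combn(length(x), 2L)
  sx <- x[pr[1L, ]] == x[pr[2L, ]]
  sy <- y[pr[1L, ]] == y[pr[2L, ]]
  a <- sum(sx & sy); b <- sum(sx & !sy)
  c <- sum(!sx & sy); d <- sum(!sx & !sy)
  den <- (a + b) * (b + d) + (a + c) * (c + d)
  if (den == 0) return(1)
  2 * (a * d - b * c) / den
}

# P(overlap >= k) by enumerating every possible module draw of size m
# from a universe of N entities of which the first K carry the attribute
hyper_tail_enum <- function(N, K, m, k) {
  draws <- combn(N, m)
  mean(colSums(draws <= K) >= k)
}
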