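# Fixture graphs built in code.

make_network_df <- function(a, b, w = NULL, nodes = NULL) {
  ids <- unique(c(nodes, a, b))
  g <- igraph::graph_from_data_frame(data.frame(node1 = a, node2 = b),
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(w)) igraph::E(g)$weight <- w
  g
}

# k-cliques chained (or ringed) by single bridge edges
cliques_graph <- function(clique_size = 5, n_cliques = 2, ring = FALSE) {
  edges <- NULL
  for (c in seq_len(n_cliques) - 1L) {
    base <- c * clique_size
    pr <- combn(seq_len(clique_size) + base, 2L)
    edges <- cbind(edges, pr)
  }
  for (c in seq_len(n_cliques - 1L)) {
    edges <- cbind(edges, c((c - 1L) * clique_size + 1L, c * clique_size + 1L))
  }
  if (ring && n_cliques > 2L)
    edges <- cbind(edges, c(clique_size * (n_cliques - 1L) + 2L, 2L))
  ids <- paste0("v", seq_len(clique_size * n_cliques))
  df <- data.frame(node1 = ids[edges[1L, ]], node2 = ids[edges[2L, ]])
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g
}

clique_truth <- function(clique_size = 5, n_cliques = 2) {
  as_partition(setNames(rep(seq_len(n_cliques), each = clique_size),
                        paste0("v", seq_len(clique_size * n_cliques))))
}

# Erdos-Renyi graph with named nodes, at least one edge
random_gnp <- function(n, p, seed) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::ecount(g) >= 1L) break
    }
    igraph::V(g)$name <- paste0("v", seq_len(n))
    g
  })
}

# random partition of a graph's nodes into at most kmax labels
random_partition_of <- function(ids, kmax, seed) {
  withr::with_seed(seed, {
    repeat {
      lab <- sample.int(kmax, length(ids), replace = TRUE)
      if (length(ids) == 1L || length(unique(lab)) >= 1L) break
    }
    as_partition(setNames(lab, ids))
  })
}
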