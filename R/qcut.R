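# Newman-Girvan modularity and the Qcut module detector.
#
# Q(part) = sum_i (e_ii - a_i^2), where e_ii is the fraction of total edge
# weight internal to module i and a_i is module i's share of endpoint
# weight (half the weighted-degree share). A single-module partition gives
# Q = 0; Q is always in [-1, 1]. Qcut maximizes Q with no user-set module
# count: recursive spectral 2/3/4-way splitting accepted only when Q
# strictly increases, followed by greedy merge/move/split refinement.

# strict-increase tolerance for accepting an operation
QCUT_TOL <- 1e-10

# internal edge-list view of a network: integer endpoints, weights,
# total weight W and per-node strength s
net_data <- function(net) {
  ids <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(net))
    igraph::E(net)$weight else rep.int(1, nrow(el))
  s <- numeric(length(ids))
  for (k in seq_along(w)) {
    s[el[k, 1L]] <- s[el[k, 1L]] + w[k]
    s[el[k, 2L]] <- s[el[k, 2L]] + w[k]
  }
  list(ids = ids, ei = el[, 1L], ej = el[, 2L], w = w, W = sum(w), s = s)
}

# Q from a label vector (one integer per node, any labeling), given net_data
q_of_labels <- function(nd, lab) {
  internal <- lab[nd$ei] == lab[nd$ej]
  e_in <- sum(nd$w[internal]) / nd$W
  S <- rowsum(nd$s, lab)
  e_in - sum((S / (2 * nd$W))^2)
}

#' Modularity of a partition
#'
#' Evaluates Newman-Girvan modularity, using edge weights when the network
#' is weighted (counts otherwise). The partition must cover exactly the
#' network's nodes.
#'
#' @param net an undirected \pkg{igraph} graph with at least one edge.
#' @param part a partition of the network's nodes (named labels, see
#'   [as_partition()]).
#' @return object of class \code{modularity_score}: list with \code{q} and
#'   \code{per_module}, a data frame of \code{e_ii} (internal weight
#'   fraction) and \code{a_i} (endpoint weight share) per module.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - a, c - d, d - e, e - f, f - d)
#' modularity_score(g, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))$q  # 5/14
#' @export
modularity_score <- function(net, part) {
  part <- as_partition(part)
  nd <- net_data(net)
  if (length(nd$w) == 0L) stop("modularity is undefined for an edgeless network")
  if (!setequal(names(part), nd$ids) || length(part) != length(nd$ids))
    stop("partition must cover exactly the network's nodes")
  lab <- unname(part[nd$ids])
  internal <- lab[nd$ei] == lab[nd$ej]
  e_ii <- rowsum(c(nd$w[internal], numeric(max(lab))) / nd$W,
                 c(lab[nd$ei][internal], seq_len(max(lab))))[, 1L]
  a_i <- rowsum(nd$s, factor(lab, levels = seq_len(max(lab))))[, 1L] /
    (2 * nd$W)
  structure(list(q = sum(e_ii - a_i^2),
                 per_module = data.frame(module = seq_len(max(lab)),
                                         e_ii = e_ii, a_i = a_i,
                                         row.names = NULL)),
            class = "modularity_score")
}

#' @export
print.modularity_score <- function(x, ...) {
  cat(sprintf("Modularity Q = %.5f over %d module(s)\n",
              x$q, nrow(x$per_module)))
  invisible(x)
}

# spectral embedding of a (sub)graph adjacency: top-k eigenvectors of
# D^{-1/2} A D^{-1/2}, rows normalized to unit length (zero rows kept)
spectral_embedding <- function(A, k) {
  deg <- rowSums(A)
  dis <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  M <- A * (dis %o% dis)
  V <- eigen(M, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  V / ifelse(nrm > 0, nrm, 1)
}

#' Best spectral 2-, 3- or 4-way split of a node subset
#'
#' Embeds the induced subgraph with the symmetric normalized adjacency
#' (Ng-Jordan-Weiss style), clusters the rows with k-means (10 restarts)
#' for each k up to \code{max_way}, and evaluates the change in global
#' modularity from replacing the subset's single module with the k-way
#' split. The change only depends on the subset's internal edges and its
#' nodes' global strengths, so no surrounding partition is needed.
#'
#' @param net an undirected \pkg{igraph} graph.
#' @param nodes node names forming the subset (default: all nodes).
#' @param max_way largest number of parts tried (2 to \code{max_way}).
#' @param seed optional integer seed for the k-means restarts.
#' @return list with \code{split} (named integer vector over the subset,
#'   or \code{NULL} when no split increases Q or the subset has no
#'   internal edge) and \code{delta_q} (best Q change found; 0 when there
#'   is no internal edge).
#' @export
spectral_split <- function(net, nodes = igraph::V(net)$name, max_way = 4,
                           seed = NULL) {
  run <- function() {
    nd <- net_data(net)
    idx <- match(nodes, nd$ids)
    if (anyNA(idx)) stop("unknown node in subset")
    inset <- logical(length(nd$ids)); inset[idx] <- TRUE
    keep <- inset[nd$ei] & inset[nd$ej]
    if (!any(keep)) return(list(split = NULL, delta_q = 0))
    loc <- match(seq_along(nd$ids), idx)  # global -> local index
    lei <- loc[nd$ei[keep]]; lej <- loc[nd$ej[keep]]; lw <- nd$w[keep]
    ls <- nd$s[idx]; W <- nd$W
    m <- length(idx)
    q_sub <- function(lab) {
      sum(lw[lab[lei] == lab[lej]]) / W - sum((rowsum(ls, lab) / (2 * W))^2)
    }
    q_whole <- q_sub(rep.int(1L, m))
    A <- matrix(0, m, m)
    A[cbind(lei, lej)] <- A[cbind(lei, lej)] + lw
    A[cbind(lej, lei)] <- A[cbind(lej, lei)] + lw
    best <- list(split = NULL, delta_q = -Inf)
    for (k in 2:min(max_way, m)) {
      V <- spectral_embedding(A, k)
      if (nrow(unique(V)) < k) next
      km <- tryCatch(suppressWarnings(
        kmeans(V, centers = k, nstart = 10, iter.max = 100)),
        error = function(e) NULL)
      if (is.null(km)) next
      dq <- q_sub(km$cluster) - q_whole
      if (dq > best$delta_q)
        best <- list(split = setNames(km$cluster, nodes), delta_q = dq)
    }
    if (!is.finite(best$delta_q)) return(list(split = NULL, delta_q = 0))
    if (best$delta_q <= QCUT_TOL) best$split <- NULL
    best
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Greedy merge/move/split refinement of a partition
#'
#' Repeatedly applies the three operation families — moving a node to a
#' neighboring module, merging two connected modules, and spectrally
#' re-splitting a module — accepting any operation that strictly increases
#' modularity, until a full cycle yields no improvement. Q never
#' decreases. Incremental Q updates are used throughout; with
#' \code{trace = TRUE} the accepted operations and the incrementally
#' maintained Q after each are attached as attribute \code{"trace"} (for
#' auditing against from-scratch evaluation).
#'
#' @inheritParams modularity_score
#' @param trace record accepted operations?
#' @return improved canonical partition (attribute \code{"trace"}: list of
#'   operations, each with the post-operation \code{q}).
#' @export
refine_partition <- function(net, part, trace = FALSE) {
  part <- as_partition(part)
  nd <- net_data(net)
  if (length(nd$w) == 0L) return(part)
  if (!setequal(names(part), nd$ids) || length(part) != length(nd$ids))
    stop("partition must cover exactly the network's nodes")
  lab <- unname(part[nd$ids])
  W <- nd$W; s <- nd$s
  n <- length(nd$ids)
  nextlab <- max(lab) + 1L
  # per-node adjacency (neighbor index, edge weight)
  nb <- vector("list", n); nbw <- vector("list", n)
  for (k in seq_along(nd$w)) {
    i <- nd$ei[k]; j <- nd$ej[k]
    nb[[i]] <- c(nb[[i]], j); nbw[[i]] <- c(nbw[[i]], nd$w[k])
    nb[[j]] <- c(nb[[j]], i); nbw[[j]] <- c(nbw[[j]], nd$w[k])
  }
  S <- numeric(max(lab) * 2L + 8L)
  for (v in seq_len(n)) S[lab[v]] <- S[lab[v]] + s[v]
  grow <- function(S, upto) {
    if (upto > length(S)) S <- c(S, numeric(upto * 2L - length(S)))
    S
  }
  Q <- q_of_labels(nd, lab)
  tr <- list()
  log_op <- function(op) if (trace) tr[[length(tr) + 1L]] <<- op

  repeat {
    improved_cycle <- FALSE

    # node moves: full sweeps in fixed node order until stable
    repeat {
      moved <- FALSE
      for (v in seq_len(n)) {
        if (is.null(nb[[v]])) next
        a <- lab[v]
        kvc <- rowsum(nbw[[v]], lab[nb[[v]]])
        cand <- as.integer(rownames(kvc))
        kva <- if (a %in% cand) kvc[match(a, cand), 1L] else 0
        bestdq <- QCUT_TOL; bestb <- NA_integer_
        for (ci in seq_along(cand)) {
          b <- cand[ci]
          if (b == a) next
          dq <- (kvc[ci, 1L] - kva) / W -
            s[v] * (S[b] - S[a] + s[v]) / (2 * W^2)
          if (dq > bestdq) { bestdq <- dq; bestb <- b }
        }
        if (!is.na(bestb)) {
          S[a] <- S[a] - s[v]; S[bestb] <- S[bestb] + s[v]
          lab[v] <- bestb
          Q <- unname(Q + bestdq)
          log_op(list(op = "move", node = nd$ids[v], from = a, to = bestb,
                      q = Q))
          moved <- TRUE
        }
      }
      if (!moved) break
      improved_cycle <- TRUE
    }

    # merges of connected module pairs, best-first
    repeat {
      cross <- lab[nd$ei] != lab[nd$ej]
      if (!any(cross)) break
      pa <- pmin(lab[nd$ei][cross], lab[nd$ej][cross])
      pb <- pmax(lab[nd$ei][cross], lab[nd$ej][cross])
      agg <- rowsum(nd$w[cross], paste(pa, pb))
      ab <- matrix(as.integer(unlist(strsplit(rownames(agg), " "))),
                   ncol = 2L, byrow = TRUE)
      dq <- agg[, 1L] / W - S[ab[, 1L]] * S[ab[, 2L]] / (2 * W^2)
      bi <- which.max(dq)
      if (dq[bi] <= QCUT_TOL) break
      a <- ab[bi, 1L]; b <- ab[bi, 2L]
      lab[lab == b] <- a
      S[a] <- S[a] + S[b]; S[b] <- 0
      Q <- unname(Q + dq[bi])
      log_op(list(op = "merge", from = b, into = a, q = Q))
      improved_cycle <- TRUE
    }

    # per-module spectral re-splits
    for (m in unique(lab)) {
      members <- which(lab == m)
      if (length(members) < 2L) next
      sp <- spectral_split(net, nd$ids[members])
      if (!is.null(sp$split)) {
        newlabs <- nextlab + sp$split - 1L
        nextlab <- nextlab + max(sp$split)
        S <- grow(S, nextlab)
        lab[members] <- unname(newlabs[match(nd$ids[members],
                                             names(sp$split))])
        for (l in unique(lab[members]))
          S[l] <- sum(s[members][lab[members] == l])
        S[m] <- 0
        Q <- Q + sp$delta_q
        log_op(list(op = "split", module = m,
                    assignment = setNames(lab[members], nd$ids[members]),
                    q = Q))
        improved_cycle <- TRUE
      }
    }

    if (!improved_cycle) break
  }
  out <- as_partition(setNames(lab, nd$ids))
  if (trace) attr(out, "trace") <- tr
  out
}

#' Qcut: parameter-free modularity-maximizing module detection
#'
#' Starts from the connected components, recursively applies
#' [spectral_split()] depth-first — accepting a split only when global
#' modularity strictly increases — and finishes with
#' [refine_partition()]. The number of modules is determined by the data;
#' results are deterministic given \code{seed}.
#'
#' @inheritParams modularity_score
#' @param seed optional integer seed governing all randomness (k-means
#'   restarts).
#' @return list with \code{partition} (canonical partition) and
#'   \code{modularity} (a [modularity_score()]).
#' @examples
#' pp <- planted_partition_graph(rep(8, 4), p_in = 0.9, p_out = 0.05, seed = 1)
#' res <- qcut_partition(pp$network, seed = 1)
#' adjusted_rand_index(res$partition, pp$partition)
#' @export
qcut_partition <- function(net, seed = NULL) {
  run <- function() {
    nd <- net_data(net)
    if (length(nd$w) == 0L)
      stop("modularity is undefined for an edgeless network")
    comp <- igraph::components(net)$membership
    lab <- unname(comp[nd$ids])
    nextlab <- max(lab) + 1L
    queue <- unique(lab)
    while (length(queue)) {
      m <- queue[[1L]]; queue <- queue[-1L]
      members <- which(lab == m)
      if (length(members) < 2L) next
      sp <- spectral_split(net, nd$ids[members])
      if (is.null(sp$split)) next
      newlabs <- nextlab + sp$split - 1L
      nextlab <- nextlab + max(sp$split)
      lab[members] <- unname(newlabs[match(nd$ids[members], names(sp$split))])
      queue <- c(queue, unique(lab[members]))
    }
    part <- refine_partition(net, as_partition(setNames(lab, nd$ids)))
    list(partition = part, modularity = modularity_score(net, part))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' All set partitions of n items
#'
#' Enumerates every set partition of \code{1..n} as restricted-growth
#' label vectors, for brute-force maximization or bounds checks of
#' modularity on small graphs. The count is the Bell number B(n); keep
#' \code{n} at 12 or below.
#'
#' @param n number of items.
#' @return integer matrix, one row per partition, entry \code{[p, i]} =
#'   module label of item \code{i}.
#' @export
all_partitions <- function(n) {
  stopifnot(n >= 1, n <= 12)
  M <- matrix(1L, 1L, 1L); mx <- 1L
  for (k in seq_len(n - 1L)) {
    reps <- mx + 1L
    idx <- rep(seq_along(mx), reps)
    newcol <- sequence(reps)
    M <- cbind(M[idx, , drop = FALSE], newcol)
    mx <- pmax(mx[idx], newcol)
  }
  dimnames(M) <- NULL
  M
}
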