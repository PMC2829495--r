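# Pairwise similarity and co-expression network construction.
#
# Rank-based construction connects each entity to its d most similar
# partners; because ranking is asymmetric, the union graph has minimum
# degree d and mean degree between d and 2d, while the maximum degree can
# be as large as n - 1. Value-based construction applies one global
# similarity threshold.

#' Pairwise similarity between expression profiles
#'
#' Computes an entity-by-entity similarity matrix, oriented so that larger
#' always means more similar: Pearson correlation, or negative Euclidean
#' distance. The diagonal is set to \code{NA} and ignored by all consumers.
#' Under Pearson, zero-variance (flat) profiles cannot be correlated; their
#' similarities are set to \code{-Inf} so they rank last, with a warning.
#'
#' @param expr numeric matrix, rows = entities, columns = conditions.
#' @param method \code{"pearson"} or \code{"negative_euclidean"}.
#' @return symmetric numeric matrix with entity dimnames, \code{NA}
#'   diagonal, and attribute \code{kind} recording the method.
#' @examples
#' x <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
#' compute_similarity(x, "pearson")["a", "b"]  # 0.8
#' @export
compute_similarity <- function(expr,
                               method = c("pearson", "negative_euclidean")) {
  method <- match.arg(method)
  expr <- validate_expression_matrix(expr)
  if (method == "pearson") {
    sds <- apply(expr, 1L, function(r) max(r) - min(r))
    flat <- sds == 0
    s <- suppressWarnings(cor(t(expr)))
    if (any(flat)) {
      warning("zero-variance profile(s) ranked last under pearson: ",
              paste(rownames(expr)[flat], collapse = ", "))
      s[flat, ] <- -Inf
      s[, flat] <- -Inf
    }
  } else {
    s <- -as.matrix(dist(expr))
  }
  dimnames(s) <- list(rownames(expr), rownames(expr))
  diag(s) <- NA_real_
  structure(s, kind = method)
}

#' Rank-based nearest-neighbor co-expression network
#'
#' Connects every entity to the \code{d} entities most similar to it and
#' takes the undirected union: an edge exists if either endpoint lists the
#' other in its top-\code{d}. Ties are broken deterministically by
#' (similarity descending, node index ascending) and exactly \code{d}
#' neighbors are taken. With \code{floor} set, edges whose similarity is
#' below \code{floor} are removed after the rank step (used for sample
#' networks, where correlations below 0.2 are considered unreliable).
#'
#' Without a floor the minimum degree is \code{d} and the mean degree lies
#' in \code{[d, 2d]}.
#'
#' @param sim symmetric similarity matrix from [compute_similarity()].
#' @param d number of neighbors, \code{1 <= d <= n - 1}.
#' @param floor optional similarity floor applied after ranking.
#' @return an undirected simple \pkg{igraph} graph over all entities
#'   (nodes dropped below the floor stay as singletons).
#' @export
rank_network <- function(sim, d, floor = NULL) {
  n <- nrow(sim)
  if (d < 1L || d > n - 1L) stop("d must be between 1 and n - 1")
  ids <- rownames(sim)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- NA_real_
    ord <- order(-s, seq_len(n), na.last = TRUE)[seq_len(d)]
    from <- c(from, rep.int(i, d)); to <- c(to, ord)
  }
  key <- paste(pmin(from, to), pmax(from, to))
  keep <- !duplicated(key)
  from <- from[keep]; to <- to[keep]
  if (!is.null(floor)) {
    svals <- sim[cbind(from, to)]
    ok <- svals >= floor
    from <- from[ok]; to <- to[ok]
  }
  make_network(data.frame(node1 = ids[from], node2 = ids[to]), nodes = ids)
}

#' Value-based co-expression network
#'
#' Connects two entities when their similarity is at or above a global
#' threshold (closed comparison). Entities with no qualifying partner are
#' retained as singletons.
#'
#' @inheritParams rank_network
#' @param threshold global similarity threshold.
#' @return an undirected simple \pkg{igraph} graph over all entities.
#' @export
value_network <- function(sim, threshold) {
  ids <- rownames(sim)
  ut <- upper.tri(sim)
  hit <- which(ut & !is.na(sim) & sim >= threshold, arr.ind = TRUE)
  make_network(data.frame(node1 = ids[hit[, 1L]], node2 = ids[hit[, 2L]]),
               nodes = ids)
}

#' Threshold achieving a target mean degree
#'
#' Returns the largest threshold \code{t} such that [value_network()] at
#' \code{t} has mean degree at least \code{target_mean_degree}: exactly the
#' \code{ceiling(n * target / 2)}-th largest off-diagonal similarity
#' (counting each unordered pair once).
#'
#' @inheritParams rank_network
#' @param target_mean_degree desired average degree, in \code{(0, n - 1]}.
#' @return the similarity threshold.
#' @export
threshold_for_mean_degree <- function(sim, target_mean_degree) {
  n <- nrow(sim)
  if (target_mean_degree <= 0 || target_mean_degree > n - 1)
    stop("target mean degree must be in (0, n - 1]")
  vals <- sim[upper.tri(sim)]
  vals <- vals[!is.na(vals)]
  m <- ceiling(n * target_mean_degree / 2)
  m <- min(m, length(vals))
  sort(vals, decreasing = TRUE)[m]
}
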