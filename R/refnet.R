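# Reference networks from gene-attribute annotations, and the
# imposed-partition modularity score.
#
# A reference network links entities that share annotations (GO terms, TF
# targets, ...), weighting edges by the cosine of IDF-weighted attribute
# vectors so that non-specific attributes contribute little. Imposing a
# co-expression partition on the reference network and reading off its
# weighted modularity scores the partition without bias from the number
# or sizes of modules.

#' Propagate annotations up an ontology and filter attributes
#'
#' Closes the incidence under ancestor propagation (an entity annotated to
#' a term is also annotated to all the term's ancestors), removes
#' duplicate attributes (among attributes with identical entity sets only
#' the lexicographically smallest id is kept), then removes attributes
#' covering fewer than \code{min_size} or more than \code{max_size}
#' entities.
#'
#' @param attrs binary entity x attribute matrix (see
#'   [read_attribute_table()]).
#' @param dag data frame of \code{child}, \code{parent} term edges
#'   (acyclic); terms absent from the dag are treated as parentless.
#' @param min_size,max_size attribute coverage bounds (defaults 5 and 500,
#'   the usual GO-term filter).
#' @return filtered binary entity x attribute matrix.
#' @export
propagate_and_filter <- function(attrs, dag = NULL, min_size = 5,
                                 max_size = 500) {
  if (!is.null(dag) && nrow(dag)) {
    validate_term_dag(dag)
    terms <- unique(c(colnames(attrs), dag$child, dag$parent))
    m <- matrix(0, nrow(attrs), length(terms),
                dimnames = list(rownames(attrs), terms))
    m[, colnames(attrs)] <- attrs
    parents <- split(dag$parent, dag$child)
    anc_cache <- new.env(parent = emptyenv())
    ancestors <- function(t) {
      got <- mget(t, anc_cache, ifnotfound = list(NULL))[[1L]]
      if (!is.null(got)) return(got)
      ps <- parents[[t]]
      res <- if (is.null(ps)) character()
             else unique(c(ps, unlist(lapply(ps, ancestors))))
      assign(t, res, anc_cache)
      res
    }
    for (t in colnames(attrs)) {
      anc <- ancestors(t)
      if (length(anc)) {
        hit <- m[, t] > 0
        m[hit, anc] <- 1
      }
    }
    attrs <- m
  }
  # dedup: identical entity sets keep the lexicographically smallest id
  sig <- apply(attrs, 2L, paste, collapse = "")
  ord <- order(colnames(attrs))
  keep_names <- colnames(attrs)[ord][!duplicated(sig[ord])]
  attrs <- attrs[, colnames(attrs) %in% keep_names, drop = FALSE]
  cov <- colSums(attrs)
  attrs[, cov >= min_size & cov <= max_size, drop = FALSE]
}

#' IDF-weight an attribute matrix
#'
#' Transforms binary incidence \code{a_ij} into \code{w_ij = a_ij *
#' idf_j} with \code{idf_j = log(n / sum_i a_ij)} (natural log; the
#' downstream cosine is invariant to the base). Attributes occurring in
#' many entities receive low weight; an attribute covering all entities
#' gets weight zero.
#'
#' @param attrs binary entity x attribute matrix; every attribute must
#'   cover at least one entity.
#' @return numeric weight matrix of the same shape, with the per-attribute
#'   IDF attached as attribute \code{"idf"}.
#' @export
idf_weight <- function(attrs) {
  cov <- colSums(attrs != 0)
  if (any(cov == 0))
    stop("attribute with zero coverage: ", colnames(attrs)[cov == 0][1L])
  idf <- log(nrow(attrs) / cov)
  w <- sweep(attrs, 2L, idf, `*`)
  attr(w, "idf") <- setNames(idf, colnames(attrs))
  w
}

#' Build an IDF-weighted cosine reference network
#'
#' Links two entities when they share at least one attribute and the
#' cosine of their IDF-weighted attribute vectors is at or above
#' \code{weight_cutoff}; the cosine becomes the edge weight. Entities
#' with all-zero weight vectors remain singletons.
#'
#' @param wattrs weighted attribute matrix from [idf_weight()].
#' @param weight_cutoff cosine cutoff in \code{[0, 1]}.
#' @return weighted undirected \pkg{igraph} graph over all entities.
#' @export
build_reference_network <- function(wattrs, weight_cutoff = 0) {
  if (weight_cutoff < 0 || weight_cutoff > 1)
    stop("weight_cutoff must be in [0, 1]")
  ids <- rownames(wattrs)
  share <- (wattrs != 0) %*% t(wattrs != 0) > 0
  nrm <- sqrt(rowSums(wattrs^2))
  cosim <- tcrossprod(wattrs / ifelse(nrm > 0, nrm, 1))
  hit <- which(upper.tri(cosim) & share & cosim >= weight_cutoff &
                 cosim > 0, arr.ind = TRUE)
  make_network(data.frame(node1 = ids[hit[, 1L]], node2 = ids[hit[, 2L]]),
               weights = cosim[hit], nodes = ids)
}

#' Score a partition against a reference network
#'
#' Imposes the partition's module memberships on the reference network and
#' evaluates the reference network's weighted modularity. A score of 1
#' means the modules perfectly agree with the reference network's modular
#' structure; size-preserving random shuffles score near 0, so the metric
#' is unbiased by module number and size distribution. Entities in the
#' partition but absent from the reference network contribute nothing.
#'
#' @param ref weighted reference network (see
#'   [build_reference_network()]); must have positive total edge weight.
#' @param part a partition covering at least the reference network's
#'   nodes.
#' @return a [modularity_score()] of the reference network under the
#'   imposed labels.
#' @export
score_partition_on_reference <- function(ref, part) {
  if (igraph::ecount(ref) == 0L)
    stop("reference network has zero total edge weight")
  part <- as_partition(part)
  ids <- igraph::V(ref)$name
  missing <- setdiff(ids, names(part))
  if (length(missing))
    stop("partition does not cover reference node(s): ", missing[1L])
  modularity_score(ref, restrict_partition(part, ids))
}

#' Shuffle a partition preserving module sizes
#'
#' Permutes the node labels uniformly at random, leaving the multiset of
#' module sizes untouched — the null model for reference-network scores.
#'
#' @param part a partition.
#' @param seed optional integer seed.
#' @return shuffled canonical partition over the same nodes.
#' @export
shuffle_partition_preserving_sizes <- function(part, seed = NULL) {
  part <- as_partition(part)
  run <- function() as_partition(setNames(unname(part),
                                          sample(names(part))))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
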