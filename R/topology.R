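# Topology statistics and the two null models used to contrast real
# rank-based co-expression networks with chance: degree-preserving
# rewiring and independent per-row permutation of the expression data.

#' Topology summary of a network
#'
#' Singleton (degree-0) nodes are excluded from the clustering
#' coefficient, which is the mean of \code{C_i = 2 n_i / (k_i (k_i - 1))}
#' over non-singleton nodes (\code{C_i = 0} when \code{k_i = 1}). Path
#' length and diameter are over reachable pairs only. The summary also
#' carries the degree histogram \code{f(k)} and the mean clustering
#' coefficient per degree \code{C(k)} used for hierarchical-modularity
#' plots.
#'
#' @param net an undirected \pkg{igraph} graph.
#' @return list of class \code{topology_summary}: \code{n_nodes},
#'   \code{n_edges}, \code{n_singletons}, \code{largest_component_size},
#'   \code{mean_degree}, \code{max_degree}, \code{clustering_coefficient},
#'   \code{average_path_length}, \code{diameter},
#'   \code{degree_histogram} (data frame \code{k}, \code{count}) and
#'   \code{ck_curve} (data frame \code{k}, \code{mean_c}).
#' @export
topology_summary <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L)
    return(structure(list(n_nodes = 0L, n_edges = 0L, n_singletons = 0L,
                          largest_component_size = 0L, mean_degree = 0,
                          max_degree = 0, clustering_coefficient = 0,
                          average_path_length = 0, diameter = 0,
                          degree_histogram = data.frame(k = integer(),
                                                        count = integer()),
                          ck_curve = data.frame(k = integer(),
                                                mean_c = numeric())),
                     class = "topology_summary"))
  deg <- igraph::degree(net)
  ci <- igraph::transitivity(net, type = "local", isolates = "zero")
  nonsing <- deg > 0
  comp <- igraph::components(net)
  d <- igraph::distances(net, weights = NA)
  finite_off <- is.finite(d) & upper.tri(d)
  reach <- d[finite_off]
  hist_df <- as.data.frame(table(k = deg), stringsAsFactors = FALSE)
  hist_df$k <- as.integer(hist_df$k)
  names(hist_df)[2L] <- "count"
  ck <- aggregate(list(mean_c = ci[nonsing]), list(k = deg[nonsing]), mean)
  structure(list(
    n_nodes = n,
    n_edges = igraph::ecount(net),
    n_singletons = sum(!nonsing),
    largest_component_size = max(comp$csize),
    mean_degree = mean(deg),
    max_degree = max(deg),
    clustering_coefficient = if (any(nonsing)) mean(ci[nonsing]) else 0,
    average_path_length = if (length(reach)) mean(reach) else 0,
    diameter = if (length(reach)) max(reach) else 0,
    degree_histogram = hist_df,
    ck_curve = ck
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Network: %d nodes, %d edges (%d singletons)\n",
    "  largest component %d, mean degree %.2f, max degree %d\n",
    "  C = %.4f, <l> = %.3f, diameter %d\n"),
    x$n_nodes, x$n_edges, x$n_singletons, x$largest_component_size,
    x$mean_degree, x$max_degree, x$clustering_coefficient,
    x$average_path_length, x$diameter))
  invisible(x)
}

#' Fit a power law to a degree histogram
#'
#' Fits \code{f(k) = c * k^-gamma} by least squares on
#' \code{(log10 k, log10 f(k))} over degrees \code{k >= 1} with positive
#' frequency; no binning. Scale-free networks typically show gamma
#' between 2 and 3.
#'
#' @param degree_histogram data frame with columns \code{k} and
#'   \code{count} (as produced by [topology_summary()]), or a network to
#'   take the histogram from.
#' @return list of class \code{power_law_fit}: \code{gamma} (= minus the
#'   fitted slope), \code{c} (prefactor), \code{k_range} used.
#' @export
fit_power_law <- function(degree_histogram) {
  if (inherits(degree_histogram, "igraph"))
    degree_histogram <- topology_summary(degree_histogram)$degree_histogram
  h <- degree_histogram[degree_histogram$k >= 1 & degree_histogram$count > 0, ]
  if (nrow(h) < 3L)
    stop("power-law fit needs >= 3 distinct degrees with nonzero frequency")
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(h$k),
                                            y = log10(h$count)))
  co <- stats::coef(fit)
  structure(list(gamma = -unname(co[2L]), c = 10^unname(co[1L]),
                 k_range = range(h$k)),
            class = "power_law_fit")
}

#' Degree-preserving random rewiring null model
#'
#' Randomizes the edges by repeated double-edge swaps that reject
#' self-loops and duplicate edges, so every node keeps its exact degree
#' while triangles (and hence the clustering coefficient) are destroyed.
#'
#' @param net an undirected \pkg{igraph} graph with >= 2 edges.
#' @param seed optional integer seed.
#' @param n_swaps number of attempted swaps (default \code{10 * |E|}).
#' @return rewired \pkg{igraph} graph with identical degree sequence.
#' @export
rewire_preserving_degrees <- function(net, seed = NULL,
                                      n_swaps = 10 * igraph::ecount(net)) {
  if (igraph::ecount(net) < 2L) stop("rewiring needs at least 2 edges")
  run <- function() igraph::rewire(net,
                                   igraph::keeping_degseq(loops = FALSE,
                                                          niter = n_swaps))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Permuted-expression null model
#'
#' Permutes each entity's expression values independently across
#' conditions, destroying all co-expression while preserving every row's
#' value multiset. Rebuilding a rank network from the result gives the
#' "permuted data" null.
#'
#' @param expr numeric expression matrix (entities x conditions).
#' @param seed optional integer seed.
#' @return matrix of the same shape and dimnames.
#' @export
permute_expression_rows <- function(expr, seed = NULL) {
  run <- function() {
    out <- t(apply(expr, 1L, sample))
    dimnames(out) <- dimnames(expr)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
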