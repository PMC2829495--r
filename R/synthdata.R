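# Seeded synthetic-data generators: clustered expression matrices with a
# planted truth, Gaussian point clouds for the connectivity experiment,
# and planted-partition benchmark graphs. Pure functions of their seed.

#' Simulate clustered expression data with a planted partition
#'
#' Emulates the synthetic microarray benchmark: each cluster gets a
#' template profile drawn i.i.d. standard normal per condition (values
#' are log-scale, so raw intensities are log-normal), and each gene is
#' its cluster template plus i.i.d. Gaussian noise. Defaults: 600 genes
#' in 15 equal clusters of 40 under 50 conditions. Noise SDs of interest
#' run from 0 (identical within-cluster profiles) through 1.2 (clusters
#' barely distinguishable).
#'
#' @param n_genes,n_clusters,n_conditions dataset shape.
#' @param noise_sd standard deviation of the per-gene Gaussian noise.
#' @param cluster_sizes optional integer vector of cluster sizes summing
#'   to \code{n_genes}; default as equal as possible.
#' @param seed optional integer seed.
#' @return list of class \code{synthetic_dataset}: \code{expr} (matrix
#'   genes x conditions), \code{truth} (planted partition), \code{params}.
#' @export
simulate_clustered_expression <- function(n_genes = 600, n_clusters = 15,
                                          n_conditions = 50, noise_sd = 0.4,
                                          cluster_sizes = NULL, seed = NULL) {
  if (n_clusters > n_genes) stop("more clusters than genes")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(cluster_sizes)) {
    cluster_sizes <- rep(n_genes %/% n_clusters, n_clusters)
    extra <- n_genes %% n_clusters
    if (extra) cluster_sizes[seq_len(extra)] <- cluster_sizes[seq_len(extra)] + 1L
  }
  if (sum(cluster_sizes) != n_genes)
    stop("cluster_sizes must sum to n_genes")
  run <- function() {
    templates <- matrix(rnorm(n_clusters * n_conditions),
                        n_clusters, n_conditions)
    truth <- rep(seq_len(n_clusters), cluster_sizes)
    expr <- templates[truth, , drop = FALSE] +
      matrix(rnorm(n_genes * n_conditions, sd = noise_sd),
             n_genes, n_conditions)
    dimnames(expr) <- list(sprintf("g%04d", seq_len(n_genes)),
                           sprintf("c%02d", seq_len(n_conditions)))
    structure(list(expr = expr,
                   truth = as_partition(setNames(truth, rownames(expr))),
                   params = list(n_genes = n_genes, n_clusters = n_clusters,
                                 n_conditions = n_conditions,
                                 noise_sd = noise_sd,
                                 cluster_sizes = cluster_sizes,
                                 seed = seed)),
              class = "synthetic_dataset")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Gaussian point cloud
#'
#' \code{n_points} i.i.d. standard-normal points in \code{dim}
#' dimensions, as an expression-matrix-shaped input for the rank-network
#' connectivity experiment (a nearest-neighbor graph on random geometric
#' points connects at very small \code{d} once the dimension exceeds
#' about 10).
#'
#' @param n_points number of points (rows).
#' @param dim number of dimensions (columns), >= 1.
#' @param seed optional integer seed.
#' @return numeric matrix \code{n_points x dim} with row and column
#'   names.
#' @export
gaussian_cloud <- function(n_points = 1000, dim, seed = NULL) {
  if (dim < 1) stop("dim must be >= 1")
  run <- function() {
    m <- matrix(rnorm(n_points * dim), n_points, dim)
    dimnames(m) <- list(sprintf("p%04d", seq_len(n_points)),
                        sprintf("d%02d", seq_len(dim)))
    m
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Planted-partition benchmark graph
#'
#' Connects within-group pairs independently with probability
#' \code{p_in} and between-group pairs with \code{p_out}; the planted
#' grouping is returned alongside the graph as ground truth for module
#' detectors.
#'
#' @param sizes integer vector of group sizes.
#' @param p_in,p_out edge probabilities, \code{0 <= p_out <= p_in <= 1}.
#' @param seed optional integer seed.
#' @return list: \code{network} (\pkg{igraph} graph) and
#'   \code{partition} (planted truth).
#' @export
planted_partition_graph <- function(sizes, p_in, p_out, seed = NULL) {
  if (p_out > p_in || p_in > 1 || p_out < 0)
    stop("need 0 <= p_out <= p_in <= 1")
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  ids <- sprintf("n%03d", seq_len(n))
  run <- function() {
    pr <- combn(n, 2L)
    p <- ifelse(grp[pr[1L, ]] == grp[pr[2L, ]], p_in, p_out)
    keep <- runif(ncol(pr)) < p
    net <- make_network(data.frame(node1 = ids[pr[1L, keep]],
                                   node2 = ids[pr[2L, keep]]),
                        nodes = ids)
    list(network = net,
         partition = as_partition(setNames(grp, ids)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Smallest neighbor count connecting a rank network
#'
#' Builds rank networks of increasing \code{d} on one similarity matrix
#' and returns the smallest \code{d} whose network is a single connected
#' component (the Gaussian-cloud connectivity experiment).
#'
#' @param sim similarity matrix from [compute_similarity()].
#' @param d_max give up beyond this \code{d}.
#' @return smallest connecting \code{d}, or \code{NA} if none up to
#'   \code{d_max}.
#' @export
smallest_connecting_d <- function(sim, d_max = 10) {
  for (d in seq_len(d_max)) {
    if (igraph::components(rank_network(sim, d))$no == 1L) return(d)
  }
  NA_integer_
}
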