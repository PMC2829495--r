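# Partition-accuracy and functional-enrichment statistics.

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table of the two partitions: 1 means identical up to relabeling, values
#' near 0 are what random assignments with the same sizes achieve.
#'
#' @param x,y partitions over the same object set (named labels).
#' @return the adjusted Rand index.
#' @examples
#' adjusted_rand_index(c(a = 1, b = 1, c = 2, d = 2),
#'                     c(a = 1, b = 2, c = 1, d = 2))  # -0.5
#' @export
adjusted_rand_index <- function(x, y) {
  x <- as_partition(x); y <- as_partition(y)
  if (!setequal(names(x), names(y)) || length(x) != length(y))
    stop("partitions must cover the same object set")
  y <- y[names(x)]
  tab <- table(x, y)
  n <- length(x)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(tab)
  sum_i <- ch2(rowSums(tab))
  sum_j <- ch2(colSums(tab))
  expected <- sum_i * sum_j / ch2(n)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Cumulative hypergeometric enrichment of an attribute in a module
#'
#' Tests whether the overlap between a module and an attribute's entity
#' set is larger than expected when drawing the module from the universe:
#' raw p = P(X >= k) for X ~ Hypergeometric(universe, attribute,
#' module). Fold enrichment is the overlap fraction over the attribute's
#' background frequency.
#'
#' @param module,attribute character vectors of entity ids, both subsets
#'   of \code{universe} and non-empty.
#' @param universe character vector of all entity ids under
#'   consideration.
#' @return list: \code{overlap}, \code{module_size},
#'   \code{attribute_size}, \code{universe_size}, \code{fold},
#'   \code{p_raw}.
#' @export
hypergeometric_enrichment <- function(module, attribute, universe) {
  module <- unique(module); attribute <- unique(attribute)
  universe <- unique(universe)
  if (length(module) == 0L || length(attribute) == 0L)
    stop("module and attribute must be non-empty")
  if (!all(module %in% universe) || !all(attribute %in% universe))
    stop("module and attribute must be subsets of the universe")
  N <- length(universe); m <- length(module); K <- length(attribute)
  k <- length(intersect(module, attribute))
  list(overlap = k, module_size = m, attribute_size = K, universe_size = N,
       fold = (k / m) / (K / N),
       p_raw = phyper(k - 1, K, N - K, m, lower.tail = FALSE))
}

#' Enrichment summary of a partition against an attribute matrix
#'
#' Tests every (module, attribute) pair with the cumulative
#' hypergeometric test over the universe of partitioned entities present
#' in the attribute matrix. Attributes with no member in that universe
#' are not tested. P-values are Bonferroni-corrected by the number of
#' tests performed (modules x attributes tested). For each significance
#' level in \code{alpha_grid} the summary reports the number of enriched
#' (module, attribute) pairs and the fraction of modules with at least
#' one enriched attribute.
#'
#' @param part a partition.
#' @param attrs binary entity x attribute matrix.
#' @param alpha_grid significance levels on the corrected p-values.
#' @return list: \code{tests} (one row per tested pair, with raw and
#'   corrected p) and \code{summary} (one row per alpha:
#'   \code{n_enriched_terms}, \code{frac_modules_enriched}).
#' @export
enrichment_summary <- function(part, attrs, alpha_grid = 0.05) {
  part <- as_partition(part)
  universe <- intersect(names(part), rownames(attrs))
  if (length(universe) == 0L) stop("partition and attributes share no entity")
  sub <- attrs[universe, , drop = FALSE]
  tested <- colnames(sub)[colSums(sub != 0) > 0]
  modules <- sort(unique(part[universe]))
  rows <- list()
  for (m in modules) {
    mod_ents <- universe[part[universe] == m]
    for (a in tested) {
      att_ents <- universe[sub[, a] != 0]
      h <- hypergeometric_enrichment(mod_ents, att_ents, universe)
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, attribute = a, overlap = h$overlap,
                   module_size = h$module_size,
                   attribute_size = h$attribute_size,
                   universe_size = h$universe_size, fold = h$fold,
                   p_raw = h$p_raw)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_corrected <- pmin(1, tests$p_raw * nrow(tests))
  summary <- do.call(rbind, lapply(alpha_grid, function(alpha) {
    sig <- tests[tests$p_corrected <= alpha, ]
    data.frame(alpha = alpha,
               n_enriched_terms = nrow(sig),
               frac_modules_enriched =
                 length(unique(sig$module)) / length(modules))
  }))
  list(tests = tests, summary = summary)
}
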