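#' Coerce labels to a canonical partition
#'
#' A partition assigns every node a module label; canonical form is a named
#' integer vector with labels renumbered contiguously from 1 in order of
#' the sorted original labels (numeric sort when all labels are numeric,
#' lexicographic otherwise), so that two partitions with the same grouping
#' compare equal.
#'
#' @param x a named vector (or factor) of module labels; names are node ids.
#' @return named integer vector with labels in \code{1..k}, every module
#'   non-empty.
#' @examples
#' as_partition(c(a = 5, b = 9, c = 5))
#' @export
as_partition <- function(x) {
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("partition must be a named vector (names are node ids)")
  if (anyDuplicated(names(x)))
    stop("duplicate node id in partition: ",
         names(x)[anyDuplicated(names(x))])
  if (length(x) == 0L) stop("empty partition")
  if (anyNA(x)) stop("missing module label in partition")
  lab <- as.character(unclass(x))
  u <- unique(lab)
  num <- suppressWarnings(as.numeric(u))
  u <- if (!anyNA(num)) u[order(num)] else sort(u)
  out <- match(lab, u)
  names(out) <- names(x)
  out
}

#' Module sizes of a partition
#'
#' @param part a partition (see [as_partition()]).
#' @return integer vector of module sizes indexed by label.
#' @export
partition_sizes <- function(part) {
  part <- as_partition(part)
  tabulate(part, nbins = max(part))
}

# partition restricted to the given node ids, relabeled contiguously
restrict_partition <- function(part, ids) {
  keep <- part[names(part) %in% ids]
  if (length(keep) == 0L) stop("partition covers none of the requested nodes")
  as_partition(keep)
}
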