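# Plain-text tabular I/O for every pipeline artifact.
#
# One dialect only: tab-separated, UTF-8, '#' lines are comments. Paths
# ending in ".gz" are read and written through a gzip connection.

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

write_tsv <- function(df, path, header = NULL) {
  con <- open_out(path)
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = "character", quote = "", ...)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of condition ids and a first column of entity
#' (gene or sample) ids. Values must be numeric and complete; they are
#' taken as already log-scale. Row and column order are preserved.
#'
#' @param path TSV file (optionally gzipped).
#' @return numeric matrix, rows = entities, columns = conditions.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 3L) stop("expression matrix needs >= 2 condition columns")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate entity id: ", dup[1L])
  vals <- as.matrix(df[-1L])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at entity '%s', condition '%s'",
                 ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  rownames(vals) <- ids
  validate_expression_matrix(vals)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be numeric")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs >= 2 entities and >= 2 conditions")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("entity ids must be present and unique")
  if (anyNA(x)) stop("expression matrix contains missing values")
  x
}

#' Write an expression matrix to TSV
#'
#' @param expr numeric matrix with entity row names and condition column
#'   names.
#' @inheritParams read_expression_matrix
#' @param header optional character vector of comment lines (written with a
#'   leading \code{#}).
#' @export
write_expression_matrix <- function(expr, path, header = NULL) {
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE)
  write_tsv(df, path, header = header)
}

#' Read a network from a TSV edge list
#'
#' Columns \code{node1}, \code{node2} and optionally \code{weight}.
#' Self-loops and duplicate edges with conflicting weights are errors;
#' weights must be positive. Extra isolated nodes can be declared with
#' \code{nodes}.
#'
#' @inheritParams read_expression_matrix
#' @param nodes optional character vector of node ids to include even if
#'   they carry no edge (singletons).
#' @return an undirected simple \pkg{igraph} graph; weighted if the file
#'   has a weight column.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("edge list needs columns node1, node2[, weight]")
  a <- df[[1L]]; b <- df[[2L]]
  loop <- a == b
  if (any(loop)) stop("self-loop on node '", a[which(loop)[1L]], "'")
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  w <- NULL
  if (ncol(df) >= 3L) {
    w <- as.numeric(df[[3L]])
    if (anyNA(w) || any(w <= 0)) stop("edge weights must be positive numbers")
  }
  if (anyDuplicated(key)) {
    if (is.null(w)) {
      keep <- !duplicated(key)
      a <- a[keep]; b <- b[keep]
    } else {
      rng <- tapply(w, key, function(z) diff(range(z)))
      if (any(rng > 0))
        stop("duplicate edge with conflicting weight: ",
             gsub("\r", "--", names(rng)[rng > 0][1L]))
      keep <- !duplicated(key)
      a <- a[keep]; b <- b[keep]; w <- w[keep]
    }
  }
  make_network(data.frame(node1 = a, node2 = b), weights = w, nodes = nodes)
}

# Build a validated network from an edge data frame (+ optional weights and
# isolated nodes).
make_network <- function(edges, weights = NULL, nodes = NULL) {
  ids <- unique(c(nodes, edges[[1L]], edges[[2L]]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}

#' Write a network to a TSV edge list
#'
#' @param net an undirected \pkg{igraph} graph.
#' @inheritParams write_expression_matrix
#' @export
write_edge_list <- function(net, path, header = NULL) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(node1 = el[, 1L], node2 = el[, 2L])
  if ("weight" %in% igraph::edge_attr_names(net))
    df$weight <- igraph::E(net)$weight
  write_tsv(df, path, header = header)
}

#' Read a partition from TSV
#'
#' Columns \code{node_id}, \code{module_label}. Labels are renumbered to
#' contiguous \code{1..k} (see [as_partition()]).
#'
#' @inheritParams read_expression_matrix
#' @return a canonical partition.
#' @export
read_partition <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("partition file needs columns node_id, module_label")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("node listed twice in partition: ", dup[1L])
  as_partition(setNames(df[[2L]], ids))
}

#' Write a partition to TSV
#'
#' @param part a partition.
#' @inheritParams write_expression_matrix
#' @export
write_partition <- function(part, path, header = NULL) {
  part <- as_partition(part)
  write_tsv(data.frame(node_id = names(part), module_label = unname(part)),
            path, header = header)
}

#' Read a binary entity-attribute incidence table
#'
#' Rows are (entity, attribute) pairs; the result has incidence 1 for every
#' listed pair. Repeated pairs are allowed and collapse to 1.
#'
#' @inheritParams read_expression_matrix
#' @return binary matrix, rows = entities, columns = attributes.
#' @export
read_attribute_table <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("attribute table needs columns entity, attribute")
  ents <- unique(df[[1L]]); atts <- unique(df[[2L]])
  m <- matrix(0, length(ents), length(atts), dimnames = list(ents, atts))
  m[cbind(match(df[[1L]], ents), match(df[[2L]], atts))] <- 1
  m
}

#' Read a term-parent ontology edge table
#'
#' Rows are (child_term, parent_term) edges of a directed acyclic graph;
#' a cycle is a hard error reporting one offending cycle.
#'
#' @inheritParams read_expression_matrix
#' @return data frame with columns \code{child}, \code{parent}.
#' @export
read_term_parents <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("ontology table needs columns child_term, parent_term")
  dag <- data.frame(child = df[[1L]], parent = df[[2L]],
                    stringsAsFactors = FALSE)
  validate_term_dag(dag)
  dag
}

validate_term_dag <- function(dag) {
  g <- igraph::graph_from_data_frame(dag, directed = TRUE)
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle(dag)
    stop("term-parent table contains a cycle: ",
         paste(cyc, collapse = " -> "))
  }
  invisible(dag)
}

# one directed cycle child -> parent -> ... -> child, for the error message
find_cycle <- function(dag) {
  succ <- split(dag$parent, dag$child)
  state <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, state, ifnotfound = 0L)[[1L]]
    if (st == 1L) { found <<- c(path[match(v, path):length(path)], v); return() }
    if (st == 2L) return()
    assign(v, 1L, state)
    path <<- c(path, v)
    for (w in succ[[v]]) visit(w)
    path <<- path[-length(path)]
    assign(v, 2L, state)
  }
  for (v in unique(dag$child)) { visit(v); if (!is.null(found)) break }
  found
}
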