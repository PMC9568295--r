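#' Build an undirected simple graph from explicit nodes and edges
#'
#' The basic container for degree-based descriptor computation: an undirected
#' simple graph with opaque character node labels. Self-loops, duplicate
#' (unordered) edges and edges touching undeclared nodes are rejected rather
#' than silently repaired; isolated nodes are permitted.
#'
#' @param nodes Character vector of distinct node labels (at least one).
#' @param edges Edge set: a two-column matrix or data frame of node labels,
#'   one edge per row, or `NULL` for an edgeless graph.
#' @return An object of class `topograph`: a list with elements `nodes`
#'   (character vector) and `from`/`to` (integer indices into `nodes`, stored
#'   with `from <= to`).
#' @examples
#' g <- graph_from_edges(c("a", "b", "c"),
#'                       rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' degree_map(g)
#' @seealso [degree_map()], [edge_partition()], [read_edge_list()]
#' @export
graph_from_edges <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a graph needs at least one node")
  if (anyNA(nodes) || !all(nzchar(nodes))) stop("node labels must be non-empty")
  if (anyDuplicated(nodes)) stop("duplicate node labels: ",
                                 paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (is.null(edges) || NROW(edges) == 0L) {
    return(structure(list(nodes = nodes, from = integer(0), to = integer(0)),
                     class = "topograph"))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  from <- match(edges[, 1L], nodes)
  to <- match(edges[, 2L], nodes)
  if (anyNA(from) || anyNA(to)) {
    bad <- unique(c(edges[, 1L][is.na(from)], edges[, 2L][is.na(to)]))
    stop("edge endpoint not among declared nodes: ", paste(bad, collapse = ", "))
  }
  if (any(from == to)) {
    stop("self-loops are not allowed (node ",
         paste(unique(nodes[from[from == to]]), collapse = ", "), ")")
  }
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    ij <- as.integer(strsplit(dup, " ", fixed = TRUE)[[1L]])
    stop("duplicate edge: ", nodes[ij[1L]], " -- ", nodes[ij[2L]])
  }
  structure(list(nodes = nodes, from = lo, to = hi), class = "topograph")
}

#' @export
print.topograph <- function(x, ...) {
  cat(sprintf("topograph: %d nodes, %d edges\n",
              length(x$nodes), length(x$from)))
  invisible(x)
}

#' Number of nodes / edges of a graph
#' @param graph A `topograph` object.
#' @return An integer count.
#' @export
n_nodes <- function(graph) {
  stopifnot(inherits(graph, "topograph"))
  length(graph$nodes)
}

#' @rdname n_nodes
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "topograph"))
  length(graph$from)
}

#' Node degrees of a graph
#'
#' The degree of a node is the number of edges incident on it. The degrees
#' always satisfy the handshake identity: their sum equals twice the number
#' of edges.
#'
#' @param graph A `topograph` object.
#' @return A named integer vector of degrees in node order.
#' @export
degree_map <- function(graph) {
  stopifnot(inherits(graph, "topograph"))
  d <- tabulate(c(graph$from, graph$to), nbins = length(graph$nodes))
  names(d) <- graph$nodes
  d
}

#' Partition the edges of a graph by endpoint degrees
#'
#' Classifies every edge by the unordered pair of its endpoint degrees --
#' the central computational device of the edge-partition method: a
#' degree-based index is then a class-count-weighted sum (or product) of a
#' per-class term instead of a sum over individual edges.
#'
#' @param graph A `topograph` object.
#' @return An `edge_partition`: a data frame with integer columns `d1`, `d2`
#'   (`d1 <= d2`) and `count`, ordered by `(d1, d2)`, whose counts sum to the
#'   number of edges.
#' @examples
#' tri <- graph_from_edges(c("a", "b", "c"),
#'                         rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' edge_partition(tri)  # one class: (2, 2) x 3
#' @export
edge_partition <- function(graph) {
  stopifnot(inherits(graph, "topograph"))
  deg <- unname(degree_map(graph))
  a <- deg[graph$from]
  b <- deg[graph$to]
  edge_partition_table(a, b)
}

#' Assemble an edge partition from degree pairs and counts
#'
#' Canonicalizes degree pairs to `(min, max)` and merges coincident classes
#' by summing their counts. Merging is harmless because every catalog index
#' term is symmetric in the two endpoint degrees.
#'
#' @param d1,d2 Positive integer vectors of endpoint degrees, one entry per
#'   class (order within a pair irrelevant).
#' @param count Positive integer vector of edge counts per class (recycled
#'   scalar 1 by default, i.e. one edge per listed pair).
#' @return An `edge_partition` data frame (see [edge_partition()]).
#' @export
edge_partition_table <- function(d1, d2, count = 1) {
  stopifnot(length(d1) == length(d2))
  if (length(d1) == 0L) {
    out <- data.frame(d1 = integer(0), d2 = integer(0), count = numeric(0))
    class(out) <- c("edge_partition", "data.frame")
    return(out)
  }
  count <- rep_len(count, length(d1))
  stopifnot(all(d1 >= 1), all(d2 >= 1), all(count >= 1),
            all(d1 == floor(d1)), all(d2 == floor(d2)),
            all(count == floor(count)))
  lo <- pmin(d1, d2)
  hi <- pmax(d1, d2)
  key <- paste(lo, hi)
  cnt <- rowsum(as.numeric(count), group = key)
  pair <- do.call(rbind, strsplit(rownames(cnt), " ", fixed = TRUE))
  out <- data.frame(d1 = as.integer(pair[, 1L]), d2 = as.integer(pair[, 2L]),
                    count = as.numeric(cnt[, 1L]))
  out <- out[order(out$d1, out$d2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_partition", "data.frame")
  out
}

#' @export
print.edge_partition <- function(x, ...) {
  cat(sprintf("edge partition: %d class(es), %d edge(s)\n",
              nrow(x), sum(x$count)))
  print.data.frame(x, ...)
  invisible(x)
}
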