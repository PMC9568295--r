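#' Specify a layered fully connected network architecture
#'
#' The graph family DNN(M; N1..Nr; N): an input layer of `M` nodes, `r >= 1`
#' hidden layers of widths `N1..Nr`, and an output layer of `N` nodes, with
#' complete bipartite wiring between consecutive layers and no other edges.
#'
#' @param input_width Positive integer `M`.
#' @param hidden_widths Positive integer vector `N1..Nr`, `r >= 1`.
#' @param output_width Positive integer `N`.
#' @return A `dnn_spec`: list with `M`, `hidden`, `N`, `r`.
#' @examples
#' dnn_spec(4, c(4, 5, 6, 4, 3), 3)  # 29 nodes, 111 edges
#' @seealso [parse_architecture()], [build_dnn_graph()],
#'   [closed_form_partition()]
#' @export
dnn_spec <- function(input_width, hidden_widths, output_width) {
  ok <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 1) &&
    all(x == floor(x))
  if (!ok(input_width) || length(input_width) != 1L)
    stop("input_width must be a single positive integer")
  if (!ok(output_width) || length(output_width) != 1L)
    stop("output_width must be a single positive integer")
  if (!ok(hidden_widths) || length(hidden_widths) < 1L)
    stop("hidden_widths must be a non-empty vector of positive integers")
  structure(list(M = as.integer(input_width),
                 hidden = as.integer(hidden_widths),
                 N = as.integer(output_width),
                 r = length(hidden_widths)),
            class = "dnn_spec")
}

#' @export
print.dnn_spec <- function(x, ...) {
  cat(sprintf("DNN(%d; %s; %d): %d hidden layer(s), %d nodes, %d edges\n",
              x$M, paste(x$hidden, collapse = ","), x$N, x$r,
              dnn_node_count(x), dnn_edge_count(x)))
  invisible(x)
}

#' Node and edge counts of a DNN architecture
#'
#' `|V| = M + sum(N_i) + N`; `|E| = M N_1 + sum_{i<r} N_i N_{i+1} + N_r N`.
#'
#' @param spec A `dnn_spec`.
#' @return An integer count.
#' @export
dnn_node_count <- function(spec) {
  stopifnot(inherits(spec, "dnn_spec"))
  spec$M + sum(spec$hidden) + spec$N
}

#' @rdname dnn_node_count
#' @export
dnn_edge_count <- function(spec) {
  stopifnot(inherits(spec, "dnn_spec"))
  w <- c(spec$M, spec$hidden, spec$N)
  sum(w[-length(w)] * w[-1L])
}

#' Parse a comma-separated architecture string
#'
#' `"4,4,5,6,4,3,3"` is read as input width 4, hidden widths 4,5,6,4,3 and
#' output width 3: the first and last entries are the input and output
#' layers, so at least three entries are required.
#'
#' @param text A string of at least three comma-separated positive integers.
#' @return A `dnn_spec`.
#' @export
parse_architecture <- function(text) {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1L]]
  w <- suppressWarnings(as.integer(trimws(parts)))
  if (anyNA(w) || length(w) < 3L || any(w < 1L)) {
    stop("architecture must be >= 3 comma-separated positive integers ",
         "(input, hidden..., output), got '", text, "'")
  }
  dnn_spec(w[1L], w[2:(length(w) - 1L)], w[length(w)])
}

#' Degree of every node in a given layer
#'
#' Layers are numbered 0 (input) to `r + 1` (output). All nodes of a layer
#' share one degree: a node is adjacent to every node of the previous and of
#' the next layer, so with the boundary convention `N0 = M`, `N_{r+1} = N`
#' (and width 0 beyond the input/output layers) the degree of layer `i` is
#' `N_{i-1} + N_{i+1}`. In particular the input layer has degree `N1` and the
#' output layer degree `Nr`.
#'
#' @param spec A `dnn_spec`.
#' @param layer Integer layer index (vectorized), between 0 and `r + 1`.
#' @return Integer degree(s).
#' @examples
#' s <- dnn_spec(4, c(4, 5, 6, 4, 3), 3)
#' layer_degree(s, 0)   # 4  (input degree N1)
#' layer_degree(s, 1)   # 9  (M + N2)
#' layer_degree(s, 6)   # 3  (output degree Nr)
#' @export
layer_degree <- function(spec, layer) {
  stopifnot(inherits(spec, "dnn_spec"))
  if (any(layer < 0) || any(layer > spec$r + 1L) || any(layer != floor(layer))) {
    stop("layer index must lie between 0 (input) and r + 1 = ",
         spec$r + 1L, " (output)")
  }
  wpad <- c(0L, spec$M, spec$hidden, spec$N, 0L)  # wpad[l + 2] = width of layer l
  wpad[layer + 1L] + wpad[layer + 3L]
}

#' Construct the DNN graph explicitly
#'
#' Materializes the layered graph node by node and edge by edge: every node
#' of each layer is joined to every node of the next layer. Node labels are
#' `"L<layer>:<k>"` with `k` 0-based within the layer, so fixtures are
#' deterministic and self-describing.
#'
#' @param spec A `dnn_spec`.
#' @return A `topograph` with `dnn_node_count(spec)` nodes and
#'   `dnn_edge_count(spec)` edges.
#' @examples
#' build_dnn_graph(dnn_spec(1, 1, 1))  # a 3-node path
#' @export
build_dnn_graph <- function(spec) {
  stopifnot(inherits(spec, "dnn_spec"))
  w <- c(spec$M, spec$hidden, spec$N)
  layers <- lapply(seq_along(w), function(j) {
    paste0("L", j - 1L, ":", seq_len(w[j]) - 1L)
  })
  edges <- do.call(rbind, lapply(seq_len(length(w) - 1L), function(j) {
    as.matrix(expand.grid(layers[[j]], layers[[j + 1L]],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  }))
  graph_from_edges(unlist(layers), edges)
}

#' Closed-form edge partition of a DNN architecture
#'
#' Derives the degree-class partition directly from the widths, without
#' building the graph: the edges between layers `i` and `i + 1` form one
#' class with degree pair `(layer_degree(i), layer_degree(i+1))` and count
#' `width_i * width_{i+1}`. Coincident degree pairs from different layer
#' gaps are merged. The result equals `edge_partition(build_dnn_graph(spec))`
#' exactly.
#'
#' @param spec A `dnn_spec`.
#' @return An `edge_partition`.
#' @examples
#' closed_form_partition(dnn_spec(2, 3, 2))  # single class (3,4) x 12
#' @export
closed_form_partition <- function(spec) {
  stopifnot(inherits(spec, "dnn_spec"))
  w <- c(spec$M, spec$hidden, spec$N)
  deg <- layer_degree(spec, 0:(spec$r + 1L))
  L <- length(w)
  edge_partition_table(deg[-L], deg[-1L], w[-L] * w[-1L])
}

#' Closed-form index value of a DNN architecture
#'
#' Evaluates a catalog index over the closed-form partition of the
#' architecture -- the width-arithmetic route, never touching an explicit
#' graph. Agrees with `evaluate_on_graph(build_dnn_graph(spec), name)`
#' exactly for integer-valued indices and to floating precision otherwise.
#'
#' @param spec A `dnn_spec`.
#' @inheritParams evaluate_on_graph
#' @return An `index_value`.
#' @examples
#' closed_form_index(dnn_spec(1, 1, 1), "zagreb1")  # 6
#' @export
closed_form_index <- function(spec, name, alpha = NULL) {
  evaluate_on_partition(closed_form_partition(spec), name, alpha)
}

#' Index growth under increasing depth
#'
#' Evaluates indices over the uniform-width family DNN(k; k,...,k; k) at
#' depths `1..max_depth`. For every sum-aggregated index with strictly
#' positive terms the values increase strictly with depth: appending a
#' width-`k` hidden layer adds `k^2` edges of degree class `(2k, 2k)` while
#' leaving all previously counted classes in place.
#'
#' @param width Positive integer `k`, the common layer width.
#' @param max_depth Maximum number of hidden layers.
#' @param indices Character vector of index names, or `"all"`.
#' @param alpha Exponent used for `general_randic`.
#' @return A data frame with columns `depth`, `index`, `alpha`, `value`,
#'   `log10` (log10 set for product indices).
#' @examples
#' growth_profile(2, 4, indices = "zagreb1")
#' @export
growth_profile <- function(width, max_depth, indices = "all", alpha = 0.5) {
  stopifnot(width >= 1, max_depth >= 1)
  if (identical(indices, "all")) indices <- .INDEX_NAMES
  rows <- lapply(seq_len(max_depth), function(r) {
    spec <- dnn_spec(width, rep(width, r), width)
    part <- closed_form_partition(spec)
    do.call(rbind, lapply(indices, function(nm) {
      iv <- evaluate_on_partition(part, nm, alpha)
      data.frame(depth = r, index = nm,
                 alpha = if (nm == "general_randic") alpha else NA_real_,
                 value = iv$value, log10 = iv$log10,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
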