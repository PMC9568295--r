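#' Read an undirected graph from a tab-separated edge list
#'
#' Dialect: one edge per line, two tab-separated node labels; blank lines
#' and lines starting with `#` are ignored. The graph must be simple --
#' self-loops and duplicate (unordered) edges are reported as errors with
#' their line number. Nodes are ordered by first appearance.
#'
#' @param path Path to the edge-list file.
#' @return A `topograph`.
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  stripped <- trimws(lines, which = "right")
  keep <- which(nzchar(trimws(stripped)) & !startsWith(trimws(stripped), "#"))
  if (length(keep) == 0L) stop("no edges found in '", path, "'")
  u <- character(length(keep))
  v <- character(length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- strsplit(stripped[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 2L || !all(nzchar(fields))) {
      stop("line ", ln, ": expected exactly two tab-separated node labels")
    }
    if (fields[1L] == fields[2L]) {
      stop("line ", ln, ": self-loop on node '", fields[1L], "'")
    }
    u[k] <- fields[1L]
    v[k] <- fields[2L]
  }
  key <- paste(pmin(u, v), pmax(u, v), sep = "\r")
  if (anyDuplicated(key)) {
    ln <- keep[which(duplicated(key))[1L]]
    stop("line ", ln, ": duplicate edge '", u[duplicated(key)][1L], " -- ",
         v[duplicated(key)][1L], "'")
  }
  nodes <- unique(as.vector(rbind(u, v)))
  graph_from_edges(nodes, cbind(u, v))
}

#' Write a graph as a tab-separated edge list
#'
#' @param graph A `topograph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "topograph"))
  writeLines(paste(graph$nodes[graph$from], graph$nodes[graph$to], sep = "\t"),
             path)
  invisible(path)
}

#' Evaluate a set of indices as a report table
#'
#' Dispatches on the input: a `dnn_spec` is evaluated through its
#' closed-form partition, a `topograph` through direct edge summation, and
#' an `edge_partition` through the partition evaluator.
#'
#' @param x A `dnn_spec`, `topograph` or `edge_partition`.
#' @param indices Character vector of index names, or `"all"`.
#' @param alpha Exponent used for `general_randic`.
#' @return A data frame with columns `index`, `alpha`, `value`, `exact`
#'   (decimal string or `NA`) and `log10`.
#' @examples
#' index_report(dnn_spec(1, 1, 1), indices = c("zagreb1", "randic"))
#' @export
index_report <- function(x, indices = "all", alpha = 0.5) {
  if (identical(indices, "all")) indices <- .INDEX_NAMES
  bad <- setdiff(indices, .INDEX_NAMES)
  if (length(bad)) {
    stop("unknown index name(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(.INDEX_NAMES, collapse = ", "))
  }
  eval1 <- if (inherits(x, "dnn_spec")) {
    part <- closed_form_partition(x)
    function(nm, a) evaluate_on_partition(part, nm, a)
  } else if (inherits(x, "topograph")) {
    function(nm, a) evaluate_on_graph(x, nm, a)
  } else if (inherits(x, "edge_partition")) {
    function(nm, a) evaluate_on_partition(x, nm, a)
  } else {
    stop("x must be a dnn_spec, topograph or edge_partition")
  }
  rows <- lapply(indices, function(nm) {
    iv <- eval1(nm, if (nm == "general_randic") alpha else NULL)
    data.frame(index = nm,
               alpha = if (nm == "general_randic") alpha else NA_real_,
               value = iv$value, exact = iv$exact, log10 = iv$log10,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a report (or any data frame) to TSV or JSON
#'
#' Column order is preserved; exact integers travel as strings in JSON so
#' that consumers do not silently round them through doubles. `format_report`
#' returns the serialized lines; `write_report` writes them to a file.
#'
#' @param report A data frame, typically from [index_report()],
#'   [growth_profile()] or [verify_closed_forms()].
#' @param format `"tsv"` or `"json"`.
#' @param path Output path.
#' @return `format_report`: a character vector of lines. `write_report`:
#'   `path`, invisibly.
#' @export
format_report <- function(report, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(report, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    close(con)
    return(out)
  }
  as.character(jsonlite::toJSON(report, dataframe = "rows", na = "null",
                                digits = NA, pretty = TRUE))
}

#' @rdname format_report
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  writeLines(format_report(report, format), path)
  invisible(path)
}
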