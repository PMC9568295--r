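# Seeded generators and the closed-form-vs-oracle verification sweep.

# Run `expr` under a private RNG stream, leaving the caller's stream intact.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate reproducible random DNN architectures
#'
#' Depth is uniform on `1..max_depth` and every width uniform on
#' `1..max_width`, the regime used throughout the verification sweep:
#' small widths deliberately exercise the degenerate shapes (width-1
#' layers, coinciding degree classes) where closed forms are most likely
#' to break.
#'
#' @param n Number of architectures.
#' @param seed Integer RNG seed; the same seed yields the same sequence.
#' @param max_depth Maximum number of hidden layers.
#' @param max_width Maximum layer width.
#' @return A list of `dnn_spec` objects.
#' @export
random_dnn_specs <- function(n, seed = 20221007, max_depth = 8, max_width = 12) {
  stopifnot(n >= 1, max_depth >= 1, max_width >= 1)
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      r <- sample.int(max_depth, 1L)
      dnn_spec(sample.int(max_width, 1L),
               sample.int(max_width, r, replace = TRUE),
               sample.int(max_width, 1L))
    })
  })
}

#' Generate a random Erdos-Renyi-style graph
#'
#' Each of the `choose(n, 2)` possible edges is included independently with
#' probability `p`; if none survives, one uniformly chosen edge is added so
#' the graph always has at least one edge. Uses the current RNG stream
#' (wrap in `set.seed()` for reproducibility).
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param p Edge probability.
#' @return A `topograph` with nodes `v1..vn`.
#' @export
random_graph <- function(n_nodes, p = 0.3) {
  stopifnot(n_nodes >= 2, p >= 0, p <= 1)
  nodes <- paste0("v", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  graph_from_edges(nodes, cbind(nodes[pairs[keep, 1L]], nodes[pairs[keep, 2L]]))
}

# Compare a closed-form index_value against the graph oracle. Integer-valued
# indices must agree exactly (decimal strings); product indices additionally
# in log space; everything else to a relative tolerance.
.compare_index_values <- function(cf, or, name, alpha) {
  exact_ok <- TRUE
  if (.index_is_integer(name, alpha) &&
      !is.na(cf$exact) && !is.na(or$exact)) {
    exact_ok <- identical(cf$exact, or$exact)
  }
  ref <- if (name %in% .PRODUCT_INDICES) or$log10 else or$value
  got <- if (name %in% .PRODUCT_INDICES) cf$log10 else cf$value
  rel <- if (ref == got) 0 else abs(got - ref) / max(abs(ref), 1)
  list(exact_ok = exact_ok, rel_err = rel)
}

#' Verify the closed forms against the brute-force oracle
#'
#' For each random architecture, computes all twelve indices twice -- once
#' from the closed-form width-arithmetic partition and once by direct
#' summation over the explicitly built graph -- and records the
#' discrepancies. Integer-valued indices (the Zagreb family, forgotten,
#' hyper-Zagreb, the multiplicative pair) are compared as exact integers;
#' real-valued indices by relative error; products also on the log10 scale.
#'
#' @inheritParams random_dnn_specs
#' @param alpha Exponent used for `general_randic` in the sweep.
#' @param tol Relative tolerance beyond which a value pair counts as a
#'   mismatch.
#' @return A data frame with one row per index: `index`, `max_rel_err`,
#'   `exact_mismatches`, `n_specs`, `ok`. Attribute `"pass"` is `TRUE` when
#'   every index passed.
#' @examples
#' verify_closed_forms(trials = 5, seed = 1)
#' @export
verify_closed_forms <- function(trials = 200, seed = 20221007, max_depth = 8,
                                max_width = 12, alpha = 0.5, tol = 1e-9) {
  specs <- random_dnn_specs(trials, seed = seed, max_depth = max_depth,
                            max_width = max_width)
  max_rel <- stats::setNames(numeric(length(.INDEX_NAMES)), .INDEX_NAMES)
  exact_bad <- stats::setNames(integer(length(.INDEX_NAMES)), .INDEX_NAMES)
  for (spec in specs) {
    g <- build_dnn_graph(spec)
    part <- closed_form_partition(spec)
    for (nm in .INDEX_NAMES) {
      a <- if (nm == "general_randic") alpha else NULL
      cmp <- .compare_index_values(evaluate_on_partition(part, nm, a),
                                   evaluate_on_graph(g, nm, a), nm, a)
      max_rel[nm] <- max(max_rel[nm], cmp$rel_err)
      if (!cmp$exact_ok) exact_bad[nm] <- exact_bad[nm] + 1L
    }
  }
  out <- data.frame(index = .INDEX_NAMES,
                    max_rel_err = unname(max_rel),
                    exact_mismatches = unname(exact_bad),
                    n_specs = length(specs),
                    ok = unname(max_rel <= tol & exact_bad == 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$ok)
  out
}
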