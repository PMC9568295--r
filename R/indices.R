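#' @keywords internal
"_PACKAGE"

.INDEX_NAMES <- c("randic", "general_randic", "zagreb1", "zagreb2",
                  "mult_zagreb1", "mult_zagreb2", "hyper_zagreb",
                  "abc", "sci", "ga", "forgotten", "azi")

.PRODUCT_INDICES <- c("mult_zagreb1", "mult_zagreb2")

# Per-edge term f(d_u, d_v) for each catalog entry; all symmetric in (a, b).
.index_term_fun <- function(name) {
  switch(name,
    randic         = function(a, b, alpha) 1 / sqrt(a * b),
    general_randic = function(a, b, alpha) (a * b)^alpha,
    zagreb1        = function(a, b, alpha) a + b,
    zagreb2        = function(a, b, alpha) a * b,
    mult_zagreb1   = function(a, b, alpha) a + b,
    mult_zagreb2   = function(a, b, alpha) a * b,
    hyper_zagreb   = function(a, b, alpha) (a + b)^2,
    abc            = function(a, b, alpha) sqrt((a + b - 2) / (a * b)),
    sci            = function(a, b, alpha) 1 / sqrt(a + b),
    ga             = function(a, b, alpha) 2 * sqrt(a * b) / (a + b),
    forgotten      = function(a, b, alpha) a^2 + b^2,
    azi            = function(a, b, alpha) (a * b / (a + b - 2))^3,
    stop("unknown index '", name, "'; known indices: ",
         paste(.INDEX_NAMES, collapse = ", "))
  )
}

# Does the index take exact integer values (so an exact field is reported)?
.index_is_integer <- function(name, alpha) {
  if (name %in% c("zagreb1", "zagreb2", "hyper_zagreb", "forgotten")) return(TRUE)
  if (name %in% .PRODUCT_INDICES) return(TRUE)
  if (name == "general_randic") {
    return(!is.null(alpha) && alpha >= 0 && alpha == floor(alpha))
  }
  FALSE
}

#' The catalog of degree-based topological indices
#'
#' Twelve classical degree-based descriptors, each a sum or product over the
#' edges of a symmetric function of the endpoint degrees \eqn{(d_u, d_v)}:
#'
#' * `randic` -- Randic connectivity index \eqn{\chi = \sum (d_u d_v)^{-1/2}}
#' * `general_randic` -- \eqn{R_\alpha = \sum (d_u d_v)^\alpha} (needs `alpha`)
#' * `zagreb1` -- first Zagreb \eqn{M_1 = \sum (d_u + d_v)}
#' * `zagreb2` -- second Zagreb \eqn{M_2 = \sum d_u d_v}
#' * `mult_zagreb1` -- first multiplicative Zagreb \eqn{PM_1 = \prod (d_u + d_v)}
#' * `mult_zagreb2` -- second multiplicative Zagreb \eqn{PM_2 = \prod d_u d_v}
#' * `hyper_zagreb` -- \eqn{HM = \sum (d_u + d_v)^2}
#' * `abc` -- atom-bond connectivity \eqn{\sum \sqrt{(d_u + d_v - 2)/(d_u d_v)}}
#' * `sci` -- sum-connectivity \eqn{\sum (d_u + d_v)^{-1/2}}
#' * `ga` -- geometric-arithmetic \eqn{\sum 2\sqrt{d_u d_v}/(d_u + d_v)}
#' * `forgotten` -- forgotten index \eqn{F = \sum (d_u^2 + d_v^2)}
#' * `azi` -- augmented Zagreb \eqn{\sum (d_u d_v/(d_u + d_v - 2))^3}
#'
#' @return A data frame with one row per index: `name`, `aggregation`
#'   (`"sum"` or `"product"`), `needs_alpha`, and a human-readable `term`.
#' @examples
#' index_catalog()
#' @export
index_catalog <- function() {
  data.frame(
    name = .INDEX_NAMES,
    aggregation = ifelse(.INDEX_NAMES %in% .PRODUCT_INDICES, "product", "sum"),
    needs_alpha = .INDEX_NAMES == "general_randic",
    term = c("(du*dv)^(-1/2)", "(du*dv)^alpha", "du+dv", "du*dv",
             "du+dv", "du*dv", "(du+dv)^2", "sqrt((du+dv-2)/(du*dv))",
             "(du+dv)^(-1/2)", "2*sqrt(du*dv)/(du+dv)", "du^2+dv^2",
             "(du*dv/(du+dv-2))^3"),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the per-edge term of an index
#'
#' @param name An index name from [index_catalog()].
#' @param du,dv Positive integer endpoint degrees (vectorized).
#' @param alpha Exponent for `general_randic`; ignored otherwise.
#' @return Numeric vector of term values.
#' @examples
#' edge_term("ga", 3, 3)      # 1: geometric and arithmetic mean coincide
#' edge_term("abc", 1, 1)     # 0: zero numerator under the root
#' edge_term("azi", 2, 3)     # (6/3)^3 = 8
#' @export
edge_term <- function(name, du, dv, alpha = NULL) {
  name <- match.arg(name, .INDEX_NAMES)
  stopifnot(length(du) == length(dv),
            all(du >= 1), all(dv >= 1),
            all(du == floor(du)), all(dv == floor(dv)))
  if (name == "general_randic" && is.null(alpha)) {
    stop("general_randic requires an explicit alpha")
  }
  if (name == "azi" && any(du + dv == 2)) {
    stop("augmented Zagreb index is undefined on an edge with d_u = d_v = 1 ",
         "(zero denominator)")
  }
  .index_term_fun(name)(as.numeric(du), as.numeric(dv), alpha)
}

# Shared evaluator over (a, b, count) class triples. `count` is all-ones for
# the per-edge (graph oracle) route.
.evaluate_classes <- function(name, a, b, count, alpha) {
  if (length(a) == 0L) {
    warning("graph has no edges; returning the aggregation identity (",
            if (name %in% .PRODUCT_INDICES) "1" else "0", ")")
    if (name %in% .PRODUCT_INDICES) {
      return(new_index_value(name, alpha, value = 1, exact = "1", log10 = 0))
    }
    return(new_index_value(name, alpha, value = 0,
                           exact = if (.index_is_integer(name, alpha)) "0" else NA_character_))
  }
  terms <- edge_term(name, a, b, alpha)
  if (name %in% .PRODUCT_INDICES) {
    # terms are positive integers (degree sums or products); collapse repeats
    # so the exact big-integer product costs one power per distinct term
    u <- sort(unique(terms))
    cnt <- vapply(u, function(t) sum(count[terms == t]), numeric(1))
    exact <- Reduce(big_mul,
                    Map(function(t, k) big_pow(big_from_num(t), k), u, cnt),
                    big_from_num(1))
    lg <- sum(cnt * log10(u))
    s <- big_to_string(exact)
    value <- if (nchar(s) <= 15L) as.numeric(s) else if (lg < 308) 10^lg else Inf
    return(new_index_value(name, alpha, value = value, exact = s, log10 = lg))
  }
  value <- sum(count * terms)
  exact <- NA_character_
  if (.index_is_integer(name, alpha) && abs(value) < 2^53) {
    exact <- sprintf("%.0f", value)
  }
  new_index_value(name, alpha, value = value, exact = exact)
}

new_index_value <- function(name, alpha, value, exact = NA_character_,
                            log10 = NA_real_) {
  structure(list(name = name,
                 alpha = if (name == "general_randic") alpha else NULL,
                 value = value, exact = exact, log10 = log10),
            class = "index_value")
}

#' @export
print.index_value <- function(x, ...) {
  lab <- x$name
  if (!is.null(x$alpha)) lab <- sprintf("%s(alpha=%g)", lab, x$alpha)
  cat(sprintf("%s = %.10g", lab, x$value))
  if (!is.na(x$exact) && nchar(x$exact) > 15L) {
    cat(sprintf("  [exact: %d digits, log10 = %.6f]", nchar(x$exact), x$log10))
  } else if (!is.na(x$exact)) {
    cat(sprintf("  [exact: %s]", x$exact))
  }
  cat("\n")
  invisible(x)
}

#' Evaluate an index directly on a graph (brute-force oracle)
#'
#' Sums (or multiplies) the per-edge term over every edge of the graph,
#' iterating the edge set exactly once. This is the reference path against
#' which partition-based and closed-form evaluation are verified.
#'
#' @param graph A `topograph` object.
#' @param name An index name from [index_catalog()].
#' @param alpha Exponent for `general_randic`.
#' @return An `index_value`: list with `name`, `alpha` (general Randic only),
#'   `value` (double), `exact` (decimal string when the index is
#'   integer-valued, else `NA`), and `log10` (set for product indices).
#' @examples
#' tri <- graph_from_edges(c("a", "b", "c"),
#'                         rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' evaluate_on_graph(tri, "zagreb1")  # 3 edges x (2+2) = 12
#' @export
evaluate_on_graph <- function(graph, name, alpha = NULL) {
  stopifnot(inherits(graph, "topograph"))
  deg <- unname(degree_map(graph))
  a <- deg[graph$from]
  b <- deg[graph$to]
  .evaluate_classes(name, a, b, rep(1, length(a)), alpha)
}

#' Evaluate an index from an edge partition
#'
#' The edge-partition method: each degree class `(d1, d2)` contributes
#' `count * term` to a sum index and `term ^ count` to a product index.
#' For a partition obtained from a graph this agrees with
#' [evaluate_on_graph()] exactly (integer indices) or to floating precision.
#'
#' @param partition An `edge_partition` (from [edge_partition()],
#'   [edge_partition_table()] or [closed_form_partition()]).
#' @inheritParams evaluate_on_graph
#' @return An `index_value`; see [evaluate_on_graph()].
#' @examples
#' p <- edge_partition_table(3, 4, 12)
#' evaluate_on_partition(p, "zagreb1")  # 12 * 7 = 84
#' @export
evaluate_on_partition <- function(partition, name, alpha = NULL) {
  stopifnot(inherits(partition, "edge_partition"))
  .evaluate_classes(name, partition$d1, partition$d2, partition$count, alpha)
}

#' Log-space evaluation of a product index
#'
#' Returns \eqn{\sum_{classes} count \cdot \log_{10}(term)}, the base-10
#' logarithm of the multiplicative index value. Useful when the exact
#' product is astronomically large.
#'
#' @param partition An `edge_partition`.
#' @param name A product-aggregated index (`mult_zagreb1` or `mult_zagreb2`).
#' @return A double: the log10 of the index value.
#' @export
log_space_product <- function(partition, name) {
  stopifnot(inherits(partition, "edge_partition"))
  name <- match.arg(name, .PRODUCT_INDICES)
  if (nrow(partition) == 0L) return(0)
  terms <- edge_term(name, partition$d1, partition$d2)
  if (any(terms <= 0)) stop("log-space product requires strictly positive terms")
  sum(partition$count * log10(terms))
}
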