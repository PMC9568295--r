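# Small fixtures and comparison helpers shared across the suite.

triangle_graph <- function() {
  graph_from_edges(c("a", "b", "c"),
                   rbind(c("a", "b"), c("b", "c"), c("a", "c")))
}

path3_graph <- function() {
  # same shape as DNN(1;[1];1): degrees 1, 2, 1
  graph_from_edges(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
}

fig_spec <- function() dnn_spec(4, c(4, 5, 6, 4, 3), 3)

partition_as_map <- function(p) {
  stats::setNames(p$count, paste0("(", p$d1, ",", p$d2, ")"))
}

rel_err <- function(got, ref) {
  if (identical(got, ref)) return(0)
  abs(got - ref) / max(abs(ref), 1)
}

# Sum-type catalog indices whose terms are strictly positive on every graph
# with all degrees >= 1 and no (1,1) edge.
positive_sum_indices <- function() {
  c("randic", "zagreb1", "zagreb2", "hyper_zagreb", "sci", "ga", "forgotten")
}
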