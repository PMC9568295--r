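test_that("the catalog lists the twelve descriptors with their aggregation", {
  cat12 <- index_catalog()
  expect_equal(nrow(cat12), 12L)
  expect_setequal(cat12$name[cat12$aggregation == "product"],
                  c("mult_zagreb1", "mult_zagreb2"))
  expect_equal(cat12$name[cat12$needs_alpha], "general_randic")
})

test_that("edge terms reproduce hand-computed values and guard their domains", {
  expect_equal(edge_term("ga", 3, 3), 1)
  expect_equal(edge_term("ga", 7, 7), 1)
  expect_equal(edge_term("abc", 1, 1), 0)
  expect_equal(edge_term("azi", 2, 3), 8)       # (6/3)^3
  expect_equal(edge_term("randic", 2, 2), 0.5)
  expect_equal(edge_term("general_randic", 2, 3, alpha = 2), 36)
  expect_error(edge_term("azi", 1, 1), "undefined")
  expect_error(edge_term("general_randic", 2, 3), "alpha")
  expect_error(edge_term("nonsense", 2, 3))
  # symmetry in the endpoint degrees
  for (nm in index_catalog()$name) {
    a <- if (nm == "general_randic") 0.7 else NULL
    expect_equal(edge_term(nm, 3, 5, a), edge_term(nm, 5, 3, a))
  }
})

test_that("direct and partition evaluation give the documented small values", {
  expect_equal(evaluate_on_graph(triangle_graph(), "zagreb1")$value, 12)
  expect_equal(evaluate_on_partition(edge_partition_table(3, 4, 12),
                                     "zagreb1")$value, 84)
  expect_equal(evaluate_on_partition(edge_partition_table(1, 2, 2),
                                     "hyper_zagreb")$value, 18)
  pm2 <- evaluate_on_graph(path3_graph(), "mult_zagreb2")
  expect_identical(pm2$exact, "4")
  expect_equal(pm2$value, 4)
  k2 <- graph_from_edges(c("a", "b"), rbind(c("a", "b")))
  expect_equal(evaluate_on_graph(k2, "mult_zagreb2")$log10, 0)
})

test_that("log-space products agree with the exact big-integer value", {
  expect_equal(log_space_product(edge_partition_table(1, 2, 2), "mult_zagreb1"),
               2 * log10(3))
  expect_equal(log_space_product(edge_partition_table(3, 4, 12), "mult_zagreb2"),
               12 * log10(12))
  set.seed(23)
  for (i in 1:10) {
    g <- random_graph(sample(5:25, 1), 0.4)
    p <- edge_partition(g)
    for (nm in c("mult_zagreb1", "mult_zagreb2")) {
      iv <- evaluate_on_partition(p, nm)
      expect_equal(iv$log10, log_space_product(p, nm), tolerance = 1e-12)
      # log10 field consistent with the exact integer's magnitude
      lead <- as.numeric(substr(iv$exact, 1, 15)) /
        10^(min(nchar(iv$exact), 15) - 1)
      expect_equal(iv$log10, nchar(iv$exact) - 1 + log10(lead),
                   tolerance = 1e-12)
    }
  }
})

test_that("partition evaluation matches direct evaluation on random graphs", {
  set.seed(314)
  for (i in 1:40) {
    g <- random_graph(sample(4:30, 1), stats::runif(1, 0.15, 0.9))
    p <- edge_partition(g)
    deg <- degree_map(g)
    has11 <- any(deg[g$from] + deg[g$to] == 2)
    for (nm in index_catalog()$name) {
      if (nm == "azi" && has11) next
      a <- if (nm == "general_randic") stats::runif(1, -2, 2) else NULL
      iv_g <- evaluate_on_graph(g, nm, a)
      iv_p <- evaluate_on_partition(p, nm, a)
      if (nm %in% c("mult_zagreb1", "mult_zagreb2")) {
        expect_identical(iv_p$exact, iv_g$exact)
        expect_lt(rel_err(iv_p$log10, iv_g$log10), 1e-12)
      } else {
        expect_lt(rel_err(iv_p$value, iv_g$value), 1e-12)
      }
    }
  }
})

test_that("integer-valued indices carry an exact decimal field", {
  g <- build_dnn_graph(fig_spec())
  for (nm in c("zagreb1", "zagreb2", "hyper_zagreb", "forgotten")) {
    iv <- evaluate_on_graph(g, nm)
    expect_identical(iv$exact, sprintf("%.0f", iv$value))
  }
  expect_identical(evaluate_on_graph(g, "general_randic", alpha = 2)$exact,
                   sprintf("%.0f", evaluate_on_graph(g, "general_randic",
                                                     alpha = 2)$value))
  expect_true(is.na(evaluate_on_graph(g, "randic")$exact))
})

test_that("an edgeless graph yields the aggregation identity with a warning", {
  g <- graph_from_edges(c("a", "b"))
  expect_warning(s <- evaluate_on_graph(g, "zagreb1"), "no edges")
  expect_equal(s$value, 0)
  expect_warning(p <- evaluate_on_graph(g, "mult_zagreb1"), "no edges")
  expect_equal(p$value, 1)
  expect_identical(p$exact, "1")
})

test_that("algebraic identities hold across random graphs", {
  set.seed(2718)
  for (i in 1:30) {
    g <- random_graph(sample(4:30, 1), stats::runif(1, 0.15, 0.9))
    deg <- as.numeric(degree_map(g))
    hm <- evaluate_on_graph(g, "hyper_zagreb")$value
    f <- evaluate_on_graph(g, "forgotten")$value
    m1 <- evaluate_on_graph(g, "zagreb1")$value
    m2 <- evaluate_on_graph(g, "zagreb2")$value
    expect_identical(hm, f + 2 * m2)
    expect_identical(m1, sum(deg^2))
    expect_equal(evaluate_on_graph(g, "general_randic", alpha = 0)$value,
                 n_edges(g))
    expect_equal(evaluate_on_graph(g, "general_randic", alpha = 1)$value, m2)
    expect_lt(rel_err(evaluate_on_graph(g, "general_randic", alpha = -0.5)$value,
                      evaluate_on_graph(g, "randic")$value), 1e-12)
    # PM2 = prod_v d_v^{d_v}, via an independent big-integer route over nodes
    pm2 <- evaluate_on_graph(g, "mult_zagreb2")
    node_route <- Reduce(topodnn:::big_mul,
                         lapply(deg[deg > 0],
                                function(d) topodnn:::big_pow(
                                  topodnn:::big_from_num(d), d)),
                         topodnn:::big_from_num(1))
    expect_identical(pm2$exact, topodnn:::big_to_string(node_route))
  }
})

test_that("geometric-arithmetic index is bounded by the edge count", {
  set.seed(161)
  for (i in 1:20) {
    g <- random_graph(sample(4:25, 1), stats::runif(1, 0.2, 0.9))
    ga <- evaluate_on_graph(g, "ga")$value
    expect_lte(ga, n_edges(g) + 1e-12)
    deg <- degree_map(g)
    if (all(deg[g$from] == deg[g$to])) {
      expect_equal(ga, n_edges(g))
    } else {
      expect_lt(ga, n_edges(g))
    }
  }
  # equality case: a regular graph
  expect_equal(evaluate_on_graph(triangle_graph(), "ga")$value, 3)
})
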