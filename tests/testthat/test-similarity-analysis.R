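test_that("Pearson correlation matches the direct covariance formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 7), -1)
  y <- c(1, 3, 2, 5)
  expect_equal(pearson_r(x, y), 5.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  expect_error(pearson_r(x, c(2, 2, 2, 2)), "constant")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
})

test_that("Pearson correlation is affine-invariant up to sign", {
  withr::with_seed(31, {
    for (i in 1:20) {
      x <- stats::rnorm(20)
      y <- stats::rnorm(20)
      a <- stats::runif(1, -3, 3)
      if (abs(a) < 0.1) a <- 0.5
      b <- stats::rnorm(1)
      expect_equal(pearson_r(x, a * y + b), sign(a) * pearson_r(x, y),
                   tolerance = 1e-12)
    }
  })
})

make_records <- function(scores_by_strategy) {
  npairs <- length(scores_by_strategy[[1]])
  do.call(rbind, lapply(names(scores_by_strategy), function(s) {
    data.frame(graph = "g", strategy = s,
               u = as.character(seq_len(npairs)),
               v = as.character(seq_len(npairs) + 100),
               label = rep_len(c(1L, 0L), npairs),
               normalized = scores_by_strategy[[s]],
               stringsAsFactors = FALSE)
  }))
}

test_that("strategy-pair correlation matrices are symmetric with unit diagonal", {
  s <- c(0.1, 0.9, 0.4, 0.7, 0.2)
  rec <- make_records(list(A = s, B = 0.5 * s + 0.1, C = rev(s)))
  m <- walk_pair_correlations(rec)
  expect_equal(diag(m), c(A = 1, B = 1, C = 1))
  expect_equal(m, t(m))
  expect_equal(m["A", "B"], 1) # affinely related scores correlate perfectly
  expect_true(all(is.finite(m)))
})

test_that("a broken shared split is a hard error", {
  s <- c(0.1, 0.9, 0.4, 0.7, 0.2)
  rec <- make_records(list(A = s, B = s))
  rec$u[rec$strategy == "B"][1] <- "999"
  expect_error(walk_pair_correlations(rec), "shared split")
})

test_that("median correlation is entrywise and preserves symmetry", {
  base <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  m2 <- base; m2["A", "B"] <- m2["B", "A"] <- 0.5
  m3 <- base; m3["A", "B"] <- m3["B", "A"] <- 0.9
  med <- median_correlation(list(base, m2, m3))
  expect_equal(med["A", "B"], 0.5)
  expect_equal(med, t(med), ignore_attr = TRUE)
  expect_equal(diag(med), c(A = 1, B = 1))
  # single matrix: identity operation
  expect_equal(median_correlation(list(base))[, ], base[, ])
  bad <- base[2:1, 2:1]
  expect_error(median_correlation(list(base, bad)), "ordering")
})

test_that("RW and N2V(1, 1) similarity profiles correlate strongly", {
  g <- generate_graph(graph_spec("stochastic_block", 90,
    list(block_sizes = c(45L, 45L), p_in = 0.3, p_out = 0.02), seed = 12))
  strategies <- stats::setNames(
    list(walk_config("RW", beta = 20, alpha = 60),
         walk_config("N2V", beta = 20, alpha = 60, p = 1, q = 1)),
    c("RW", "N2V(1, 1)"))
  out <- evaluate_strategies(list(sbm = g), strategies,
                             embedding_config(dimension = 32, seed = 3),
                             split_seed = 8)
  m <- walk_pair_correlations(out$records)
  expect_gte(m["RW", "N2V(1, 1)"], 0.9)
  # same walk law, different sampling stream: AUCs close
  expect_lt(abs(diff(out$results$auc_roc)), 0.05)
})

test_that("network metrics match closed forms on fixtures", {
  m <- network_metrics(fixture_graph("triangle"))
  expect_equal(m$mean_clustering, 1)
  expect_equal(m$diameter, 1)
  expect_equal(m$density, 1)
  expect_equal(m$degree_entropy, 0) # regular graph: degenerate distribution

  m4 <- network_metrics(fixture_graph("path4"))
  expect_equal(m4$mean_clustering, 0)
  expect_equal(m4$diameter, 3)
  expect_equal(m4$n_nodes, 4)
  expect_equal(m4$n_edges, 3)
  # degrees 1,2,2,1: entropy of a fair coin
  expect_equal(m4$degree_entropy, 1)

  ms <- network_metrics(fixture_graph("star5"))
  expect_equal(ms$assortativity, -1)
  expect_equal(ms$mean_degree, 8 / 5)

  disco <- igraph::graph_from_edgelist(matrix(c("0","1","2","3"), ncol = 2,
                                              byrow = TRUE), directed = FALSE)
  expect_error(network_metrics(disco), "connected")
})

test_that("metric-performance correlation recovers exact relations and skips constants", {
  results <- data.frame(
    graph = rep(c("a", "b", "c", "d"), each = 2),
    strategy = rep(c("RW", "DG"), 4),
    auc_roc = rep(c(0.6, 0.7, 0.8, 0.9), each = 2))
  metrics <- data.frame(graph = c("a", "b", "c", "d"),
                        perf_copy = c(0.6, 0.7, 0.8, 0.9),
                        flat = c(1, 1, 1, 1),
                        anti = c(4, 3, 2, 1))
  expect_warning(r <- metric_performance_correlation(results, metrics), "flat")
  expect_equal(unname(r["perf_copy"]), 1)
  expect_equal(unname(r["anti"]), -1)
  expect_false("flat" %in% names(r))
})
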