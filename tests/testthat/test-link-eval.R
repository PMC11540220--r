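test_that("cosine similarity behaves on identity, orthogonal and opposite vectors", {
  a <- c(1, 2, 3)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(a, -a), -1)
  expect_error(cosine_similarity(a, c(1, 2)), "dimensions")
  expect_error(cosine_similarity(a, c(0, 0, 0)), "zero vector")
})

test_that("min-max normalization maps to [0, 1] with the degenerate-input rule", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-1, 1)), c(0, 1))
  expect_warning(out <- minmax_normalize(c(3, 3, 3)), "constant")
  expect_equal(out, c(0.5, 0.5, 0.5))
  expect_error(minmax_normalize(5), "at least 2")
})

test_that("AUC-ROC matches hand-checked cases and rejects bad input", {
  expect_equal(auc_roc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_roc(c(1, 0), c(0.3, 0.7)), 0)
  expect_equal(auc_roc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(auc_roc(c(1, 0, 1, 0), c(0.5, 0.5, 0.5, 0.5)), 0.5) # all ties
  expect_error(auc_roc(c(1, 1), c(0.1, 0.2)), "both classes")
  expect_error(auc_roc(c(1, 0), c(0.1, 0.2, 0.3)), "length")
})

test_that("AUC-PR matches hand-checked cases", {
  expect_equal(auc_pr(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_pr(c(1, 0), c(0.3, 0.7)), 0.5)
  expect_equal(auc_pr(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)),
               ap_threshold_oracle(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)))
})

test_that("both AUCs equal their exhaustive oracles on random tie-rich instances", {
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      labels <- c(1, 0, stats::rbinom(n - 2, 1, 0.5))
      # coarse rounding forces plenty of ties
      scores <- round(stats::runif(n), sample(1:2, 1))
      expect_equal(auc_roc(labels, scores), auc_pairwise_oracle(labels, scores),
                   tolerance = 1e-12)
      expect_equal(auc_pr(labels, scores), ap_threshold_oracle(labels, scores),
                   tolerance = 1e-12)
      # rank-preserving normalization leaves AUC unchanged exactly
      expect_identical(auc_roc(labels, scores),
                       auc_roc(labels, suppressWarnings(minmax_normalize(scores))))
      # label antisymmetry
      expect_equal(auc_roc(1 - labels, scores), 1 - auc_roc(labels, scores),
                   tolerance = 1e-12)
    }
  })
})

test_that("pair scoring covers the dataset and normalizes per group", {
  g <- largest_connected_component(generate_graph(
    graph_spec("stochastic_block", 60,
               list(block_sizes = c(30L, 30L), p_in = 0.3, p_out = 0.02),
               seed = 16)))
  sp <- make_split(g, 0.25, seed = 2)
  corpus <- generate_walks(sp$residual, walk_config("RW", beta = 5, alpha = 40, seed = 3))
  emb <- train_embeddings(corpus, embedding_config(dimension = 32, seed = 4))
  sc <- score_pairs(emb, sp$dataset)
  expect_equal(nrow(sc), nrow(sp$dataset))
  expect_true(all(sc$raw_cosine >= -1 & sc$raw_cosine <= 1))
  expect_true(all(sc$normalized >= 0 & sc$normalized <= 1))
  expect_equal(order(sc$raw_cosine), order(sc$normalized)) # monotone transform
})

test_that("evaluation produces one row per graph-strategy pair with shared splits", {
  graphs <- list(
    sbm = generate_graph(graph_spec("stochastic_block", 60,
      list(block_sizes = c(30L, 30L), p_in = 0.3, p_out = 0.02), seed = 16)),
    er = generate_graph(graph_spec("erdos_renyi", 50, list(p = 0.15), seed = 17)))
  strategies <- list(walk_config("RW", beta = 4, alpha = 30),
                     walk_config("DG", beta = 4, alpha = 30))
  strategies <- stats::setNames(strategies, c("RW", "DG"))
  out <- evaluate_strategies(graphs, strategies,
                             embedding_config(dimension = 24, seed = 1),
                             split_seed = 5)
  expect_equal(nrow(out$results), 4)
  expect_true(all(out$results$auc_roc >= 0 & out$results$auc_roc <= 1))
  expect_true(all(out$results$auc_pr >= 0 & out$results$auc_pr <= 1))
  # median over two graphs is the mean of the two AUCs
  med <- out$medians
  for (s in c("RW", "DG")) {
    expect_equal(med$auc_roc[med$strategy == s],
                 mean(out$results$auc_roc[out$results$strategy == s]))
  }
  # shared split: both strategies scored the identical pair list per graph
  for (gname in names(graphs)) {
    gr <- out$records[out$records$graph == gname, ]
    pairs <- split(paste(gr$u, gr$v), gr$strategy)
    expect_identical(pairs[[1]], pairs[[2]])
  }
  expect_error(evaluate_strategies(graphs, list(),
                                   embedding_config(dimension = 8)),
               "at least one strategy")
})
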