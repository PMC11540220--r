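test_that("transition weights follow each strategy's law on known states", {
  tri <- fixture_graph("triangle")

  # TSAW: weight exp(-lambda f) halves per visit at lambda = ln 2
  w <- transition_weights(tri, walk_config("TSAW"), "0",
                          visit_counts = c("1" = 1, "2" = 2))
  expect_equal(unname(w[c("1", "2")]), c(0.5, 0.25))
  w0 <- transition_weights(tri, walk_config("TSAW"), "0")
  expect_equal(unname(w0), c(1, 1))

  # DG: neighbour degrees become weights; probabilities follow by
  # normalization (degrees 3 and 1 -> 0.75 / 0.25)
  g <- igraph::graph_from_edgelist(matrix(c("0","1", "0","2", "1","3", "1","4"),
                                          ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  wd <- transition_weights(g, walk_config("DG"), "0")
  expect_equal(unname(wd[c("1", "2")]), c(3, 1))
  expect_equal(unname(wd / sum(wd))[1:2], c(0.75, 0.25))

  # ID: reciprocal neighbour degree
  wi <- transition_weights(g, walk_config("ID"), "1")
  expect_equal(unname(wi[c("0", "3", "4")]), c(0.5, 1, 1))

  # N2V p=2, q=0.5 from Fig-3-style state: back 1/p, common neighbour 1,
  # outward 1/q
  h <- igraph::graph_from_edgelist(matrix(c("x","c", "x","y", "c","y", "c","z"),
                                          ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  wn <- transition_weights(h, walk_config("N2V", p = 2, q = 0.5), "c",
                           previous = "x")
  expect_equal(unname(wn[c("x", "y", "z")]), c(0.5, 1, 2))
  # without a predecessor the N2V weights are uniform
  wn0 <- transition_weights(h, walk_config("N2V", p = 2, q = 0.5), "c")
  expect_true(all(wn0 == 1))
})

test_that("weights are positive, normalize to 1, and DG/ID are reciprocal", {
  for (nm in fixture_names) {
    g <- fixture_graph(nm)
    for (st in all_walk_states(g)) {
      for (strat in c("RW", "DG", "ID", "N2V")) {
        w <- transition_weights(g, walk_config(strat, p = 1.7, q = 0.6),
                                st$current, st$previous)
        expect_true(all(w > 0))
        expect_equal(sum(w / sum(w)), 1, tolerance = 1e-12)
      }
      wdg <- transition_weights(g, walk_config("DG"), st$current)
      wid <- transition_weights(g, walk_config("ID"), st$current)
      expect_equal(unname(wdg * wid), rep(1, length(wdg)), tolerance = 1e-12)
    }
  }
})

test_that("TSAW at vanishing decay reduces to the unbiased walk", {
  g <- fixture_graph("barbell")
  vc <- c("0" = 3, "4" = 1)
  w <- transition_weights(g, walk_config("TSAW", decay_lambda = 1e-12), "3",
                          visit_counts = vc)
  expect_equal(unname(w), rep(1, length(w)), tolerance = 1e-10)
})

test_that("single steps stay on neighbours and update TSAW memory", {
  g <- fixture_graph("star5")
  cfg <- walk_config("DG", seed = 1)
  state <- list(current = "1", previous = NULL, visit_counts = NULL)
  st2 <- walk_step(state, g, cfg)
  expect_equal(st2$current, "0") # a leaf's only neighbour is the hub
  expect_equal(st2$previous, "1")

  cfg <- walk_config("TSAW")
  state <- list(current = "0", previous = NULL, visit_counts = c("0" = 1))
  withr::with_seed(5, {
    for (i in 1:10) {
      nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, state$current))]
      state2 <- walk_step(state, g, cfg)
      expect_true(state2$current %in% nb)
      expect_equal(sum(state2$visit_counts) - sum(state$visit_counts), 1)
      state <- state2
    }
  })
})

test_that("corpora have beta walks per node of the requested length", {
  tri <- fixture_graph("triangle")
  co <- generate_walks(tri, walk_config("RW", beta = 2, alpha = 5, seed = 3))
  expect_length(co$walks, 6)
  expect_true(all(lengths(co$walks) == 5))
  starts <- co$nodes[vapply(co$walks, `[`, 1L, 1L)]
  expect_equal(unname(table(starts)[c("0", "1", "2")]), rep(2L, 3),
               ignore_attr = TRUE)
  # consecutive pairs are edges
  for (w in co$walks) {
    toks <- co$nodes[w]
    for (i in seq_len(length(toks) - 1)) {
      expect_true(igraph::are_adjacent(tri, toks[i], toks[i + 1]))
    }
  }
})

test_that("walks truncate at isolated nodes but keep them in the corpus", {
  g <- igraph::graph_from_edgelist(matrix(c("0", "1"), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = "2")
  co <- generate_walks(g, walk_config("RW", beta = 2, alpha = 10, seed = 1))
  lens <- vapply(co$walks, length, 1L)
  starts <- co$nodes[vapply(co$walks, `[`, 1L, 1L)]
  expect_true(all(lens[starts == "2"] == 1))
  expect_true(all(lens[starts != "2"] == 10))
  expect_true("2" %in% co$nodes)
})

test_that("corpus generation is deterministic under the config seed", {
  g <- generate_graph(graph_spec("barabasi_albert", 80, list(m = 2), seed = 2))
  for (strat in c("RW", "TSAW", "N2V")) {
    cfg <- walk_config(strat, beta = 3, alpha = 20, seed = 11, p = 0.5, q = 2)
    c1 <- generate_walks(g, cfg)
    c2 <- generate_walks(g, cfg)
    expect_identical(c1$walks, c2$walks)
  }
})

test_that("exact transition matrices match the walk laws and refuse memory walks", {
  p4 <- fixture_graph("path4")
  P <- exact_transition_matrix(p4, "RW")
  expect_equal(unname(P["0", ]), c(0, 1, 0, 0))
  expect_equal(unname(P["1", ]), c(0.5, 0, 0.5, 0))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))

  s5 <- fixture_graph("star5")
  Pd <- exact_transition_matrix(s5, "DG")
  expect_equal(unname(Pd["1", "0"]), 1)
  expect_equal(unname(Pd["0", c("1", "2", "3", "4")]), rep(0.25, 4))

  expect_error(exact_transition_matrix(p4, "TSAW"))
  expect_error(exact_transition_matrix(p4, "N2V"))
})

test_that("the ID matrix on a seeded random graph matches brute-force normalization", {
  g <- generate_graph(graph_spec("erdos_renyi", 20, list(p = 0.3), seed = 7))
  P <- exact_transition_matrix(g, "ID")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(A)
  ref <- matrix(0, 20, 20, dimnames = dimnames(A))
  for (u in seq_len(20)) {
    if (deg[u] == 0) next
    w <- A[u, ] / deg # tau = 1/deg(v) on neighbours
    ref[u, ] <- w / sum(w)
  }
  expect_equal(P[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
})

test_that("N2V(1, 1) transition distributions equal RW everywhere", {
  for (nm in fixture_names) {
    g <- fixture_graph(nm)
    for (st in all_walk_states(g)) {
      wr <- transition_weights(g, walk_config("RW"), st$current, st$previous)
      wn <- transition_weights(g, walk_config("N2V", p = 1, q = 1),
                               st$current, st$previous)
      expect_identical(wr / sum(wr), wn / sum(wn))
    }
  }
})

test_that("empirical step frequencies agree with the exact law (chi-square)", {
  g <- fixture_graph("barbell")
  for (strat in c("RW", "DG", "ID")) {
    P <- exact_transition_matrix(g, strat)
    counts <- sample_transitions(g, walk_config(strat), current = "3",
                                 nsteps = 2e4, seed = 41)
    probs <- P["3", ]
    keep <- probs > 0
    fit <- stats::chisq.test(counts[keep], p = probs[keep])
    expect_gt(fit$p.value, 0.001)
    expect_equal(sum(counts[!keep]), 0)
  }
})

test_that("a long unbiased walk visits nodes proportionally to degree", {
  g <- fixture_graph("two_triangles_bridge") # connected, non-bipartite
  trace <- walk_trace(g, walk_config("RW", seed = 8), start = "0", length = 2e5)
  emp <- table(factor(trace, levels = igraph::V(g)$name)) / length(trace)
  pi_deg <- igraph::degree(g) / (2 * igraph::ecount(g))
  expect_lt(sum(abs(emp - pi_deg[names(emp)])) / 2, 0.02)
})
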