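# Independent oracles, kept deliberately naive.

# AUC-ROC as the exhaustive pairwise probability that a positive outscores
# a negative, ties counting one half.
auc_pairwise_oracle <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Average precision by exhaustive enumeration of descending unique-score
# thresholds.
ap_threshold_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_recall <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / npos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Pearson r straight from the covariance formula.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# all (previous, current) states of a graph with current non-isolated
all_walk_states <- function(g) {
  nodes <- igraph::V(g)$name
  states <- list()
  for (cur in nodes) {
    nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, cur))]
    if (length(nb) == 0) next
    states[[length(states) + 1]] <- list(current = cur, previous = NULL)
    for (prev in nb) {
      states[[length(states) + 1]] <- list(current = cur, previous = prev)
    }
  }
  states
}

fixture_names <- c("triangle", "path4", "star5", "two_triangles_bridge", "barbell")

# small corpus for embedding tests
tiny_corpus <- function(name = "triangle", strategy = "RW", beta = 4, alpha = 10,
                        seed = 1) {
  generate_walks(fixture_graph(name),
                 walk_config(strategy, beta = beta, alpha = alpha, seed = seed))
}
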