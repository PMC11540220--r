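#' Cosine similarity of two vectors
#'
#' `dot(a, b) / (||a|| ||b||)`, in \[-1, 1\].
#'
#' @param a,b Numeric vectors of equal length, both non-zero.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors have different dimensions")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Min-max normalization to \[0, 1\]
#'
#' `(s - min) / (max - min)`. A constant input has no range and is mapped
#' to all 0.5 with a warning.
#'
#' @param scores Numeric vector of at least 2 values.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores to normalize")
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    warning("constant scores: min-max normalization degenerate, mapping to 0.5")
    return(rep(0.5, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

check_binary_scores <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
}

#' Area under the ROC curve
#'
#' Computed by the Mann-Whitney rank formulation with midrank tie
#' handling: the probability that a random positive outscores a random
#' negative, counting ties as 1/2.
#'
#' @param labels Binary 0/1 vector with both classes present.
#' @param scores Numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(labels, scores) {
  check_binary_scores(labels, scores)
  r <- rank(scores) # midranks
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Stepwise summation `sum_k (R_k - R_{k-1}) P_k` over descending unique
#' score thresholds, with tied scores grouped at one threshold.
#'
#' @param labels Binary 0/1 vector with both classes present.
#' @param scores Numeric scores, same length.
#' @return Average precision in \[0, 1\].
#' @export
auc_pr <- function(labels, scores) {
  check_binary_scores(labels, scores)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  # cumulative tp/fp per threshold group
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- match(s, thresholds)
  tp_g <- tapply(l, grp, sum)
  n_g <- tapply(l, grp, length)
  tp <- cumsum(tp_g)
  pred <- cumsum(n_g)
  precision <- tp / pred
  recall <- tp / n_pos
  sum((recall - c(0, recall[-length(recall)])) * precision)
}

#' Cosine-score a labeled edge set against an embedding
#'
#' Raw cosine similarities plus their min-max normalization within the
#' scored set. Pairs with a node missing from the vocabulary (guarded
#' against, impossible with walk truncation enabled) receive the median
#' raw score of the set, with a warning.
#'
#' @param emb A `node_embedding`.
#' @param dataset A `labeled_edge_set`.
#' @return A data frame with columns `u`, `v`, `label`, `raw_cosine`,
#'   `normalized`.
#' @export
score_pairs <- function(emb, dataset) {
  stopifnot(inherits(emb, "node_embedding"), inherits(dataset, "labeled_edge_set"))
  vocab <- rownames(emb$vectors)
  iu <- match(dataset$u, vocab)
  iv <- match(dataset$v, vocab)
  ok <- !is.na(iu) & !is.na(iv)
  raw <- rep(NA_real_, nrow(dataset))
  # row-normalize once, then cosine = dot of unit rows
  vn <- emb$vectors / sqrt(rowSums(emb$vectors^2))
  raw[ok] <- rowSums(vn[iu[ok], , drop = FALSE] * vn[iv[ok], , drop = FALSE])
  raw <- pmin(1, pmax(-1, raw))
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) with out-of-vocabulary nodes scored at the group median")
    raw[!ok] <- stats::median(raw[ok])
  }
  out <- data.frame(u = dataset$u, v = dataset$v, label = dataset$label,
                    raw_cosine = raw, stringsAsFactors = FALSE)
  out$normalized <- minmax_normalize(out$raw_cosine)
  out
}

# stage seeds derived from one split seed by fixed offsets, so graphs and
# (graph, strategy) stages use isolated streams
derive_seed <- function(base, graph_index, strategy_index = 0L, stage = 0L) {
  as.integer((base + graph_index * 10000L + strategy_index * 100L + stage) %% .Machine$integer.max)
}

#' Run the link-prediction comparison over a graph suite
#'
#' For every graph: extract the largest connected component, make one
#' shared edge split, and for every walk strategy generate walks on the
#' residual graph, train embeddings, score the labeled pairs by cosine
#' similarity, and compute AUC-ROC and AUC-PR. The split is computed once
#' per graph and shared by all strategies so that per-edge similarities
#' are comparable across walks.
#'
#' @param graphs Named list of `igraph` graphs.
#' @param strategies Named list of [walk_config()]s (default: the nine
#'   default strategies).
#' @param emb_config An [embedding_config()].
#' @param split_seed Integer seed from which all per-graph and per-strategy
#'   stage seeds are derived by fixed offsets.
#' @param removal_fraction Fraction of edges removed per graph
#'   (default 0.25).
#' @param min_positives Graphs whose split would yield fewer positives are
#'   rejected (default 10).
#' @param verbose Print progress.
#' @return A `link_eval_results` list: `results` (data frame: graph,
#'   strategy, auc_roc, auc_pr, n_pos, n_neg), `records` (per-edge
#'   similarity data frame with graph and strategy columns), `medians`
#'   (per-strategy median AUCs, sorted descending by AUC).
#' @export
evaluate_strategies <- function(graphs, strategies = default_strategies(),
                                emb_config = embedding_config(),
                                split_seed = 1L, removal_fraction = 0.25,
                                min_positives = 10L, verbose = FALSE) {
  if (length(graphs) < 1L) stop("need at least one graph")
  if (length(strategies) < 1L) stop("need at least one strategy")
  if (is.null(names(graphs)) || anyDuplicated(names(graphs)))
    stop("graphs must be uniquely named")
  strat_names <- vapply(strategies, `[[`, "", "name")
  if (anyDuplicated(strat_names)) stop("duplicate strategy names")

  res <- list(); recs <- list()
  for (gi in seq_along(graphs)) {
    gname <- names(graphs)[gi]
    lcc <- largest_connected_component(graphs[[gi]])
    split <- make_split(lcc, removal_fraction,
                        seed = derive_seed(split_seed, gi),
                        min_positives = min_positives)
    for (si in seq_along(strategies)) {
      cfg <- strategies[[si]]
      cfg$seed <- derive_seed(split_seed, gi, si, 1L)
      if (verbose) message("  ", gname, " / ", cfg$name)
      corpus <- generate_walks(split$residual, cfg)
      emb_cfg <- emb_config
      emb_cfg$seed <- derive_seed(split_seed, gi, si, 2L)
      emb <- train_embeddings(corpus, emb_cfg)
      scored <- score_pairs(emb, split$dataset)
      res[[length(res) + 1L]] <- data.frame(
        graph = gname, strategy = cfg$name,
        auc_roc = auc_roc(scored$label, scored$normalized),
        auc_pr = auc_pr(scored$label, scored$normalized),
        n_pos = sum(scored$label == 1L), n_neg = sum(scored$label == 0L),
        stringsAsFactors = FALSE)
      scored$graph <- gname
      scored$strategy <- cfg$name
      recs[[length(recs) + 1L]] <- scored
    }
  }
  results <- do.call(rbind, res)
  structure(list(results = results,
                 records = do.call(rbind, recs),
                 medians = strategy_medians(results)),
            class = "link_eval_results")
}

#' Per-strategy median AUCs across graphs
#'
#' @param results Data frame with columns `strategy`, `auc_roc`, `auc_pr`
#'   (one row per graph and strategy).
#' @return Data frame (strategy, auc_roc, auc_pr) of medians across
#'   graphs, sorted descending by AUC-ROC.
#' @export
strategy_medians <- function(results) {
  med <- do.call(rbind, lapply(split(results, results$strategy), function(d) {
    data.frame(strategy = d$strategy[1],
               auc_roc = stats::median(d$auc_roc),
               auc_pr = stats::median(d$auc_pr),
               stringsAsFactors = FALSE)
  }))
  med <- med[order(-med$auc_roc, med$strategy), ]
  rownames(med) <- NULL
  med
}

#' @export
print.link_eval_results <- function(x, ...) {
  cat("<link_eval_results> ", length(unique(x$results$graph)), " graphs x ",
      length(unique(x$results$strategy)), " strategies\nmedians:\n", sep = "")
  print(x$medians)
  invisible(x)
}
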