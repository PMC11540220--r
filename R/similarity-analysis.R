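#' Pearson correlation coefficient
#'
#' Sample Pearson correlation, with explicit rejection of the degenerate
#' inputs (constant vectors) for which it is undefined.
#'
#' @param x,y Numeric vectors of equal length, at least 3, both
#'   non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for constant input")
  stats::cor(x, y, method = "pearson")
}

#' Pairwise correlation of walk strategies on one graph
#'
#' Pearson correlation between the per-edge normalized similarity vectors
#' of every pair of walk strategies, over the shared labeled pair list of
#' one graph. All strategies must have scored exactly the same pairs in
#' the same order (guaranteed when the split is shared); a mismatch is a
#' hard error.
#'
#' @param records Per-edge similarity data frame for a single graph, with
#'   columns `u`, `v`, `strategy`, `normalized` (the `records` element of
#'   [evaluate_strategies()] restricted to one graph).
#' @return A symmetric correlation matrix with unit diagonal, attribute
#'   `aggregation = "per_graph"`.
#' @export
walk_pair_correlations <- function(records) {
  if ("graph" %in% names(records) && length(unique(records$graph)) > 1L)
    stop("records span multiple graphs; correlate one graph at a time")
  strategies <- unique(records$strategy)
  per <- split(records, factor(records$strategy, levels = strategies))
  ref <- paste(per[[1]]$u, per[[1]]$v)
  cols <- lapply(per, function(d) {
    if (!identical(paste(d$u, d$v), ref))
      stop("labeled pair lists differ across strategies; the shared split is broken")
    d$normalized
  })
  m <- stats::cor(do.call(cbind, cols), method = "pearson")
  dimnames(m) <- list(strategies, strategies)
  diag(m) <- 1
  attr(m, "aggregation") <- "per_graph"
  m
}

#' Entrywise median of per-graph correlation matrices
#'
#' @param per_graph List of correlation matrices from
#'   [walk_pair_correlations()], with identical strategy ordering.
#' @return Symmetric matrix of entrywise medians with unit diagonal,
#'   attribute `aggregation = "median_across_graphs"`.
#' @export
median_correlation <- function(per_graph) {
  if (length(per_graph) < 1L) stop("need at least one matrix")
  dn <- dimnames(per_graph[[1]])
  for (m in per_graph) {
    if (!identical(dimnames(m), dn)) stop("strategy ordering differs across matrices")
  }
  out <- apply(simplify2array(per_graph), c(1, 2), stats::median)
  dimnames(out) <- dn
  attr(out, "aggregation") <- "median_across_graphs"
  out
}

#' Topology metrics of a network
#'
#' The ten summary metrics used to relate link-prediction performance to
#' network structure: node count, edge count, density, mean degree, degree
#' assortativity, mean local clustering coefficient (isolated and
#' degree-one nodes count 0), transitivity (global clustering), diameter,
#' mean shortest-path length, and the Shannon entropy (base 2) of the
#' empirical degree distribution. Metrics are intended for the pre-removal
#' connected graph; a disconnected input is refused since the path metrics
#' are undefined there.
#'
#' @param g A connected `igraph` graph.
#' @return A one-row data frame with the ten metrics.
#' @export
network_metrics <- function(g) {
  if (!igraph::is_connected(g)) stop("network metrics require a connected graph")
  deg <- igraph::degree(g)
  ptab <- table(deg) / length(deg)
  entropy <- -sum(ptab * log2(ptab))
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  data.frame(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    density = igraph::edge_density(g),
    mean_degree = mean(deg),
    assortativity = assort,
    mean_clustering = igraph::transitivity(g, type = "localaverage", isolates = "zero"),
    transitivity = igraph::transitivity(g, type = "global"),
    diameter = igraph::diameter(g),
    mean_path_length = igraph::mean_distance(g),
    degree_entropy = entropy)
}

#' Correlate link-prediction performance with topology metrics
#'
#' For every metric, the Pearson correlation between the per-graph metric
#' values and the per-graph AUC-ROC (aggregated across strategies by the
#' median). Metrics constant across the graphs are skipped with a warning.
#'
#' @param results Results data frame from [evaluate_strategies()] (the
#'   `results` element), or a `link_eval_results` object.
#' @param metrics Data frame of per-graph metrics with a `graph` column
#'   and one column per metric (see [network_metrics()]).
#' @return Named numeric vector: metric -> Pearson r with median AUC.
#' @export
metric_performance_correlation <- function(results, metrics) {
  if (inherits(results, "link_eval_results")) results <- results$results
  if (!"graph" %in% names(metrics)) stop("metrics needs a 'graph' column")
  auc_by_graph <- vapply(split(results$auc_roc, results$graph),
                         stats::median, numeric(1))
  if (length(auc_by_graph) < 3L) stop("need at least 3 graphs")
  metrics <- metrics[match(names(auc_by_graph), metrics$graph), ]
  metric_cols <- setdiff(names(metrics), "graph")
  out <- numeric(0)
  for (mc in metric_cols) {
    x <- metrics[[mc]]
    if (anyNA(x) || stats::sd(x) == 0) {
      warning("metric '", mc, "' constant or undefined across graphs; skipped")
      next
    }
    out[mc] <- pearson_r(x, unname(auc_by_graph))
  }
  out
}

#' Heatmap of a strategy correlation matrix
#'
#' Optional ggplot2 rendering of a [walk_pair_correlations()] or
#' [median_correlation()] matrix.
#'
#' @param m A correlation matrix.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(m) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- expand.grid(x = rownames(m), y = colnames(m), stringsAsFactors = FALSE)
  df$r <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r")
}
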