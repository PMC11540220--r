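#' Configuration of an end-to-end pipeline run
#'
#' Validates and freezes everything a run needs: the input graphs (a named
#' list, or `NULL` to generate the synthetic benchmark suite from the
#' master seed), the edge-removal fraction, the walk strategies, the
#' embedding settings, the master seed (all stage seeds are derived from
#' it by fixed offsets) and the output directory.
#'
#' @param graphs Named list of `igraph` graphs, or `NULL` to use
#'   [make_benchmark_suite()] at the master seed.
#' @param removal_fraction Fraction of edges removed per graph
#'   (default 0.25).
#' @param strategies Named list of [walk_config()]s; names must be unique
#'   (default: the nine default strategies).
#' @param emb_config An [embedding_config()].
#' @param master_seed Integer master seed (default 1).
#' @param out_dir Output directory.
#' @param min_positives Minimum positive-edge count per graph (default 10).
#' @return A `run_config` object.
#' @export
run_config <- function(graphs = NULL, removal_fraction = 0.25,
                       strategies = default_strategies(),
                       emb_config = embedding_config(),
                       master_seed = 1L, out_dir = tempfile("walklink_run_"),
                       min_positives = 10L) {
  stopifnot(removal_fraction > 0, removal_fraction < 1)
  nm <- vapply(strategies, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate strategy names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  if (!is.null(graphs) && (is.null(names(graphs)) || anyDuplicated(names(graphs))))
    stop("graphs must be uniquely named")
  stopifnot(inherits(emb_config, "embedding_config"))
  structure(list(graphs = graphs, removal_fraction = removal_fraction,
                 strategies = stats::setNames(strategies, nm),
                 emb_config = emb_config, master_seed = as.integer(master_seed),
                 out_dir = out_dir, min_positives = as.integer(min_positives)),
            class = "run_config")
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(strategy = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

sanitize <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Run the full pipeline
#'
#' Executes graph preparation, walk generation, embedding training, link
#' prediction and correlation analysis for every (graph, strategy)
#' combination, writing per-stage artifacts under `config$out_dir`:
#'
#' * `graphs/` - input graphs as edge lists;
#' * `splits/` - residual edge lists and labeled pair CSVs per graph;
#' * `corpora/` - one walk-corpus text file per (graph, strategy);
#' * `embeddings/` - one word-vector text file per (graph, strategy);
#' * `similarities/` - per-edge similarity CSVs per graph;
#' * `results.csv`, `medians.csv` - per-run AUC table and per-strategy
#'   medians;
#' * `correlations/` - per-graph and median strategy-correlation CSVs;
#' * `metric_correlations.csv` - topology-metric vs AUC correlations;
#' * `manifest.json` - configuration echo, derived seeds and a config
#'   hash.
#'
#' Reruns with the same configuration reproduce byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @param verbose Print progress.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  for (d in c("", "graphs", "splits", "corpora", "embeddings", "similarities",
              "correlations")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  graphs <- config$graphs %||% make_benchmark_suite(config$master_seed)

  seeds <- list()
  res <- list(); recs <- list(); metrics <- list()
  for (gi in seq_along(graphs)) {
    gname <- names(graphs)[gi]
    gtag <- sanitize(gname)
    if (verbose) message("graph ", gname)
    write_graph_file(graphs[[gi]], file.path(out, "graphs", paste0(gtag, ".edgelist")))
    lcc <- largest_connected_component(graphs[[gi]])
    metrics[[gname]] <- cbind(data.frame(graph = gname), network_metrics(lcc))
    split_seed <- derive_seed(config$master_seed, gi)
    seeds[[gname]] <- list(split = split_seed)
    split <- make_split(lcc, config$removal_fraction, seed = split_seed,
                        min_positives = config$min_positives)
    write_graph_file(split$residual,
                     file.path(out, "splits", paste0(gtag, "_residual.edgelist")))
    write_labeled_edges(split$dataset,
                        file.path(out, "splits", paste0(gtag, "_labeled.csv")))
    for (si in seq_along(config$strategies)) {
      cfg <- config$strategies[[si]]
      stag <- sanitize(cfg$name)
      cfg$seed <- derive_seed(config$master_seed, gi, si, 1L)
      emb_cfg <- config$emb_config
      emb_cfg$seed <- derive_seed(config$master_seed, gi, si, 2L)
      seeds[[gname]][[cfg$name]] <- c(walk = cfg$seed, embed = emb_cfg$seed)
      if (verbose) message("  ", cfg$name)
      corpus <- generate_walks(split$residual, cfg)
      write_corpus(corpus, file.path(out, "corpora", paste0(gtag, "_", stag, ".txt")))
      emb <- train_embeddings(corpus, emb_cfg)
      export_embeddings(emb, file.path(out, "embeddings",
                                       paste0(gtag, "_", stag, ".vec")))
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
  records <- do.call(rbind, recs)
  utils::write.csv(results, file.path(out, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(strategy_medians(results), file.path(out, "medians.csv"),
                   row.names = FALSE)

  per_graph <- list()
  for (gname in unique(records$graph)) {
    gr <- records[records$graph == gname, ]
    utils::write.csv(gr, file.path(out, "similarities",
                                   paste0(sanitize(gname), ".csv")),
                     row.names = FALSE)
    cm <- walk_pair_correlations(gr)
    per_graph[[gname]] <- cm
    write_matrix_csv(cm, file.path(out, "correlations",
                                   paste0(sanitize(gname), ".csv")))
  }
  write_matrix_csv(median_correlation(per_graph),
                   file.path(out, "correlations", "median.csv"))

  metrics_df <- do.call(rbind, metrics)
  utils::write.csv(metrics_df, file.path(out, "network_metrics.csv"),
                   row.names = FALSE)
  if (length(unique(results$graph)) >= 3L) {
    mc <- metric_performance_correlation(results, metrics_df)
    utils::write.csv(data.frame(metric = names(mc), pearson_r = unname(mc)),
                     file.path(out, "metric_correlations.csv"),
                     row.names = FALSE)
  }

  cfg_echo <- list(
    removal_fraction = config$removal_fraction,
    strategies = lapply(unname(config$strategies), function(s)
      s[c("strategy", "beta", "alpha", "decay_lambda", "p", "q", "name")]),
    embedding = unclass(config$emb_config)[c("dimension", "window", "negative",
                                             "epochs", "learning_rate")],
    master_seed = config$master_seed,
    min_positives = config$min_positives,
    graphs = names(graphs))
  cfg_json <- jsonlite::toJSON(cfg_echo, auto_unbox = TRUE, digits = NA)
  manifest <- list(config = cfg_echo,
                   config_hash = config_hash(cfg_json),
                   derived_seeds = seeds)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

config_hash <- function(json) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}
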