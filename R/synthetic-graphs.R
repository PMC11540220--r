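#' Specification of a synthetic benchmark graph
#'
#' A `graph_spec` bundles a random-graph model, its size, its model-specific
#' parameters and a seed, so that the same spec always regenerates the same
#' edge set. Supported models:
#'
#' * `"erdos_renyi"`: G(n, p); `model_params` needs `p` in \[0, 1\].
#' * `"barabasi_albert"`: preferential attachment; `model_params` needs the
#'   attachment count `m` (edges added per new node, `1 <= m < n_nodes`).
#' * `"watts_strogatz"`: ring lattice with rewiring; `model_params` needs the
#'   neighbourhood radius `nei >= 1` and rewiring probability `p_rewire` in
#'   \[0, 1\]. Low `p_rewire` approximates lattice-like (street-like) graphs.
#' * `"stochastic_block"`: planted communities; `model_params` needs
#'   `block_sizes` (positive integers summing to `n_nodes`), `p_in` and
#'   `p_out` in \[0, 1\].
#'
#' @param model One of `"erdos_renyi"`, `"barabasi_albert"`,
#'   `"watts_strogatz"`, `"stochastic_block"`.
#' @param n_nodes Number of nodes (at least 4).
#' @param model_params Named list of model parameters, see Details.
#' @param seed Integer seed controlling generation.
#' @return An object of class `graph_spec`.
#' @seealso [generate_graph()], [make_benchmark_suite()]
#' @export
graph_spec <- function(model, n_nodes, model_params = list(), seed = 1L) {
  models <- c("erdos_renyi", "barabasi_albert", "watts_strogatz", "stochastic_block")
  if (!is.character(model) || length(model) != 1L || !model %in% models) {
    stop("unknown model: ", paste(model, collapse = ", "),
         "; expected one of ", paste(models, collapse = ", "))
  }
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 4L) stop("n_nodes must be an integer >= 4")
  stopifnot(is.list(model_params))
  need <- switch(model,
    erdos_renyi = "p",
    barabasi_albert = "m",
    watts_strogatz = c("nei", "p_rewire"),
    stochastic_block = c("block_sizes", "p_in", "p_out"))
  missing <- setdiff(need, names(model_params))
  if (length(missing) > 0L) {
    stop("model_params incomplete for ", model, ": missing ",
         paste(missing, collapse = ", "))
  }
  if (model == "erdos_renyi" && (model_params$p < 0 || model_params$p > 1))
    stop("edge probability p must lie in [0, 1]")
  if (model == "barabasi_albert" &&
      (model_params$m < 1 || model_params$m >= n_nodes))
    stop("attachment count m must satisfy 1 <= m < n_nodes")
  if (model == "watts_strogatz" &&
      (model_params$nei < 1 || model_params$p_rewire < 0 || model_params$p_rewire > 1))
    stop("watts_strogatz needs nei >= 1 and p_rewire in [0, 1]")
  if (model == "stochastic_block") {
    bs <- model_params$block_sizes
    if (any(bs < 1) || sum(bs) != n_nodes)
      stop("block_sizes must be positive and sum to n_nodes")
    if (any(c(model_params$p_in, model_params$p_out) < 0) ||
        any(c(model_params$p_in, model_params$p_out) > 1))
      stop("p_in and p_out must lie in [0, 1]")
  }
  structure(list(model = model, n_nodes = n_nodes,
                 model_params = model_params, seed = as.integer(seed)),
            class = "graph_spec")
}

#' @export
print.graph_spec <- function(x, ...) {
  cat("<graph_spec>", x$model, "n =", x$n_nodes, "seed =", x$seed, "\n")
  invisible(x)
}

# Name vertices "0".."n-1"; node identifiers are consecutive integers from 0.
label_nodes <- function(g) {
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(igraph::vcount(g)) - 1L))
}

#' Generate a synthetic graph from a specification
#'
#' Produces a simple undirected graph (no self-loops, no multi-edges) with
#' node identifiers `"0" .. "n-1"`. Identical specs yield identical edge
#' sets.
#'
#' @param spec A [graph_spec()].
#' @return An `igraph` graph.
#' @examples
#' g <- generate_graph(graph_spec("erdos_renyi", 10, list(p = 1), seed = 1))
#' igraph::ecount(g) # 45: p = 1 forces the complete graph
#' @export
generate_graph <- function(spec) {
  if (!inherits(spec, "graph_spec")) stop("spec must be a graph_spec")
  g <- withr::with_seed(spec$seed, {
    pp <- spec$model_params
    raw <- switch(spec$model,
      erdos_renyi = igraph::sample_gnp(spec$n_nodes, pp$p),
      barabasi_albert = igraph::sample_pa(spec$n_nodes, m = pp$m, directed = FALSE),
      watts_strogatz = igraph::sample_smallworld(1, spec$n_nodes, pp$nei, pp$p_rewire),
      stochastic_block = {
        k <- length(pp$block_sizes)
        pref <- matrix(pp$p_out, k, k)
        diag(pref) <- pp$p_in
        igraph::sample_sbm(spec$n_nodes, pref.matrix = pref,
                           block.sizes = pp$block_sizes)
      })
    igraph::simplify(raw)
  })
  g <- label_nodes(g)
  g <- igraph::set_graph_attr(g, "model", spec$model)
  igraph::set_graph_attr(g, "spec_seed", spec$seed)
}

#' Small hard-coded fixture graphs
#'
#' Tiny named graphs with fully known structure, used as analytic oracles
#' for the walk transition laws.
#'
#' @param name One of `"triangle"`, `"path4"`, `"star5"`,
#'   `"two_triangles_bridge"`, `"barbell"`.
#' @return An `igraph` graph with node names `"0"`, `"1"`, ...
#' @export
fixture_graph <- function(name) {
  edges <- switch(name,
    triangle = c(0,1, 1,2, 0,2),
    path4 = c(0,1, 1,2, 2,3),
    star5 = c(0,1, 0,2, 0,3, 0,4),
    two_triangles_bridge = c(0,1, 1,2, 0,2, 3,4, 4,5, 3,5, 2,3),
    barbell = c(0,1, 0,2, 0,3, 1,2, 1,3, 2,3, 4,5, 4,6, 4,7, 5,6, 5,7, 6,7, 3,4),
    stop("unknown fixture name: ", name))
  igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2, byrow = TRUE),
                              directed = FALSE)
}

# model, size tag, n, params for the 12-graph benchmark; fixed design:
# 4 models x 3 sizes, all within the node range of the emulated corpus,
# including one dense graph (sbm_480, mean degree > 20) and one sparse
# near-tree (ws_480, mean degree 2).
benchmark_design <- function() {
  list(
    er_120  = list(model = "erdos_renyi", n = 120L, params = list(p = 6 / 119)),
    er_250  = list(model = "erdos_renyi", n = 250L, params = list(p = 8 / 249)),
    er_480  = list(model = "erdos_renyi", n = 480L, params = list(p = 10 / 479)),
    ba_120  = list(model = "barabasi_albert", n = 120L, params = list(m = 2)),
    ba_250  = list(model = "barabasi_albert", n = 250L, params = list(m = 3)),
    ba_480  = list(model = "barabasi_albert", n = 480L, params = list(m = 2)),
    ws_120  = list(model = "watts_strogatz", n = 120L, params = list(nei = 2, p_rewire = 0.05)),
    ws_250  = list(model = "watts_strogatz", n = 250L, params = list(nei = 2, p_rewire = 0.05)),
    ws_480  = list(model = "watts_strogatz", n = 480L, params = list(nei = 1, p_rewire = 0.05)),
    sbm_120 = list(model = "stochastic_block", n = 120L,
                   params = list(block_sizes = rep(30L, 4), p_in = 0.25, p_out = 0.01)),
    sbm_250 = list(model = "stochastic_block", n = 250L,
                   params = list(block_sizes = rep(50L, 5), p_in = 0.16, p_out = 0.015)),
    sbm_480 = list(model = "stochastic_block", n = 480L,
                   params = list(block_sizes = rep(96L, 5), p_in = 0.3, p_out = 0.02))
  )
}

#' Build the synthetic benchmark suite
#'
#' Twelve graphs (4 random-graph models at 3 sizes each, 120-480 nodes)
#' spanning community-structured, scale-free, lattice-like and homogeneous
#' random topologies, including one dense graph (mean degree > 20) and one
#' sparse near-tree (mean degree < 3). Per-graph seeds are derived from
#' `master_seed` by fixed offsets so each graph is an isolated random
#' instance and the whole suite is reproducible.
#'
#' @param master_seed Integer master seed.
#' @return Named list of `igraph` graphs.
#' @export
make_benchmark_suite <- function(master_seed = 1L) {
  design <- benchmark_design()
  out <- vector("list", length(design))
  names(out) <- names(design)
  for (i in seq_along(design)) {
    d <- design[[i]]
    spec <- graph_spec(d$model, d$n, d$params,
                       seed = as.integer(master_seed) + i * 101L)
    out[[i]] <- generate_graph(spec)
  }
  out
}

#' Export a graph suite to a directory
#'
#' Writes each graph as a two-column edge list and a `manifest.json`
#' recording name, model, node/edge counts and generation seed.
#'
#' @param suite Named list of `igraph` graphs, e.g. from
#'   [make_benchmark_suite()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_suite <- function(suite, dir) {
  stopifnot(is.list(suite), !is.null(names(suite)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(names(suite), function(nm) {
    g <- suite[[nm]]
    file <- paste0(nm, ".edgelist")
    write_graph_file(g, file.path(dir, file), format = "edgelist")
    list(name = nm, file = file,
         model = if (!is.null(igraph::graph_attr(g, "model")))
           igraph::graph_attr(g, "model") else NA,
         seed = if (!is.null(igraph::graph_attr(g, "spec_seed")))
           igraph::graph_attr(g, "spec_seed") else NA,
         n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
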