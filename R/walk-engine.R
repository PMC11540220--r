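strategy_codes <- c(RW = 0L, DG = 1L, ID = 2L, TSAW = 3L, N2V = 4L)

#' Configuration of a walk strategy
#'
#' Bundles a walk strategy with its parameters:
#'
#' * `RW` - unbiased walk, every neighbour weight 1;
#' * `DG` - degree-biased, weight = neighbour degree;
#' * `ID` - inverse-degree, weight = 1 / neighbour degree;
#' * `TSAW` - true self-avoiding walk, weight = `exp(-decay_lambda * f_v)`
#'   where `f_v` counts visits to the candidate node within the current
#'   walk;
#' * `N2V` - second-order node2vec walk: weight `1/p` to return to the
#'   previous node, 1 to a neighbour of the previous node, `1/q` outward.
#'
#' @param strategy One of `"RW"`, `"DG"`, `"ID"`, `"TSAW"`, `"N2V"`.
#' @param beta Walks started per node (default 40).
#' @param alpha Walk length in nodes, i.e. `alpha - 1` transitions
#'   (default 200).
#' @param decay_lambda TSAW decay factor, must be positive (default
#'   `log(2)`, halving the weight per visit).
#' @param p,q node2vec return and in-out parameters, must be positive.
#' @param seed Integer seed for corpus generation.
#' @param name Display name; defaults to the strategy, with `(p, q)`
#'   appended for N2V.
#' @return A `walk_config` object.
#' @export
walk_config <- function(strategy = c("RW", "DG", "ID", "TSAW", "N2V"),
                        beta = 40L, alpha = 200L, decay_lambda = log(2),
                        p = 1, q = 1, seed = 1L, name = NULL) {
  strategy <- match.arg(strategy)
  beta <- as.integer(beta); alpha <- as.integer(alpha)
  stopifnot(beta >= 1L, alpha >= 1L)
  if (strategy == "TSAW" && decay_lambda <= 0) stop("decay_lambda must be > 0 for TSAW")
  if (strategy == "N2V" && (p <= 0 || q <= 0)) stop("p and q must be > 0 for N2V")
  if (is.null(name)) {
    name <- if (strategy == "N2V")
      sprintf("N2V(%g, %g)", p, q) else strategy
  }
  structure(list(strategy = strategy, beta = beta, alpha = alpha,
                 decay_lambda = decay_lambda, p = p, q = q,
                 seed = as.integer(seed), name = name),
            class = "walk_config")
}

#' @export
print.walk_config <- function(x, ...) {
  cat("<walk_config>", x$name, " beta =", x$beta, " alpha =", x$alpha, "\n")
  invisible(x)
}

#' The nine default walk strategies
#'
#' RW, DG, ID, TSAW with decay `ln 2`, and node2vec at (1, 1), (1.5, 0.5),
#' (0.5, 1.5), (2.0, 1.5) and (0.25, 0.5).
#'
#' @param beta,alpha Walks per node and walk length applied to every
#'   strategy.
#' @return Named list of [walk_config()] objects.
#' @export
default_strategies <- function(beta = 40L, alpha = 200L) {
  n2v <- list(c(1, 1), c(1.5, 0.5), c(0.5, 1.5), c(2.0, 1.5), c(0.25, 0.5))
  out <- list(
    walk_config("RW", beta, alpha),
    walk_config("DG", beta, alpha),
    walk_config("ID", beta, alpha),
    walk_config("TSAW", beta, alpha, decay_lambda = log(2)))
  out <- c(out, lapply(n2v, function(pq)
    walk_config("N2V", beta, alpha, p = pq[1], q = pq[2])))
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

# CSR adjacency (0-based, sorted neighbour lists) for the compiled kernels
graph_csr <- function(g) {
  n <- igraph::vcount(g)
  al <- igraph::as_adj_list(g, mode = "all")
  al <- lapply(al, function(vs) sort(as.integer(vs) - 1L))
  deg <- lengths(al)
  list(adj = as.integer(unlist(al, use.names = FALSE)),
       off = as.integer(c(0L, cumsum(deg))),
       n = n, names = igraph::V(g)$name)
}

#' Transition weights of a walk state
#'
#' Unnormalized transition weights `tau_uv` for every neighbour `v` of the
#' current node under the given strategy; dividing by their sum gives the
#' next-step distribution. This is the reference (pure R) statement of the
#' walk laws; the compiled walker implements the same rules.
#'
#' @param g An `igraph` graph.
#' @param config A [walk_config()].
#' @param current Node name (character) of the current position.
#' @param previous Node name of the previous position, or `NULL` at the
#'   first step (N2V then weights all neighbours 1).
#' @param visit_counts Named vector of within-walk visit counts (TSAW
#'   only); nodes absent from it count as unvisited.
#' @return Named numeric vector of positive weights, one per neighbour.
#' @examples
#' g <- fixture_graph("triangle")
#' transition_weights(g, walk_config("TSAW"), current = "0",
#'                    visit_counts = c("1" = 1)) # neighbour "1" weighs 0.5
#' @export
transition_weights <- function(g, config, current, previous = NULL,
                               visit_counts = NULL) {
  stopifnot(inherits(config, "walk_config"))
  nbrs <- igraph::V(g)$name[as.integer(igraph::neighbors(g, current))]
  if (length(nbrs) == 0L) stop("current node '", current, "' is isolated")
  w <- switch(config$strategy,
    RW = rep(1, length(nbrs)),
    DG = igraph::degree(g, nbrs),
    ID = 1 / igraph::degree(g, nbrs),
    TSAW = {
      f <- rep(0, length(nbrs))
      if (!is.null(visit_counts)) {
        hit <- match(nbrs, names(visit_counts))
        f[!is.na(hit)] <- visit_counts[hit[!is.na(hit)]]
      }
      exp(-config$decay_lambda * f)
    },
    N2V = {
      if (is.null(previous)) rep(1, length(nbrs))
      else {
        prev_nbrs <- igraph::V(g)$name[as.integer(igraph::neighbors(g, previous))]
        ifelse(nbrs == previous, 1 / config$p,
               ifelse(nbrs %in% prev_nbrs, 1, 1 / config$q))
      }
    })
  stats::setNames(as.numeric(w), nbrs)
}

#' Sample one step of a walk
#'
#' Draws the next node with probability `tau_uv / Z_u` (weights from
#' [transition_weights()]) and returns the updated walk state.
#'
#' @param state List with elements `current`, `previous` (or `NULL`) and,
#'   for TSAW, `visit_counts` (named vector).
#' @param g An `igraph` graph.
#' @param config A [walk_config()].
#' @return The updated state; `state$current` is the sampled node.
#' @export
walk_step <- function(state, g, config) {
  w <- transition_weights(g, config, state$current, state$previous,
                          state$visit_counts)
  u <- stats::runif(1) * sum(w)
  nxt <- names(w)[findInterval(u, cumsum(w), left.open = TRUE) + 1L]
  if (config$strategy == "TSAW") {
    vc <- state$visit_counts %||% stats::setNames(numeric(0), character(0))
    vc[nxt] <- (if (nxt %in% names(vc)) vc[[nxt]] else 0) + 1
    state$visit_counts <- vc
  }
  state$previous <- state$current
  state$current <- nxt
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a walk corpus
#'
#' Starts `beta` walks at every node of the graph, each running for
#' `alpha` nodes unless truncated at a neighbourless node (truncated walks
#' are kept, so isolated nodes still enter the vocabulary). TSAW visit
#' counts are reset at the start of every walk, with the start node counted
#' as visited once. Deterministic under the config seed.
#'
#' @param g An `igraph` graph.
#' @param config A [walk_config()].
#' @return A `walk_corpus`: list with `walks` (list of integer vectors of
#'   1-based node indices), `nodes` (node names, indexing `walks`), and
#'   `config`.
#' @export
generate_walks <- function(g, config) {
  stopifnot(inherits(config, "walk_config"))
  csr <- graph_csr(g)
  if (csr$n == 0L) stop("empty graph")
  starts <- rep(0:(csr$n - 1L), each = config$beta)
  walks <- withr::with_seed(config$seed,
    cpp_generate_walks(csr$adj, csr$off, starts, config$alpha,
                       strategy_codes[[config$strategy]],
                       config$decay_lambda, config$p, config$q))
  walks <- lapply(walks, function(w) w + 1L)
  structure(list(walks = walks, nodes = csr$names, config = config),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("<walk_corpus> ", length(x$walks), " walks over ", length(x$nodes),
      " nodes (", x$config$name %||% "?", ")\n", sep = "")
  invisible(x)
}

#' Exact transition matrix of a memoryless walk
#'
#' Row-stochastic matrix with entry `(u, v) = tau_uv / Z_u` for the
#' memoryless strategies RW, DG and ID. History-dependent strategies (TSAW,
#' N2V) have no per-node transition matrix and are refused.
#'
#' @param g An `igraph` graph.
#' @param strategy `"RW"`, `"DG"` or `"ID"`.
#' @return A numeric matrix with node names as dimnames; rows of
#'   non-isolated nodes sum to 1.
#' @export
exact_transition_matrix <- function(g, strategy = c("RW", "DG", "ID")) {
  strategy <- match.arg(strategy)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  P <- matrix(0, n, n, dimnames = list(nodes, nodes))
  cfg <- walk_config(strategy, beta = 1L, alpha = 1L)
  for (u in nodes) {
    if (igraph::degree(g, u) == 0L) next
    w <- transition_weights(g, cfg, u)
    P[u, names(w)] <- w / sum(w)
  }
  P
}

#' Empirical next-step counts at a fixed walk state
#'
#' Repeatedly samples the next node from one frozen state using the
#' compiled walker's weight and sampling code, for goodness-of-fit
#' diagnostics against [exact_transition_matrix()].
#'
#' @param g An `igraph` graph.
#' @param config A [walk_config()].
#' @param current Node name of the current position.
#' @param previous Node name of the previous position or `NULL`.
#' @param visit_counts Named visit-count vector (TSAW), or `NULL`.
#' @param nsteps Number of draws.
#' @param seed Integer seed.
#' @return Named integer vector of counts per node.
#' @export
sample_transitions <- function(g, config, current, previous = NULL,
                               visit_counts = NULL, nsteps = 1e5, seed = 1L) {
  csr <- graph_csr(g)
  cur <- match(current, csr$names) - 1L
  prev <- if (is.null(previous)) -1L else match(previous, csr$names) - 1L
  vc <- integer(csr$n)
  if (!is.null(visit_counts)) {
    vc[match(names(visit_counts), csr$names)] <- as.integer(visit_counts)
  }
  counts <- withr::with_seed(as.integer(seed),
    cpp_sample_steps(csr$adj, csr$off, cur, prev, vc, as.integer(nsteps),
                     strategy_codes[[config$strategy]],
                     config$decay_lambda, config$p, config$q))
  stats::setNames(as.integer(counts), csr$names)
}

#' Trace a single long walk
#'
#' One walk of `length` nodes from a given start node, using the compiled
#' walker; useful for long-run visit-frequency diagnostics.
#'
#' @param g An `igraph` graph.
#' @param config A [walk_config()].
#' @param start Node name of the start position.
#' @param length Number of nodes in the trace.
#' @return Character vector of visited node names.
#' @export
walk_trace <- function(g, config, start, length) {
  csr <- graph_csr(g)
  s <- match(start, csr$names) - 1L
  if (is.na(s)) stop("unknown start node: ", start)
  w <- withr::with_seed(config$seed,
    cpp_generate_walks(csr$adj, csr$off, s, as.integer(length),
                       strategy_codes[[config$strategy]],
                       config$decay_lambda, config$p, config$q))
  csr$names[w[[1]] + 1L]
}
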