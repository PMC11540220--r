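# constructor + validator for the balanced labeled pair set; u, v are node
# name tokens, stored in canonical order (integer value of u < v)
new_labeled_edge_set <- function(u, v, label) {
  stopifnot(length(u) == length(v), length(u) == length(label))
  ui <- as.integer(u); vi <- as.integer(v)
  swap <- ui > vi
  tmp <- ui[swap]; ui[swap] <- vi[swap]; vi[swap] <- tmp
  df <- data.frame(u = as.character(ui), v = as.character(vi),
                   label = as.integer(label), stringsAsFactors = FALSE)
  if (any(df$u == df$v)) stop("labeled edge set contains a self-pair")
  if (anyDuplicated(paste(df$u, df$v))) stop("labeled edge set contains duplicate pairs")
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  class(df) <- c("labeled_edge_set", "data.frame")
  df
}

#' @export
print.labeled_edge_set <- function(x, ...) {
  cat("<labeled_edge_set> ", sum(x$label == 1L), " positives, ",
      sum(x$label == 0L), " negatives\n", sep = "")
  invisible(x)
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component; ties between
#' equal-size components are broken in favour of the component containing
#' the smallest minimum node identifier. Vertex names are preserved.
#'
#' @param g A non-empty `igraph` graph.
#' @return A connected `igraph` graph.
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    ids <- as.integer(igraph::V(g)$name)
    min_id <- vapply(best, function(k) min(ids[comp$membership == k]), numeric(1))
    best <- best[which.min(min_id)]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

# canonical integer key of an unordered pair over n nodes (0-based ids)
pair_key <- function(a, b, n) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  as.numeric(lo) * n + hi
}

#' Split a graph into a residual graph and a balanced labeled edge set
#'
#' Removes a random fraction of the edges (the positive sample) and draws
#' an equal number of node pairs uniformly from the non-edges of the
#' pre-removal graph (the negative sample). The residual graph keeps all
#' vertices and may be disconnected; it is not re-reduced to its largest
#' component. The positive count is `floor(removal_fraction * |E| + 0.5)`
#' (round half up).
#'
#' For dense graphs (non-edges under 10% of all pairs) negatives are drawn
#' by explicit enumeration of the non-edges; otherwise by batched rejection
#' sampling. Both are uniform without replacement and deterministic under
#' `seed`.
#'
#' @param g A connected `igraph` graph (typically the output of
#'   [largest_connected_component()]).
#' @param removal_fraction Fraction of edges to remove, in (0, 1).
#'   Default 0.25.
#' @param seed Integer seed.
#' @param min_positives Minimum admissible positive count (default 1);
#'   benchmark evaluation raises this to 10 to exclude graphs with too few
#'   edges to predict.
#' @return A list with elements `residual` (an `igraph` graph) and
#'   `dataset` (a `labeled_edge_set`).
#' @export
make_split <- function(g, removal_fraction = 0.25, seed = 1L, min_positives = 1L) {
  stopifnot(removal_fraction > 0, removal_fraction < 1)
  if (!igraph::is_connected(g)) stop("make_split expects a connected graph; extract the largest component first")
  m <- igraph::ecount(g)
  n <- igraph::vcount(g)
  npos <- floor(removal_fraction * m + 0.5)
  if (npos < max(1L, min_positives)) {
    stop("insufficient number of edges to predict: ", npos,
         " positives from ", m, " edges (need at least ", max(1L, min_positives), ")")
  }
  total_pairs <- n * (n - 1) / 2
  avail <- total_pairs - m
  if (avail < npos) {
    stop("graph too dense to sample negatives: need ", npos,
         " non-edges but only ", avail, " available")
  }
  names <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = FALSE) # 1-based indices
  a <- el[, 1] - 1L; b <- el[, 2] - 1L
  edge_keys <- pair_key(a, b, n)

  withr::with_seed(as.integer(seed), {
    pos_idx <- sample.int(m, npos)
    neg_keys <- if (avail / total_pairs < 0.1) {
      all_lo <- rep.int(0:(n - 2L), times = (n - 1L):1L)
      all_hi <- sequence((n - 1L):1L, from = 1:(n - 1L))
      all_keys <- pair_key(all_lo, all_hi, n)
      non_edge <- all_keys[!(all_keys %in% edge_keys)]
      sample(non_edge, npos)
    } else {
      got <- numeric(0)
      while (length(got) < npos) {
        cand_a <- sample.int(n, 2L * npos, replace = TRUE) - 1L
        cand_b <- sample.int(n, 2L * npos, replace = TRUE) - 1L
        ok <- cand_a != cand_b
        keys <- pair_key(cand_a[ok], cand_b[ok], n)
        keys <- keys[!(keys %in% edge_keys)]
        got <- unique(c(got, keys))
      }
      got[seq_len(npos)]
    }
  })

  pos_u <- a[pos_idx]; pos_v <- b[pos_idx]
  neg_u <- floor(neg_keys / n); neg_v <- neg_keys - neg_u * n
  dataset <- new_labeled_edge_set(
    u = names[c(pos_u, neg_u) + 1L],
    v = names[c(pos_v, neg_v) + 1L],
    label = rep(c(1L, 0L), c(npos, npos)))
  residual <- igraph::delete_edges(g, pos_idx)
  list(residual = residual, dataset = dataset)
}
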