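#' Read a graph from an edge-list or GraphML file
#'
#' Edge-list files contain one node pair per line, separated by whitespace
#' or a comma; `#`-prefixed lines are ignored. Duplicate edges are
#' collapsed, self-loops dropped (with a message reporting the count), and
#' node labels are mapped to consecutive internal integer identifiers
#' `"0" .. "n-1"` in order of first appearance; the original labels are
#' retained in the vertex attribute `label` and in the graph attribute
#' `label_map` (a data frame with columns `label`, `id`).
#'
#' @param path Path to the file.
#' @param format `"edgelist"` (default) or `"graphml"`.
#' @return An undirected simple `igraph` graph.
#' @export
read_graph_file <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
    labels <- if ("name" %in% igraph::vertex_attr_names(g))
      igraph::V(g)$name else as.character(seq_len(igraph::vcount(g)) - 1L)
    ids <- as.character(seq_along(labels) - 1L)
    g <- igraph::set_vertex_attr(g, "label", value = labels)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    return(igraph::set_graph_attr(g, "label_map",
      data.frame(label = labels, id = ids, stringsAsFactors = FALSE)))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  toks <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", lineno[bad[1]], " in ", path, ": '",
         lines[bad[1]], "' (expected two node labels)")
  }
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  loops <- u == v
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s) while reading ", basename(path))
    u <- u[!loops]
    v <- v[!loops]
  }
  if (length(u) == 0L) stop("no edges left after self-loop removal: ", path)
  labels <- unique(c(rbind(u, v)))
  id_of <- stats::setNames(as.character(seq_along(labels) - 1L), labels)
  # collapse duplicates under unordered comparison
  a <- id_of[u]; b <- id_of[v]
  key <- ifelse(as.integer(a) < as.integer(b), paste(a, b), paste(b, a))
  first <- !duplicated(key)
  el <- cbind(a[first], b[first])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "label",
    value = labels[match(igraph::V(g)$name, id_of)])
  igraph::set_graph_attr(g, "label_map",
    data.frame(label = labels, id = unname(id_of), stringsAsFactors = FALSE))
}

#' Write a graph to an edge-list or GraphML file
#'
#' @param g An `igraph` graph.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    writeLines(paste(el[, 1], el[, 2]), path)
  }
  invisible(path)
}

#' Write a walk corpus as plain text
#'
#' One walk per line, space-separated node tokens, the "sentence" format
#' consumed by the embedding stage.
#'
#' @param corpus A `walk_corpus` from [generate_walks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "walk_corpus"))
  lines <- vapply(corpus$walks, function(w) paste(corpus$nodes[w], collapse = " "), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a walk corpus from plain text
#'
#' Inverse of [write_corpus()] (the provenance of the original corpus is
#' not recoverable from the text file).
#'
#' @param path Path to a corpus file.
#' @return A `walk_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(lines, " ", fixed = TRUE)
  nodes <- unique(unlist(toks, use.names = FALSE))
  idx <- lapply(toks, function(tk) match(tk, nodes))
  structure(list(walks = idx, nodes = nodes, config = NULL, graph_id = NA_character_),
            class = "walk_corpus")
}

#' Write node embeddings in word-vector text format
#'
#' Standard format: a header line `"<count> <dimension>"` followed by one
#' line per node, `token v1 ... vd`. Values are printed with 9 significant
#' digits and round-trip within that precision.
#'
#' @param emb A `node_embedding` from [train_embeddings()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "node_embedding"))
  m <- emb$vectors
  if (nrow(m) == 0L) stop("cannot export an empty embedding")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i], paste(sprintf("%.9g", m[i, ]), collapse = " "))
  }, "")
  writeLines(c(paste(nrow(m), ncol(m)), rows), path)
  invisible(path)
}

#' Read node embeddings from word-vector text format
#'
#' @param path Path to a file written by [export_embeddings()].
#' @return A `node_embedding`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr))) stop("malformed embedding header: ", lines[1])
  toks <- strsplit(lines[-1], " ", fixed = TRUE)
  if (length(toks) != hdr[1]) stop("embedding row count does not match header")
  m <- t(vapply(toks, function(tk) as.numeric(tk[-1]), numeric(hdr[2])))
  rownames(m) <- vapply(toks, `[`, "", 1L)
  structure(list(vectors = m, epoch_loss = NULL, config = NULL),
            class = "node_embedding")
}

#' Write a labeled edge set as CSV
#'
#' Columns `u`, `v`, `label` (1 = removed true edge, 0 = sampled non-edge).
#'
#' @param dataset A `labeled_edge_set` from [make_split()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labeled_edges <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_edge_set"))
  utils::write.csv(as.data.frame(unclass(dataset))[c("u", "v", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled edge set from CSV
#'
#' @param path Path to a file written by [write_labeled_edges()].
#' @return A `labeled_edge_set`.
#' @export
read_labeled_edges <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character", "integer"))
  new_labeled_edge_set(df$u, df$v, df$label)
}
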