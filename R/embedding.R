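#' Configuration of the skip-gram embedding model
#'
#' Skip-gram with negative sampling (SGNS): for every center token the
#' model predicts context tokens within a window, contrasting each true
#' context against `negative` noise tokens drawn from the unigram
#' distribution raised to 3/4. Context width per center is downsampled
#' uniformly in `1..window`, so distant tokens are sampled less often. The
#' learning rate decays linearly over all epochs to 1e-4 of its initial
#' value. Training is single-worker and deterministic under the seed. No
#' minimum-frequency cutoff is applied: every corpus token is embedded.
#'
#' @param dimension Embedding dimension `d` (default 128).
#' @param window Context window `c` (default 10).
#' @param negative Noise tokens `k` per context pair (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param learning_rate Initial SGD learning rate (default 0.025).
#' @param seed Integer seed.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(dimension = 128L, window = 10L, negative = 5L,
                             epochs = 5L, learning_rate = 0.025, seed = 1L) {
  dimension <- as.integer(dimension); window <- as.integer(window)
  negative <- as.integer(negative); epochs <- as.integer(epochs)
  stopifnot(dimension >= 2L, window >= 1L, negative >= 1L, epochs >= 1L,
            learning_rate > 0)
  structure(list(dimension = dimension, window = window, negative = negative,
                 epochs = epochs, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Train node embeddings on a walk corpus
#'
#' Optimizes the skip-gram objective with the negative-sampling surrogate
#' over the walk "sentences". Every node occurring in the corpus receives
#' one input vector of length `dimension`; the per-epoch mean
#' negative-sampling loss (estimated on a fixed 1/16 subsample of context
#' pairs) is recorded in `$epoch_loss`.
#'
#' @param corpus A `walk_corpus` from [generate_walks()] or
#'   [read_corpus()].
#' @param config An [embedding_config()].
#' @return A `node_embedding`: list with `vectors` (matrix, one named row
#'   per node), `epoch_loss`, and `config`.
#' @export
train_embeddings <- function(corpus, config = embedding_config()) {
  stopifnot(inherits(corpus, "walk_corpus"), inherits(config, "embedding_config"))
  if (length(corpus$walks) == 0L) stop("empty corpus")
  present <- sort(unique(unlist(corpus$walks, use.names = FALSE)))
  if (length(present) < 2L) stop("corpus vocabulary has fewer than 2 nodes")
  vocab <- corpus$nodes[present]
  if (config$dimension >= length(vocab)) {
    message("embedding dimension (", config$dimension,
            ") is at least the vocabulary size (", length(vocab), ")")
  }
  remap <- integer(length(corpus$nodes))
  remap[present] <- seq_along(present) - 1L
  sents <- lapply(corpus$walks, function(w) remap[w])
  fit <- withr::with_seed(config$seed,
    cpp_sgns_train(sents, length(vocab), config$dimension, config$window,
                   config$negative, config$epochs, config$learning_rate))
  m <- fit$vectors
  rownames(m) <- vocab
  if (!all(is.finite(m))) stop("training produced non-finite vectors")
  structure(list(vectors = m, epoch_loss = as.numeric(fit$epoch_loss),
                 config = config),
            class = "node_embedding")
}

#' @export
print.node_embedding <- function(x, ...) {
  cat("<node_embedding> ", nrow(x$vectors), " nodes x ", ncol(x$vectors),
      " dims\n", sep = "")
  invisible(x)
}

#' Extract the vector of one node
#'
#' @param emb A `node_embedding`.
#' @param node Node name (character token).
#' @return Numeric vector of length `dimension`.
#' @export
embedding_vector <- function(emb, node) {
  stopifnot(inherits(emb, "node_embedding"))
  if (!node %in% rownames(emb$vectors)) stop("node not in vocabulary: ", node)
  emb$vectors[node, ]
}
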