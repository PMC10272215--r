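#' Train node embeddings with a node-type-aware skip-gram
#'
#' Learns a vector per node from the walk corpus with skip-gram and negative
#' sampling. The heterogeneous twist: negative samples for a (center,
#' context) pair are drawn from the unigram distribution (raised to the
#' usual 3/4 power) restricted to nodes of the *context* node's type, so
#' that, e.g., a drug context competes only against other drugs. Training is
#' single-threaded and fully deterministic under `seed`.
#'
#' @param corpus a [sample_walks()] corpus.
#' @param node_types named character vector typing every corpus node.
#' @param dim embedding dimension (default 128).
#' @param window maximum distance between center and predicted node
#'   (default 4).
#' @param negatives negative samples per positive pair (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param alpha initial learning rate, decayed linearly.
#' @param seed integer seed.
#' @return Object of class `"semwalk_emb"`: list with `vectors` (matrix,
#'   rownames = node ids), `node_type`, `dim`, and `unembedded` (nodes typed
#'   in `node_types` but absent from the corpus, which therefore got no
#'   vector).
#' @export
train_embeddings <- function(corpus, node_types, dim = 128, window = 4,
                             negatives = 5, epochs = 5, alpha = 0.025,
                             seed = 1) {
  stopifnot(window >= 1, dim >= 1, epochs >= 1, negatives >= 0)
  if (length(corpus$walks) == 0) stop("empty corpus")
  vocab <- sort(unique(unlist(corpus$walks, use.names = FALSE)))
  untyped <- setdiff(vocab, names(node_types))
  if (length(untyped) > 0) {
    stop(sprintf("corpus node '%s' has no node type", untyped[1]))
  }
  types <- unname(node_types[vocab])
  type_levels <- sort(unique(types))
  if (negatives > 0) {
    small <- type_levels[table(factor(types, levels = type_levels)) < 2]
    if (length(small) > 0) {
      stop(sprintf("negative pool too small: node type '%s' has a single node in the corpus",
                   small[1]))
    }
  }
  wlen <- max(lengths(corpus$walks))
  wm <- matrix(-1L, nrow = length(corpus$walks), ncol = wlen)
  vid <- stats::setNames(seq_along(vocab) - 1L, vocab)
  for (k in seq_along(corpus$walks)) {
    w <- corpus$walks[[k]]
    if (length(w) > 0) wm[k, seq_along(w)] <- vid[w]
  }
  mat <- .cpp_train_sgns(wm, as.integer(match(types, type_levels) - 1L),
                         length(vocab), as.integer(dim), as.integer(window),
                         as.integer(negatives), as.integer(epochs),
                         alpha, as.double(seed))
  rownames(mat) <- vocab
  if (any(!is.finite(mat))) stop("non-finite embedding values")
  structure(list(vectors = mat,
                 node_type = stats::setNames(types, vocab),
                 dim = as.integer(dim),
                 unembedded = setdiff(names(node_types), vocab)),
            class = "semwalk_emb")
}

#' @export
print.semwalk_emb <- function(x, ...) {
  tt <- table(x$node_type)
  cat(sprintf("Embedding space: %d nodes x %d dims (%s)\n",
              nrow(x$vectors), x$dim,
              paste(sprintf("%s: %d", names(tt), as.integer(tt)), collapse = ", ")))
  if (length(x$unembedded) > 0) {
    cat(sprintf("  %d typed nodes absent from the corpus (no vector)\n",
                length(x$unembedded)))
  }
  invisible(x)
}

#' Euclidean distance between two embedded nodes
#'
#' @param e an embedding space.
#' @param u,v node ids present in `e`.
#' @return nonnegative distance; symmetric in `u`, `v`.
#' @export
embedding_distance <- function(e, u, v) {
  for (id in c(u, v)) {
    if (!id %in% rownames(e$vectors)) {
      stop(sprintf("node '%s' is not embedded", id))
    }
  }
  sqrt(sum((e$vectors[u, ] - e$vectors[v, ])^2))
}

#' Read / write an embedding space as TSV
#'
#' One row per node: node_id, node_type, then `dim` floats at full double
#' precision (the round trip is lossless).
#'
#' @param e an embedding space; `path` a TSV path.
#' @export
write_embeddings <- function(e, path) {
  df <- data.frame(node_id = rownames(e$vectors),
                   node_type = unname(e$node_type[rownames(e$vectors)]),
                   stringsAsFactors = FALSE)
  vec_cols <- apply(e$vectors, 2, function(col) {
    sprintf("%.17g", col)
  })
  out <- cbind(df, vec_cols)
  write_tsv_commented(out, path,
                      c("node_id", "node_type", paste0("v", seq_len(e$dim))))
  invisible(e)
}

#' @rdname write_embeddings
#' @param path TSV path.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  types <- vapply(parts, `[[`, "", 2)
  dim <- length(parts[[1]]) - 2L
  mat <- t(vapply(parts, function(p) as.numeric(p[-(1:2)]), numeric(dim)))
  rownames(mat) <- ids
  structure(list(vectors = mat,
                 node_type = stats::setNames(types, ids),
                 dim = dim, unembedded = character(0)),
            class = "semwalk_emb")
}
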