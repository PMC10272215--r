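#' Construct a typed, weighted, undirected knowledge graph
#'
#' The knowledge graph is the walk substrate: a set of typed nodes (drug,
#' gene, disease, pathway, ...) joined by typed, weighted, undirected edges.
#' The node types `"drug"` and `"disease"` are reserved: only nodes of these
#' types are eligible for the semantic teleport operation during walks.
#'
#' Edges are stored undirected: input rows are de-duplicated as unordered
#' endpoint pairs per edge type, and every stored edge is traversable in both
#' directions. Parallel edges between the same endpoints are allowed when
#' their edge types differ.
#'
#' @param edges data.frame with columns `source`, `target`, `edge_type` and
#'   optionally `weight` (missing weights default to 1).
#' @param node_types named character vector, or data.frame with columns
#'   `node_id` and `node_type`, typing every node referenced by `edges`.
#' @return An object of class `"semwalk_kg"`: a list with elements `nodes`
#'   (character), `node_type` (named character), `edges` (data.frame with
#'   columns source, target, edge_type, weight) and `edge_types` (character).
#' @examples
#' g <- knowledge_graph(
#'   data.frame(source = c("D1", "G1"), target = c("G1", "Z1"),
#'              edge_type = c("drug_target", "disease_gene")),
#'   c(D1 = "drug", G1 = "gene", Z1 = "disease"))
#' g
#' @export
knowledge_graph <- function(edges, node_types) {
  if (is.data.frame(node_types)) {
    nt <- as.character(node_types[[2]])
    names(nt) <- as.character(node_types[[1]])
    node_types <- nt
  }
  if (anyDuplicated(names(node_types))) {
    dup <- names(node_types)[duplicated(names(node_types))][1]
    stop(sprintf("node '%s' is typed more than once", dup))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "edge_type") %in% names(edges))) {
    stop("edges must have columns source, target, edge_type")
  }
  if (is.null(edges$weight)) edges$weight <- 1.0
  edges$weight[is.na(edges$weight)] <- 1.0
  if (!is.numeric(edges$weight)) {
    bad <- which(is.na(suppressWarnings(as.numeric(edges$weight))))[1]
    stop(sprintf("non-numeric edge weight at row %d", bad))
  }
  if (any(edges$weight < 0)) {
    stop(sprintf("negative edge weight at row %d", which(edges$weight < 0)[1]))
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$edge_type <- as.character(edges$edge_type)

  referenced <- unique(c(edges$source, edges$target))
  untyped <- setdiff(referenced, names(node_types))
  if (length(untyped) > 0) {
    stop(sprintf("edge references untyped node '%s' (not in node-type table)",
                 untyped[1]))
  }
  # undirected de-duplication: unordered endpoints x edge_type
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  key <- paste(a, b, edges$edge_type, sep = "\r")
  keep <- !duplicated(key)
  edges <- edges[keep, , drop = FALSE]
  edges$source <- a[keep]
  edges$target <- b[keep]
  rownames(edges) <- NULL

  structure(list(
    nodes = names(node_types),
    node_type = node_types,
    edges = edges[, c("source", "target", "edge_type", "weight")],
    edge_types = sort(unique(edges$edge_type))
  ), class = "semwalk_kg")
}

#' @export
print.semwalk_kg <- function(x, ...) {
  tt <- table(x$node_type)
  cat(sprintf("Knowledge graph: %d nodes (%s), %d undirected edges\n",
              length(x$nodes),
              paste(sprintf("%s: %d", names(tt), as.integer(tt)), collapse = ", "),
              nrow(x$edges)))
  et <- table(x$edges$edge_type)
  cat("Edge types:", paste(sprintf("%s (%d)", names(et), as.integer(et)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Read a knowledge graph from TSV files
#'
#' @param edge_file TSV with columns source, target, edge_type and an
#'   optional weight column; lines starting with `#` are ignored.
#' @param node_type_file TSV with columns node_id, node_type.
#' @return A [knowledge_graph()] object.
#' @export
read_graph <- function(edge_file, node_type_file) {
  lines <- readLines(edge_file)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) stop(sprintf("no edges in '%s'", edge_file))
  parts <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3)) {
    stop(sprintf("row %d of '%s' has fewer than 3 columns",
                 which(ncols < 3)[1], edge_file))
  }
  src <- vapply(parts, `[[`, "", 1)
  tgt <- vapply(parts, `[[`, "", 2)
  ety <- vapply(parts, `[[`, "", 3)
  w <- rep(1.0, length(parts))
  has_w <- ncols >= 4
  if (any(has_w)) {
    raw <- vapply(parts[has_w], `[[`, "", 4)
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) {
      stop(sprintf("non-numeric weight '%s' at row %d of '%s'",
                   raw[is.na(num)][1], which(has_w)[is.na(num)][1], edge_file))
    }
    if (any(num < 0)) {
      stop(sprintf("negative weight at row %d of '%s'",
                   which(has_w)[num < 0][1], edge_file))
    }
    w[has_w] <- num
  }
  nt <- read_tsv_commented(node_type_file, c("node_id", "node_type"),
                           colClasses = "character")
  knowledge_graph(
    data.frame(source = src, target = tgt, edge_type = ety, weight = w,
               stringsAsFactors = FALSE),
    nt)
}

#' Write a knowledge graph to TSV files
#'
#' Inverse of [read_graph()]; the round trip is lossless on the node set,
#' node types, edge multiset and weights.
#'
#' @param g a knowledge graph.
#' @param edge_file,node_type_file output paths.
#' @export
write_graph <- function(g, edge_file, node_type_file) {
  write_tsv_commented(g$edges, edge_file,
                      c("source", "target", "edge_type", "weight"))
  write_tsv_commented(
    data.frame(node_id = g$nodes, node_type = unname(g$node_type[g$nodes]),
               stringsAsFactors = FALSE),
    node_type_file, c("node_id", "node_type"))
  invisible(g)
}

#' Remove all edges of one type
#'
#' Used to strip drug-disease treatment edges before embedding, so that node
#' representations are learned from molecular and semantic context alone and
#' the treatment labels remain untouched for the downstream prediction task.
#' Nodes are never removed: entities isolated by the removal still receive
#' embeddings through teleport, or are reported as unreachable by the walker.
#'
#' @param g a knowledge graph.
#' @param edge_type an edge type present in `g`.
#' @return The graph without edges of that type; node set and types unchanged.
#' @export
remove_edges_by_type <- function(g, edge_type) {
  declared <- c(g$edge_types, g$removed_edge_types)
  if (!edge_type %in% declared) {
    stop(sprintf("edge type '%s' not present in graph", edge_type))
  }
  g$edges <- g$edges[g$edges$edge_type != edge_type, , drop = FALSE]
  rownames(g$edges) <- NULL
  g$edge_types <- sort(unique(g$edges$edge_type))
  # remember removed types so the operation is idempotent
  g$removed_edge_types <- sort(unique(c(g$removed_edge_types, edge_type)))
  g
}

#' Read / write labeled drug-disease pairs
#'
#' Treatment labels for the association-prediction task: TSV with columns
#' drug, disease, label (1 = known treatment, 0 = negative).
#'
#' @param path TSV path.
#' @return data.frame with columns drug, disease, label (integer).
#' @export
read_pairs <- function(path) {
  df <- read_tsv_commented(path, c("drug", "disease", "label"),
                           colClasses = c("character", "character", "integer"))
  df$label <- as.integer(df$label)
  if (anyDuplicated(paste(df$drug, df$disease, sep = "\r"))) {
    stop("duplicate (drug, disease) entry in pair file")
  }
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  df
}

#' @rdname read_pairs
#' @param pairs data.frame with columns drug, disease, label.
#' @export
write_pairs <- function(pairs, path) {
  write_tsv_commented(pairs[, c("drug", "disease", "label")], path,
                      c("drug", "disease", "label"))
  invisible(pairs)
}

# ---- internal indexed view used by the samplers -------------------------

# Compact 0-based CSR adjacency over both edge directions, with entries
# sorted by neighbour index inside each block (binary-searchable), plus the
# edge-type codes the transition matrix indexes.
kg_index <- function(g) {
  n <- length(g$nodes)
  id <- seq_len(n) - 1L
  names(id) <- g$nodes
  et_levels <- g$edge_types
  e <- g$edges
  if (nrow(e) > 0) {
    ui <- id[e$source]; vi <- id[e$target]
    ti <- match(e$edge_type, et_levels) - 1L
    from <- c(ui, vi); to <- c(vi, ui)
    ty <- c(ti, ti); w <- c(e$weight, e$weight)
    ord <- order(from, to, ty)
    from <- from[ord]; to <- to[ord]; ty <- ty[ord]; w <- w[ord]
    ptr <- c(0L, cumsum(tabulate(from + 1L, nbins = n)))
  } else {
    from <- to <- ty <- integer(0); w <- numeric(0)
    ptr <- rep(0L, n + 1L)
  }
  list(n = n, id = id, nodes = g$nodes,
       node_type = unname(g$node_type[g$nodes]),
       edge_types = et_levels,
       adj_ptr = as.integer(ptr), adj_nbr = as.integer(to),
       adj_et = as.integer(ty), adj_w = as.numeric(w))
}
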