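#' Information content of an ontology term
#'
#' The information content (IC) of a term measures its specificity within
#' the hierarchy: the root carries no information (IC = 0) while leaves are
#' maximally specific (IC = 1). With `N(c)` the number of terms subsumed by
#' `c` (its transitive descendants), the score is
#'
#'   IC(c) = 1 - log(N(c) + 1) / log(N(root) + 1)
#'
#' The `+1` in the denominator makes the bounds exact: IC(root) = 0 and
#' IC(leaf) = 1, for any log base (the ratio is base-invariant; natural logs
#' are used). `method = "children"` swaps the descendant count for the
#' direct-children count, for sensitivity analysis only — that variant is
#' not monotone along root-to-leaf paths.
#'
#' @param h an [ontology()].
#' @param term a term identifier present in `h`.
#' @param method `"descendants"` (default) or `"children"`.
#' @return IC value in \[0, 1\].
#' @export
compute_ic <- function(h, term, method = c("descendants", "children")) {
  method <- match.arg(method)
  if (!term %in% h$terms) stop(sprintf("unknown term '%s'", term))
  if (length(h$terms) < 2) stop("degenerate hierarchy: a single term has no informative structure")
  counts <- if (method == "descendants") h$n_descendants else count_children(h)
  n_root <- counts[[h$root]]
  if (n_root < 1) stop("degenerate hierarchy: root subsumes no terms")
  1 - log(counts[[term]] + 1) / log(n_root + 1)
}

# IC for every term at once (internal, avoids repeated lookups)
ic_table <- function(h, method = "descendants") {
  counts <- if (method == "descendants") h$n_descendants else count_children(h)
  n_root <- counts[[h$root]]
  if (length(h$terms) < 2 || n_root < 1) stop("degenerate hierarchy")
  stats::setNames(1 - log(counts + 1) / log(n_root + 1), names(counts))
}

#' Semantic distance and similarity between two terms
#'
#' Distance between terms is measured through their most informative common
#' ancestor (MICA), the shared ancestor with maximal information content
#' (a term counts as its own ancestor, so when one term subsumes the other
#' the MICA is the subsumer):
#'
#'   dist(c1, c2) = IC(c1) + IC(c2) - 2 * IC(MICA(c1, c2))
#'
#' Since IC is bounded by 1 the distance is bounded by 2, attained by two
#' leaves whose only common ancestor is the root. Similarity rescales the
#' distance to \[0, 1\]:
#'
#'   sim(c1, c2) = 1 - dist(c1, c2) / 2
#'
#' so sim(c, c) = 1 and two terms related only through the root have
#' similarity 0.
#'
#' @param h an [ontology()].
#' @param c1,c2 term identifiers.
#' @return `semantic_distance`: value in \[0, 2\]; `semantic_similarity`:
#'   value in \[0, 1\].
#' @export
semantic_distance <- function(h, c1, c2) {
  ic <- ic_table(h)
  semantic_distance_ic(h, c1, c2, ic)
}

semantic_distance_ic <- function(h, c1, c2, ic) {
  for (tm in c(c1, c2)) {
    if (!tm %in% h$terms) stop(sprintf("unknown term '%s'", tm))
  }
  common <- intersect(term_ancestors(h, c1), term_ancestors(h, c2))
  if (length(common) == 0) {
    stop(sprintf("terms '%s' and '%s' share no common ancestor", c1, c2))
  }
  mica <- max(ic[common])
  unname(ic[[c1]] + ic[[c2]] - 2 * mica)
}

#' @rdname semantic_distance
#' @export
semantic_similarity <- function(h, c1, c2) {
  1 - semantic_distance(h, c1, c2) / 2
}

#' Build the per-type teleport similarity matrix
#'
#' Computes ontology-based semantic similarity for every unordered pair of
#' graph nodes of one type (drug or disease), keeps pairs above a cutoff,
#' and returns the sparse matrix that drives the teleport operation: when a
#' walker at node `v` teleports, the landing node is drawn proportionally to
#' `v`'s row of this matrix.
#'
#' Entities mapped to several terms (multiple ATC codes, say) are compared
#' by the maximum over term-pair similarities (most specific shared role);
#' `combine = "mean"` averages instead. Entries at or below `cutoff` are
#' dropped — the default 0.4 suppresses weak, noisy relations. Nodes without
#' a mapping simply get no entries.
#'
#' @param g a [knowledge_graph()].
#' @param h an [ontology()] whose entity map covers nodes of `node_type`.
#' @param node_type the node type to compare, typically `"drug"` or
#'   `"disease"`.
#' @param cutoff similarity mask threshold in \[0, 1); default 0.4.
#' @param combine multi-term combination rule, `"max"` (default) or `"mean"`.
#' @return Object of class `"semwalk_sim"`: list with `entity_ids`,
#'   `entries` (data.frame a, b, sim; a < b lexicographically), `cutoff`,
#'   `node_type`.
#' @export
build_similarity_matrix <- function(g, h, node_type, cutoff = 0.4,
                                    combine = c("max", "mean")) {
  combine <- match.arg(combine)
  stopifnot(cutoff >= 0, cutoff < 1)
  ids <- g$nodes[g$node_type[g$nodes] == node_type]
  mapped <- ids[ids %in% names(h$entity_map)]
  if (length(mapped) == 0) {
    stop(sprintf("no nodes of type '%s' have an ontology mapping", node_type))
  }
  ic <- ic_table(h)
  used_terms <- unique(unlist(h$entity_map[mapped], use.names = FALSE))
  # pairwise term similarity over the terms actually used
  k <- length(used_terms)
  tsim <- matrix(1, k, k, dimnames = list(used_terms, used_terms))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- semantic_distance_ic(h, used_terms[i], used_terms[j], ic)
        tsim[i, j] <- tsim[j, i] <- 1 - d / 2
      }
    }
  }
  res_a <- character(0); res_b <- character(0); res_s <- numeric(0)
  nm <- length(mapped)
  if (nm > 1) {
    for (i in seq_len(nm - 1)) {
      ti <- h$entity_map[[mapped[i]]]
      for (j in (i + 1):nm) {
        tj <- h$entity_map[[mapped[j]]]
        block <- tsim[ti, tj, drop = FALSE]
        s <- if (combine == "max") max(block) else mean(block)
        if (s > cutoff) {
          res_a <- c(res_a, mapped[i]); res_b <- c(res_b, mapped[j])
          res_s <- c(res_s, s)
        }
      }
    }
  }
  a <- pmin(res_a, res_b); b <- pmax(res_a, res_b)
  structure(list(
    entity_ids = ids,
    entries = data.frame(a = a, b = b, sim = res_s, stringsAsFactors = FALSE),
    cutoff = cutoff, node_type = node_type, combine = combine
  ), class = "semwalk_sim")
}

#' @export
print.semwalk_sim <- function(x, ...) {
  cat(sprintf("Similarity matrix (%s): %d entities, %d pairs above cutoff %.2f\n",
              x$node_type, length(x$entity_ids), nrow(x$entries), x$cutoff))
  invisible(x)
}

# similarity row of one entity as a named numeric vector (internal)
sim_row <- function(s, id) {
  e <- s$entries
  hit <- e$a == id | e$b == id
  if (!any(hit)) return(stats::setNames(numeric(0), character(0)))
  other <- ifelse(e$a[hit] == id, e$b[hit], e$a[hit])
  stats::setNames(e$sim[hit], other)
}

#' Read / write a similarity matrix as TSV
#'
#' One row per stored unordered pair (entity_a, entity_b, similarity), with
#' header comments recording node type and cutoff.
#'
#' @param s a similarity matrix; `path` a TSV path.
#' @export
write_similarity <- function(s, path) {
  write_tsv_commented(
    s$entries, path, c("entity_a", "entity_b", "similarity"),
    extra_comments = c(sprintf("node_type=%s", s$node_type),
                       sprintf("cutoff=%g", s$cutoff),
                       sprintf("combine=%s", s$combine %||% "max")))
  invisible(s)
}

#' @rdname write_similarity
#' @param path TSV path.
#' @export
read_similarity <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  kv <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  df <- read_tsv_commented(path, c("a", "b", "sim"),
                           colClasses = c("character", "character", "numeric"))
  df$sim <- as.numeric(df$sim)
  structure(list(
    entity_ids = sort(unique(c(df$a, df$b))),
    entries = df,
    cutoff = as.numeric(kv("cutoff", "0")),
    node_type = kv("node_type", NA_character_),
    combine = kv("combine", "max")
  ), class = "semwalk_sim")
}
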