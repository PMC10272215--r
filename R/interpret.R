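#' Window-neighbor gene set of an entity
#'
#' For every occurrence of `entity` in the corpus, collects the nodes within
#' `l` positions on either side (clipped at walk bounds), keeps those typed
#' `"gene"`, and pools them with occurrence counts. The walk sequence is
#' used as text: teleport steps do not break the window. The resulting gene
#' set summarizes the molecular context the walker visits around the entity
#' and feeds the enrichment analysis.
#'
#' @param corpus a [sample_walks()] corpus.
#' @param entity node id occurring in at least one walk.
#' @param l window half-width in positions (2 for neighbourhood inspection,
#'   4 to match the skip-gram training window).
#' @param node_types named character vector node -> type.
#' @return list of class `"semwalk_neighbors"`: `entity`, `window`, `genes`
#'   (character), `occurrence_counts` (named integer).
#' @export
window_neighbors <- function(corpus, entity, l = 4, node_types) {
  stopifnot(l >= 1)
  counts <- integer(0)
  seen <- FALSE
  for (w in corpus$walks) {
    hits <- which(w == entity)
    if (length(hits) == 0) next
    seen <- TRUE
    for (i in hits) {
      lo <- max(1, i - l); hi <- min(length(w), i + l)
      nb <- w[lo:hi]
      nb <- nb[nb != entity]
      nb <- nb[node_types[nb] == "gene"]
      for (gn in nb) {
        counts[gn] <- (if (is.na(counts[gn])) 0L else counts[gn]) + 1L
      }
    }
  }
  if (!seen) stop(sprintf("entity '%s' does not occur in the corpus", entity))
  structure(list(entity = entity, window = as.integer(l),
                 genes = sort(names(counts)),
                 occurrence_counts = counts[sort(names(counts))]),
            class = "semwalk_neighbors")
}

#' @export
print.semwalk_neighbors <- function(x, ...) {
  cat(sprintf("Window neighbors of '%s' (l = %d): %d genes\n",
              x$entity, x$window, length(x$genes)))
  invisible(x)
}

#' Over-representation test of window-neighbor genes against gene sets
#'
#' One-sided Fisher's exact test per term on the 2x2 table (neighbor-and-
#' term, neighbor-not-term, term-not-neighbor, rest of universe), followed
#' by Benjamini-Hochberg correction across all tested terms. The gene ratio
#' is the overlap divided by the term's size.
#'
#' @param neighbors a [window_neighbors()] result (or character vector of
#'   genes).
#' @param gene_sets named list term -> character vector of genes.
#' @param universe character vector of all genes under consideration; must
#'   contain every gene in `gene_sets` and `neighbors`.
#' @return data.frame with columns term, overlap, term_size, gene_ratio, p,
#'   p_adj, sorted by p_adj then p.
#' @export
enrich <- function(neighbors, gene_sets, universe) {
  genes <- if (inherits(neighbors, "semwalk_neighbors")) neighbors$genes else neighbors
  genes <- unique(genes)
  if (length(genes) == 0) stop("nothing to test: empty neighbor set")
  out_of_u <- setdiff(c(genes, unlist(gene_sets, use.names = FALSE)), universe)
  if (length(out_of_u) > 0) {
    stop(sprintf("gene '%s' is outside the supplied universe", out_of_u[1]))
  }
  N <- length(unique(universe))
  res <- lapply(names(gene_sets), function(tm) {
    gs <- unique(gene_sets[[tm]])
    ov <- length(intersect(genes, gs))
    tab <- matrix(c(ov,
                    length(genes) - ov,
                    length(gs) - ov,
                    N - length(genes) - length(gs) + ov), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, overlap = ov, term_size = length(gs),
               gene_ratio = ov / length(gs), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p_adj, res$p, res$term), , drop = FALSE]
}

#' Read gene sets in GMT-style TSV
#'
#' One line per term: term, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list term -> character vector of genes.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1))
}

#' Z-score-normalized embedding distances
#'
#' Euclidean distances are comparable within one embedding space but not
#' across spaces trained on different walk corpora. Standardizing each
#' distance against the mean and standard deviation of *all* pairwise
#' distances in its own space yields a unit-less score comparable between
#' spaces. The normalization population is every unordered node pair in the
#' space by default; `population = "within_type"` restricts it to pairs of
#' the same node type.
#'
#' @param e an embedding space.
#' @param pairs data.frame (or 2-column matrix) of node id pairs to score.
#' @param population `"all"` (default) or `"within_type"`.
#' @return numeric vector of z-scores, one per requested pair.
#' @export
znorm_distances <- function(e, pairs, population = c("all", "within_type")) {
  population <- match.arg(population)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  u <- as.character(pairs[[1]]); v <- as.character(pairs[[2]])
  miss <- setdiff(c(u, v), rownames(e$vectors))
  if (length(miss) > 0) stop(sprintf("node '%s' is not embedded", miss[1]))
  D <- stats::dist(e$vectors)
  if (population == "all") {
    popd <- as.numeric(D)
  } else {
    Dm <- as.matrix(D)
    tt <- e$node_type[rownames(Dm)]
    same <- outer(tt, tt, "==")
    popd <- Dm[upper.tri(Dm) & same]
  }
  mu <- mean(popd); s <- stats::sd(popd)
  if (length(popd) < 2 || s <= 1e-10 * max(mu, 1)) {
    stop("degenerate space: all-pairwise distances have zero variance")
  }
  Dm <- as.matrix(D)
  (Dm[cbind(u, v)] - mu) / s
}

#' Compare pair distances between two embedding spaces
#'
#' Two-sided paired t-test on the z-score-normalized distances of a common
#' pair list between two spaces (e.g. teleport-guided vs non-teleported).
#' The reported `mean_difference` is `mean(z1 - z2)`: positive when the
#' pairs sit closer together in `e2`. P values below the double-precision
#' floor are reported as `"< 1e-308"` in `p_label`.
#'
#' @param e1,e2 embedding spaces covering all pairs.
#' @param pairs data.frame/matrix of node id pairs (at least 2).
#' @return list with `t`, `df`, `p`, `p_label`, `mean_difference`, `n`.
#' @export
compare_spaces <- function(e1, e2, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  z1 <- znorm_distances(e1, pairs)
  z2 <- znorm_distances(e2, pairs)
  d <- z1 - z2
  if (stats::sd(d) == 0) {
    # identical (or uniformly shifted by zero) spaces: no detectable difference
    return(list(t = NA_real_, df = length(d) - 1L,
                p = if (all(d == 0)) 1 else 0,
                p_label = if (all(d == 0)) "1" else "< 1e-308",
                mean_difference = mean(d), n = length(d)))
  }
  tt <- stats::t.test(z1, z2, paired = TRUE)
  p <- tt$p.value
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       p_label = if (p < 1e-308) "< 1e-308" else format(p),
       mean_difference = mean(d), n = length(d))
}
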