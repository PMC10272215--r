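#' Construct an ontology hierarchy with an entity-to-term mapping
#'
#' Hierarchies of the ATC/MeSH/Disease-Ontology kind are modelled as a DAG of
#' terms (child -> parent links) plus a mapping from graph entities (drugs or
#' diseases) to one or more terms. The DAG is validated on construction; a
#' hierarchy with several roots gets a virtual super-root (`"<ROOT>"`) so
#' that every pair of terms has at least one common ancestor, which keeps
#' information content and semantic distance defined for all pairs.
#'
#' @param parent_links data.frame with columns `child`, `parent`.
#' @param entity_map data.frame with columns `node_id`, `term`; entities may
#'   map to several terms.
#' @return An object of class `"semwalk_ontology"`: list with `terms`,
#'   `parent_links`, `entity_map` (named list node_id -> character terms),
#'   `root`, `virtual_root` (logical) and a cached descendant count per term.
#' @export
ontology <- function(parent_links, entity_map = NULL) {
  parent_links <- as.data.frame(parent_links, stringsAsFactors = FALSE)
  names(parent_links)[1:2] <- c("child", "parent")
  parent_links$child <- as.character(parent_links$child)
  parent_links$parent <- as.character(parent_links$parent)
  terms <- unique(c(parent_links$child, parent_links$parent))
  if (length(terms) == 0) stop("empty hierarchy")

  # child -> parent arcs; a DAG must contain no directed cycle
  ig <- igraph::graph_from_data_frame(parent_links, directed = TRUE,
                                      vertices = terms)
  if (!igraph::is_dag(ig)) {
    stop(sprintf("hierarchy contains a cycle: %s",
                 paste(find_one_cycle(parent_links), collapse = " -> ")))
  }
  roots <- terms[!(terms %in% parent_links$child)]
  virtual_root <- FALSE
  if (length(roots) == 0) stop("hierarchy has no root")
  if (length(roots) > 1) {
    parent_links <- rbind(parent_links,
                          data.frame(child = roots, parent = "<ROOT>",
                                     stringsAsFactors = FALSE))
    terms <- c(terms, "<ROOT>")
    roots <- "<ROOT>"
    virtual_root <- TRUE
  }

  em <- list()
  if (!is.null(entity_map) && NROW(entity_map) > 0) {
    entity_map <- as.data.frame(entity_map, stringsAsFactors = FALSE)
    names(entity_map)[1:2] <- c("node_id", "term")
    unknown <- setdiff(unique(entity_map$term), terms)
    if (length(unknown) > 0) {
      stop(sprintf("entity mapped to unknown term '%s'", unknown[1]))
    }
    em <- lapply(split(as.character(entity_map$term),
                       as.character(entity_map$node_id)), unique)
  }

  h <- structure(list(terms = terms, parent_links = parent_links,
                      entity_map = em, root = roots,
                      virtual_root = virtual_root),
                 class = "semwalk_ontology")
  h$n_descendants <- count_descendants(h)
  ig2 <- igraph::graph_from_data_frame(h$parent_links, directed = TRUE,
                                       vertices = h$terms)
  h$ancestors <- lapply(stats::setNames(h$terms, h$terms), function(t) {
    names(igraph::subcomponent(ig2, t, mode = "out"))
  })
  h
}

# depth-first search for one directed cycle in child -> parent links
find_one_cycle <- function(links) {
  adj <- split(links$parent, links$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = state, ifnotfound = list(NULL))[[1]]
    if (identical(st, "active")) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (identical(st, "done")) return()
    assign(v, "active", envir = state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character(0)) visit(w)
    path <<- path[-length(path)]
    assign(v, "done", envir = state)
  }
  for (v in unique(links$child)) {
    visit(v)
    if (!is.null(found)) break
  }
  found %||% "(unlocated)"
}

#' @export
print.semwalk_ontology <- function(x, ...) {
  cat(sprintf("Ontology hierarchy: %d terms, %d links, root '%s'%s; %d mapped entities\n",
              length(x$terms), nrow(x$parent_links), x$root,
              if (x$virtual_root) " (virtual)" else "",
              length(x$entity_map)))
  invisible(x)
}

# transitive descendant count per term (the term itself excluded)
count_descendants <- function(h) {
  ig <- igraph::graph_from_data_frame(h$parent_links, directed = TRUE,
                                      vertices = h$terms)
  # arcs run child -> parent, so descendants are reached via mode = "in"
  n <- vapply(h$terms, function(t) {
    length(igraph::subcomponent(ig, t, mode = "in")) - 1L
  }, integer(1))
  names(n) <- h$terms
  n
}

# direct-children count per term
count_children <- function(h) {
  tab <- table(factor(h$parent_links$parent, levels = h$terms))
  stats::setNames(as.integer(tab), h$terms)
}

# ancestor set of a term, including the term itself
term_ancestors <- function(h, term) h$ancestors[[term]]

#' Read an ontology hierarchy from TSV files
#'
#' @param term_file TSV with columns child_term, parent_term.
#' @param mapping_file optional TSV with columns node_id, term_id.
#' @return An [ontology()] object.
#' @export
read_hierarchy <- function(term_file, mapping_file = NULL) {
  links <- read_tsv_commented(term_file, c("child", "parent"),
                              colClasses = "character")
  em <- NULL
  if (!is.null(mapping_file)) {
    em <- read_tsv_commented(mapping_file, c("node_id", "term"),
                             colClasses = "character")
  }
  ontology(links, em)
}

#' Write an ontology hierarchy to TSV files
#'
#' The virtual super-root, if one was added, is not written: the files
#' round-trip to the hierarchy as originally supplied.
#'
#' @param h an ontology.
#' @param term_file,mapping_file output paths (`mapping_file` optional).
#' @export
write_hierarchy <- function(h, term_file, mapping_file = NULL) {
  links <- h$parent_links
  if (h$virtual_root) links <- links[links$parent != "<ROOT>", , drop = FALSE]
  write_tsv_commented(links, term_file, c("child_term", "parent_term"))
  if (!is.null(mapping_file)) {
    df <- data.frame(
      node_id = rep(names(h$entity_map), lengths(h$entity_map)),
      term = unlist(h$entity_map, use.names = FALSE),
      stringsAsFactors = FALSE)
    write_tsv_commented(df, mapping_file, c("node_id", "term_id"))
  }
  invisible(h)
}
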