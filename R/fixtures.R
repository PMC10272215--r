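#' Specification of a synthetic planted-structure knowledge graph
#'
#' The generator emulates, at desk scale, the shape of real drug-gene-
#' disease-pathway knowledge graphs: genes dominate the node set (the
#' protein-interaction layer covers most nodes and edges), drugs act on a
#' handful of targets, diseases are annotated with a handful of genes, and
#' the drug/disease ontologies group entities that share biology. Structure
#' is planted through `n_modules` gene communities: protein-interaction
#' edges are dense within a module and sparse between modules, each drug
#' targets genes of a single module, each disease is associated with genes
#' of a single module, and a drug treats a disease exactly when their
#' modules match (`treatment_rule = "shared-module"`). Hierarchies are
#' depth-3 balanced trees whose leaf clusters coincide with the module
#' assignment, so semantic similarity correlates with shared indication by
#' construction.
#'
#' @param n_drugs,n_genes,n_diseases,n_pathways node counts per type.
#' @param n_modules planted gene communities.
#' @param ppi_density_in,ppi_density_out within/between-module gene-gene
#'   edge probabilities.
#' @param targets_per_drug,genes_per_disease structured degree of drugs and
#'   diseases into their module's genes.
#' @param semantic_groups hierarchy leaves per module subtree.
#' @param treatment_rule only `"shared-module"` is defined.
#' @param noise_edge_rate noise edges (edge type `"noise"`, random
#'   endpoints) as a fraction of the structured edge count.
#' @param heldout_frac fraction of true treatment pairs withheld from the
#'   labeled pair list, for recovery experiments.
#' @param seed integer seed; generation is fully reproducible.
#' @return list of class `"semwalk_fixture_spec"`.
#' @export
fixture_spec <- function(n_drugs = 40, n_genes = 200, n_diseases = 30,
                         n_pathways = 8, n_modules = 4,
                         ppi_density_in = 0.25, ppi_density_out = 0.02,
                         targets_per_drug = 3, genes_per_disease = 4,
                         semantic_groups = 4,
                         treatment_rule = "shared-module",
                         noise_edge_rate = 0.1, heldout_frac = 0.2,
                         seed = 1) {
  stopifnot(n_drugs > 0, n_genes > 0, n_diseases > 0, n_pathways >= 0,
            n_modules > 0,
            ppi_density_in >= 0, ppi_density_in <= 1,
            ppi_density_out >= 0, ppi_density_out <= 1,
            targets_per_drug > 0, genes_per_disease > 0,
            semantic_groups >= 1,
            noise_edge_rate >= 0, heldout_frac >= 0, heldout_frac < 1)
  if (treatment_rule != "shared-module") stop("unknown treatment_rule")
  if (n_modules > n_drugs || n_modules > n_diseases || n_modules > n_genes) {
    stop("inconsistent spec: more modules than drugs, diseases or genes")
  }
  if (targets_per_drug > floor(n_genes / n_modules) ||
      genes_per_disease > floor(n_genes / n_modules)) {
    stop("inconsistent spec: per-entity gene degree exceeds module size")
  }
  structure(as.list(environment()), class = "semwalk_fixture_spec")
}

#' Balanced term hierarchy
#'
#' Builds a balanced tree of the given depth and branching factor (root at
#' depth 0), useful as a minimal well-understood ontology.
#'
#' @param depth tree depth (number of levels below the root).
#' @param branching children per internal term.
#' @param prefix term-name prefix.
#' @param entity_map optional data.frame (node_id, term) mapping entities to
#'   terms.
#' @return an [ontology()].
#' @export
make_balanced_hierarchy <- function(depth = 3, branching = 2, prefix = "T",
                                    entity_map = NULL) {
  stopifnot(depth >= 1, branching >= 1)
  links <- list()
  level <- prefix
  for (d in seq_len(depth)) {
    children <- unlist(lapply(level, function(parent) {
      paste0(parent, ".", seq_len(branching))
    }))
    parents <- rep(level, each = branching)
    links[[d]] <- data.frame(child = children, parent = parents,
                             stringsAsFactors = FALSE)
    level <- children
  }
  ontology(do.call(rbind, links), entity_map)
}

# depth-3 hierarchy whose leaf clusters coincide with module assignment:
# root -> module terms -> 2 subgroups -> leaves (semantic_groups per module)
module_hierarchy <- function(prefix, entities, modules, n_modules,
                             semantic_groups) {
  links <- list()
  map <- list()
  root <- prefix
  for (m in seq_len(n_modules)) {
    mod_term <- sprintf("%s.m%d", prefix, m)
    links[[length(links) + 1]] <- data.frame(child = mod_term, parent = root)
    n_sub <- min(2L, semantic_groups)
    leaves <- character(0)
    for (s in seq_len(n_sub)) {
      sub_term <- sprintf("%s.s%d", mod_term, s)
      links[[length(links) + 1]] <- data.frame(child = sub_term,
                                               parent = mod_term)
      n_leaf <- ceiling(semantic_groups / n_sub)
      take <- if (s == n_sub) semantic_groups - n_leaf * (n_sub - 1) else n_leaf
      for (l in seq_len(take)) {
        leaf <- sprintf("%s.l%d", sub_term, l)
        links[[length(links) + 1]] <- data.frame(child = leaf,
                                                 parent = sub_term)
        leaves <- c(leaves, leaf)
      }
    }
    members <- entities[modules == m]
    if (length(members) > 0) {
      assigned <- leaves[((seq_along(members) - 1) %% length(leaves)) + 1]
      map[[m]] <- data.frame(node_id = members, term = assigned,
                             stringsAsFactors = FALSE)
    }
  }
  ontology(do.call(rbind, links), do.call(rbind, map))
}

#' Generate a seeded synthetic knowledge graph with planted structure
#'
#' See [fixture_spec()] for what is planted. The returned ground truth lists
#' every module-matched (drug, disease) pair with a `held_out` flag; held-out
#' pairs appear neither in the labeled pair list nor as treatment edges in
#' the graph, so they can be used to test recovery of unseen associations.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `"semwalk_fixture"`: `graph`, `drug_hierarchy`,
#'   `disease_hierarchy`, `pairs` (labeled positives), `ground_truth`
#'   (drug, disease, module, held_out), `modules` (named lists of module
#'   assignments), `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    drugs <- sprintf("D%03d", seq_len(spec$n_drugs))
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    diseases <- sprintf("Z%03d", seq_len(spec$n_diseases))
    pathways <- if (spec$n_pathways > 0) {
      sprintf("P%02d", seq_len(spec$n_pathways))
    } else character(0)

    mod_gene <- rep_len(seq_len(spec$n_modules), spec$n_genes)
    mod_drug <- rep_len(seq_len(spec$n_modules), spec$n_drugs)
    mod_dis <- rep_len(seq_len(spec$n_modules), spec$n_diseases)
    mod_pw <- if (spec$n_pathways > 0) {
      rep_len(seq_len(spec$n_modules), spec$n_pathways)
    } else integer(0)

    # gene-gene layer: dense within modules, sparse between
    pr <- which(upper.tri(matrix(0, spec$n_genes, spec$n_genes)),
                arr.ind = TRUE)
    same <- mod_gene[pr[, 1]] == mod_gene[pr[, 2]]
    pkeep <- ifelse(same, spec$ppi_density_in, spec$ppi_density_out)
    keep <- stats::runif(nrow(pr)) < pkeep
    ppi <- data.frame(source = genes[pr[keep, 1]],
                      target = genes[pr[keep, 2]],
                      edge_type = "PPI", stringsAsFactors = FALSE)

    # drugs target genes of their own module
    dt <- do.call(rbind, lapply(seq_along(drugs), function(i) {
      pool <- genes[mod_gene == mod_drug[i]]
      data.frame(source = drugs[i],
                 target = sample(pool, spec$targets_per_drug),
                 edge_type = "drug_target", stringsAsFactors = FALSE)
    }))
    # diseases associate with genes of their own module
    zg <- do.call(rbind, lapply(seq_along(diseases), function(i) {
      pool <- genes[mod_gene == mod_dis[i]]
      data.frame(source = diseases[i],
                 target = sample(pool, spec$genes_per_disease),
                 edge_type = "disease_gene", stringsAsFactors = FALSE)
    }))
    # pathways attach to genes of their module
    pw <- if (length(pathways) > 0) {
      do.call(rbind, lapply(seq_along(pathways), function(i) {
        pool <- genes[mod_gene == mod_pw[i]]
        data.frame(source = pathways[i],
                   target = sample(pool, min(10L, length(pool))),
                   edge_type = "pathway_gene", stringsAsFactors = FALSE)
      }))
    } else NULL

    # ground truth: a drug treats a disease iff their modules match
    gt <- do.call(rbind, lapply(seq_along(drugs), function(i) {
      z <- diseases[mod_dis == mod_drug[i]]
      if (length(z) == 0) return(NULL)
      data.frame(drug = drugs[i], disease = z, module = mod_drug[i],
                 stringsAsFactors = FALSE)
    }))
    n_hold <- round(spec$heldout_frac * nrow(gt))
    gt$held_out <- FALSE
    if (n_hold > 0) gt$held_out[sample.int(nrow(gt), n_hold)] <- TRUE
    labeled <- gt[!gt$held_out, , drop = FALSE]
    treats <- data.frame(source = labeled$drug, target = labeled$disease,
                         edge_type = "treats", stringsAsFactors = FALSE)

    structured <- rbind(ppi, dt, zg, pw, treats)
    # noise layer: random gene-gene / drug-gene / disease-gene edges
    n_noise <- round(spec$noise_edge_rate * nrow(structured))
    noise <- NULL
    if (n_noise > 0) {
      kind <- sample(c("gg", "dg", "zg"), n_noise, replace = TRUE)
      src <- character(n_noise); tgt <- character(n_noise)
      src[kind == "gg"] <- sample(genes, sum(kind == "gg"), replace = TRUE)
      tgt[kind == "gg"] <- sample(genes, sum(kind == "gg"), replace = TRUE)
      src[kind == "dg"] <- sample(drugs, sum(kind == "dg"), replace = TRUE)
      tgt[kind == "dg"] <- sample(genes, sum(kind == "dg"), replace = TRUE)
      src[kind == "zg"] <- sample(diseases, sum(kind == "zg"), replace = TRUE)
      tgt[kind == "zg"] <- sample(genes, sum(kind == "zg"), replace = TRUE)
      ok <- src != tgt
      noise <- data.frame(source = src[ok], target = tgt[ok],
                          edge_type = "noise", stringsAsFactors = FALSE)
    }
    edges <- rbind(structured, noise)
    edges$weight <- 1.0

    node_types <- stats::setNames(
      c(rep("drug", length(drugs)), rep("gene", length(genes)),
        rep("disease", length(diseases)), rep("pathway", length(pathways))),
      c(drugs, genes, diseases, pathways))
    g <- knowledge_graph(edges, node_types)

    dh <- module_hierarchy("ATC", drugs, mod_drug, spec$n_modules,
                           spec$semantic_groups)
    zh <- module_hierarchy("MESH", diseases, mod_dis, spec$n_modules,
                           spec$semantic_groups)

    pairs <- data.frame(drug = labeled$drug, disease = labeled$disease,
                        label = 1L, stringsAsFactors = FALSE)
    rownames(gt) <- NULL

    structure(list(graph = g, drug_hierarchy = dh, disease_hierarchy = zh,
                   pairs = pairs, ground_truth = gt,
                   modules = list(drug = stats::setNames(mod_drug, drugs),
                                  gene = stats::setNames(mod_gene, genes),
                                  disease = stats::setNames(mod_dis, diseases)),
                   spec = spec),
              class = "semwalk_fixture")
  })
}

#' @export
print.semwalk_fixture <- function(x, ...) {
  cat(sprintf("Synthetic fixture: %d modules, %d labeled + %d held-out treatment pairs\n",
              x$spec$n_modules, nrow(x$pairs), sum(x$ground_truth$held_out)))
  print(x$graph)
  invisible(x)
}

#' Write a fixture to a directory in the package's TSV formats
#'
#' The ground truth is written separately (`ground_truth.tsv`) and is never
#' read by pipeline code.
#'
#' @param fx a [generate_fixture()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(dir, "graph.tsv"),
             node_types = file.path(dir, "node_types.tsv"),
             drug_hierarchy = file.path(dir, "drug_hierarchy.tsv"),
             drug_mapping = file.path(dir, "drug_mapping.tsv"),
             disease_hierarchy = file.path(dir, "disease_hierarchy.tsv"),
             disease_mapping = file.path(dir, "disease_mapping.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_graph(fx$graph, paths["edges"], paths["node_types"])
  write_hierarchy(fx$drug_hierarchy, paths["drug_hierarchy"],
                  paths["drug_mapping"])
  write_hierarchy(fx$disease_hierarchy, paths["disease_hierarchy"],
                  paths["disease_mapping"])
  write_pairs(fx$pairs, paths["pairs"])
  write_tsv_commented(fx$ground_truth, paths["ground_truth"],
                      c("drug", "disease", "module", "held_out"))
  invisible(paths)
}
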