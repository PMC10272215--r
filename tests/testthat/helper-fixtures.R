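# Shared builders for tests. Everything is generated in code; nothing is
# read from disk.

# D1-D2 drugs, G1-G3 genes, Z1 disease; two edge types
tiny_graph <- function() {
  knowledge_graph(
    data.frame(
      source = c("D1", "D2", "G1", "G2", "G3", "G1"),
      target = c("G1", "G2", "G2", "G3", "Z1", "G3"),
      edge_type = c("drug_target", "drug_target", "PPI", "PPI",
                    "disease_gene", "PPI"),
      stringsAsFactors = FALSE),
    c(D1 = "drug", D2 = "drug", G1 = "gene", G2 = "gene", G3 = "gene",
      Z1 = "disease"))
}

# 5-term hierarchy root -> {A, B}, A -> {L1, L2}; the worked IC example
toy_hierarchy <- function(entity_map = NULL) {
  ontology(data.frame(child = c("A", "B", "L1", "L2"),
                      parent = c("root", "root", "A", "A"),
                      stringsAsFactors = FALSE),
           entity_map)
}

# hand-built sparse similarity matrix object (package-internal class)
manual_sim <- function(entries, node_type = "drug", cutoff = 0) {
  structure(list(entity_ids = sort(unique(c(entries$a, entries$b))),
                 entries = entries, cutoff = cutoff, node_type = node_type,
                 combine = "max"),
            class = "semwalk_sim")
}

# small, fast planted fixture for unit tests (not the study conditions)
small_fixture <- function(seed = 1, ...) {
  generate_fixture(fixture_spec(n_drugs = 12, n_genes = 60, n_diseases = 8,
                                n_pathways = 2, n_modules = 4,
                                ppi_density_in = 0.3, ppi_density_out = 0.03,
                                seed = seed, ...))
}

# hand-rolled embedding space
manual_embedding <- function(mat, types) {
  structure(list(vectors = mat, node_type = types, dim = ncol(mat),
                 unembedded = character(0)),
            class = "semwalk_emb")
}

# one-classifier AUROC of held-out true pairs vs seeded random non-pairs
heldout_auroc <- function(fit, fx, seed) {
  gt <- fx$ground_truth
  held <- gt[gt$held_out, c("drug", "disease")]
  all_d <- names(fx$modules$drug); all_z <- names(fx$modules$disease)
  grid <- expand.grid(drug = all_d, disease = all_z,
                      stringsAsFactors = FALSE)
  grid <- grid[!(paste(grid$drug, grid$disease) %in%
                 paste(gt$drug, gt$disease)), ]
  set.seed(seed + 77000)
  neg <- grid[sample.int(nrow(grid), nrow(held)), ]
  ev <- rbind(transform(held, label = 1L), transform(neg, label = 0L))
  sc <- predict(fit, pairs = ev)
  r <- rank(sc$mean_prob)
  np <- sum(sc$label == 1); nn <- sum(sc$label == 0)
  (sum(r[sc$label == 1]) - np * (np + 1) / 2) / (np * nn)
}
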