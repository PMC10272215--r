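manual_corpus <- function(walks) {
  structure(list(walks = walks,
                 actions = lapply(walks, function(w)
                   rep("traverse", max(length(w) - 1, 0))),
                 edge_types = lapply(walks, function(w)
                   rep(NA_character_, max(length(w) - 1, 0))),
                 params = NULL, teleport = "none",
                 unreachable = character(0)),
            class = "semwalk_corpus")
}

nt4 <- c(Drug1 = "drug", GeneA = "gene", Disease1 = "disease",
         GeneB = "gene", GeneC = "gene")

test_that("window neighbors collect genes within l positions only", {
  co <- manual_corpus(list(c("Drug1", "GeneA", "Disease1", "GeneB")))
  nb2 <- window_neighbors(co, "Drug1", l = 2, node_types = nt4)
  expect_equal(nb2$genes, "GeneA")    # GeneB sits 3 positions away
  nb3 <- window_neighbors(co, "Drug1", l = 3, node_types = nt4)
  expect_setequal(nb3$genes, c("GeneA", "GeneB"))
  # l at least the walk length: every co-occurring gene
  nb9 <- window_neighbors(co, "Drug1", l = 9, node_types = nt4)
  expect_setequal(nb9$genes, c("GeneA", "GeneB"))
})

test_that("window neighbor counts accumulate over occurrences", {
  co <- manual_corpus(list(c("Drug1", "GeneA", "Drug1", "GeneA"),
                           c("GeneC", "Drug1", "GeneA", "Disease1")))
  nb <- window_neighbors(co, "Drug1", l = 1, node_types = nt4)
  expect_equal(unname(nb$occurrence_counts["GeneA"]), 4L)
  expect_equal(unname(nb$occurrence_counts["GeneC"]), 1L)
  # entity itself is never its own neighbour
  expect_false("Drug1" %in% nb$genes)
})

test_that("entities without nearby genes give empty sets; absent ones error", {
  co <- manual_corpus(list(c("Drug1", "Disease1")))
  nb <- window_neighbors(co, "Drug1", l = 1, node_types = nt4)
  expect_length(nb$genes, 0)
  expect_error(window_neighbors(co, "GeneB", l = 1, node_types = nt4),
               "does not occur")
})

test_that("Fisher enrichment equals the hypergeometric tail sum", {
  # 2x2 table (3, 7, 2, 88): universe 100, neighbours 10, term 5, overlap 3
  universe <- sprintf("g%03d", 1:100)
  term <- universe[1:5]
  neighbors <- c(universe[1:3], universe[11:17])
  res <- enrich(neighbors, list(TERM = term), universe)
  p_oracle <- sum(stats::dhyper(3:5, 5, 95, 10))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$overlap, 3)
  expect_equal(res$term_size, 5)
  expect_equal(res$gene_ratio, 3 / 5)
})

test_that("enrichment extremes behave: full containment and disjointness", {
  universe <- sprintf("g%04d", 1:1000)
  term <- universe[1:5]
  res <- enrich(term, list(HIT = term, MISS = universe[900:950]), universe)
  hit <- res[res$term == "HIT", ]
  expect_lt(hit$p_adj, 1e-10)
  expect_equal(hit$gene_ratio, 1.0)
  miss <- res[res$term == "MISS", ]
  expect_equal(miss$p, 1)
  expect_error(enrich(character(0), list(T1 = term), universe),
               "nothing to test")
})

test_that("Benjamini-Hochberg adjustment is monotone and >= p", {
  universe <- sprintf("g%03d", 1:200)
  set.seed(2)
  sets <- lapply(1:8, function(i) sample(universe, 20))
  names(sets) <- paste0("T", 1:8)
  nb <- sample(universe, 30)
  res <- enrich(nb, sets, universe)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_equal(order(res$p), order(res$p_adj))  # same ordering up to ties
  expect_equal(res$p_adj, sort(res$p_adj))      # sorted output
})

test_that("GMT-style gene set files round-trip into named lists", {
  f <- tempfile()
  writeLines(c("pathA\tdescription A\tg1\tg2\tg3",
               "pathB\tanother\tg2\tg9"), f)
  gs <- read_gene_sets(f)
  expect_equal(gs, list(pathA = c("g1", "g2", "g3"), pathB = c("g2", "g9")))
})

test_that("z-normalized distances standardize against all pairs", {
  # 4-point space with hand-computable distances
  m <- rbind(a = c(0, 0), b = c(3, 0), c = c(0, 4), d = c(3, 4))
  e <- manual_embedding(m, stats::setNames(rep("gene", 4), rownames(m)))
  dists <- c(3, 4, 5, 5, 4, 3)  # ab, ac, ad, bc, bd, cd
  mu <- mean(dists); s <- stats::sd(dists)
  z <- znorm_distances(e, data.frame(u = c("a", "a"), v = c("b", "d")))
  expect_equal(z, c((3 - mu) / s, (5 - mu) / s), tolerance = 1e-12)
  # normalization identity: full population has mean 0, sd 1
  allp <- t(combn(rownames(m), 2))
  zall <- znorm_distances(e, allp)
  expect_equal(mean(zall), 0, tolerance = 1e-12)
  expect_equal(stats::sd(zall), 1, tolerance = 1e-12)
  # pair exactly at the mean distance scores 0
  expect_equal(znorm_distances(e, data.frame("a", "d"))[1], (5 - mu) / s)
})

test_that("degenerate spaces with zero distance variance are rejected", {
  m <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, sqrt(3) / 2))
  e <- manual_embedding(m, stats::setNames(rep("gene", 3), rownames(m)))
  expect_error(znorm_distances(e, data.frame("a", "b")), "degenerate")
})

test_that("space comparison is a paired two-sided t-test on z distances", {
  set.seed(8)
  m1 <- matrix(rnorm(40), 20, 2,
               dimnames = list(sprintf("n%02d", 1:20), NULL))
  e1 <- manual_embedding(m1, stats::setNames(rep("gene", 20),
                                             rownames(m1)))
  # e2: same geometry but the first five points pulled toward each other
  m2 <- m1
  m2[1:5, ] <- m2[1:5, ] * 0.2
  e2 <- manual_embedding(m2, e1$node_type)
  pairs <- t(combn(sprintf("n%02d", 1:5), 2))
  res <- compare_spaces(e1, e2, pairs)
  expect_gt(res$mean_difference, 0)   # pairs sit closer in e2
  expect_lt(res$p, 0.05)
  # closed-form t statistic on the same z values
  z1 <- znorm_distances(e1, pairs); z2 <- znorm_distances(e2, pairs)
  d <- z1 - z2
  t_manual <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, length(d) - 1)
})

test_that("identical spaces report no difference", {
  set.seed(9)
  m <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("n%02d", 1:10), NULL))
  e <- manual_embedding(m, stats::setNames(rep("gene", 10), rownames(m)))
  pairs <- t(combn(sprintf("n%02d", 1:4), 2))
  res <- compare_spaces(e, e, pairs)
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p, 1)
  expect_error(compare_spaces(e, e, pairs[1, , drop = FALSE]), "at least 2")
})

test_that("teleport corpora widen window-neighbor gene diversity", {
  # directional property, median over seeds
  diversity <- function(seed, mode) {
    fx <- small_fixture(seed = seed)
    g <- remove_edges_by_type(fx$graph, "treats")
    sims <- list(drug = build_similarity_matrix(g, fx$drug_hierarchy, "drug"),
                 disease = build_similarity_matrix(g, fx$disease_hierarchy,
                                                   "disease"))
    co <- sample_walks(g, sim = sims,
                       params = walk_params(num_walks_per_node = 30,
                                            seed = seed),
                       teleport = mode)
    drugs <- names(fx$modules$drug)[1:4]
    mean(vapply(drugs, function(d) {
      length(window_neighbors(co, d, l = 4, g$node_type)$genes)
    }, numeric(1)))
  }
  seeds <- 1:5
  on_div <- vapply(seeds, diversity, numeric(1), mode = "semantic")
  off_div <- vapply(seeds, diversity, numeric(1), mode = "none")
  expect_gte(stats::median(on_div), stats::median(off_div))
})
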