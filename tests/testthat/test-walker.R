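# A 4-node graph with a distinct edge type per pair, so the incoming edge
# type of any step is unambiguous.
quad_graph <- function() {
  knowledge_graph(
    data.frame(source = c("A", "A", "B", "C"),
               target = c("B", "C", "C", "D"),
               edge_type = c("t1", "t2", "t3", "t4"),
               weight = c(1, 2, 1.5, 1)),
    c(A = "gene", B = "gene", C = "gene", D = "gene"))
}

test_that("next-step distribution matches the hand-worked teleport example", {
  g <- knowledge_graph(
    data.frame(source = "D1", target = "G1", edge_type = "drug_target"),
    c(D1 = "drug", G1 = "gene", D2 = "drug", D3 = "drug"))
  ms <- manual_sim(data.frame(a = c("D1", "D1"), b = c("D2", "D3"),
                              sim = c(0.8, 0.2), stringsAsFactors = FALSE))
  d <- step_distribution(g, NULL, "D1", sim = list(drug = ms),
                         params = walk_params(tau = 0.3))
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(d[["D2"]], 0.3 * 0.8)
  expect_equal(d[["D3"]], 0.3 * 0.2)
  expect_equal(d[["G1"]], 0.7)
})

test_that("a non-teleport node with equal weights steps uniformly", {
  g <- knowledge_graph(
    data.frame(source = c("G0", "G0", "G0"), target = c("G1", "G2", "G3"),
               edge_type = "PPI"),
    c(G0 = "gene", G1 = "gene", G2 = "gene", G3 = "gene"))
  d <- step_distribution(g, NULL, "G0", params = walk_params())
  expect_equal(unname(d[c("G1", "G2", "G3")]), rep(1 / 3, 3))
})

test_that("an empty similarity row falls back to pure traversal", {
  g <- knowledge_graph(
    data.frame(source = "D1", target = "G1", edge_type = "drug_target"),
    c(D1 = "drug", G1 = "gene"))
  d_empty <- step_distribution(g, NULL, "D1", sim = list(),
                               params = walk_params(tau = 0.3))
  expect_equal(d_empty[["G1"]], 1)
  # isolated non-teleportable node is a dead end
  g2 <- knowledge_graph(
    data.frame(source = "D1", target = "G1", edge_type = "drug_target"),
    c(D1 = "drug", G1 = "gene", G9 = "gene"))
  expect_error(step_distribution(g2, NULL, "G9"), "dead-end")
})

test_that("with tau = 0 the law reduces exactly to node2vec traversal", {
  g <- quad_graph()
  e <- g$edges
  pp <- walk_params(tau = 0, p = 2, q = 0.5)
  # brute-force enumeration straight from the edge list
  nbrs <- function(v) {
    nb <- e[e$source == v | e$target == v, , drop = FALSE]
    nb$other <- ifelse(nb$source == v, nb$target, nb$source)
    nb
  }
  for (curr in g$nodes) {
    for (prev in c(NA, nbrs(curr)$other)) {
      nb <- nbrs(curr)
      w <- nb$weight
      if (!is.na(prev)) {
        pn <- nbrs(prev)$other
        alpha <- ifelse(nb$other == prev, 1 / pp$p,
                        ifelse(nb$other %in% pn, 1, 1 / pp$q))
        w <- w * alpha
        d <- step_distribution(g, prev, curr, params = pp)
      } else {
        d <- step_distribution(g, NULL, curr, params = pp)
      }
      want <- tapply(w / sum(w), nb$other, sum)
      expect_equal(d[names(want)], want[names(want)], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("the transition-matrix factor reweights by incoming edge type", {
  g <- quad_graph()
  M <- structure(list(
    M = matrix(c(0.7, 0.6, 0.5, 0.4,
                 0.6, 0.7, 0.3, 0.2,
                 0.5, 0.3, 0.7, 0.6,
                 0.4, 0.2, 0.6, 0.7), 4, 4, byrow = TRUE,
               dimnames = list(paste0("t", 1:4), paste0("t", 1:4))),
    edge_types = paste0("t", 1:4), n_iter_run = 1L),
    class = "semwalk_etm")
  # at C having arrived from A via t2: neighbours A (t2), B (t3), D (t4)
  d <- step_distribution(g, "A", "C", M = M, params = walk_params(tau = 0))
  w <- c(A = 2 * M$M["t2", "t2"] * (1 / 1),   # back to prev: alpha = 1/p = 1
         B = 1.5 * M$M["t2", "t3"] * 1,       # B adjacent to A
         D = 1 * M$M["t2", "t4"] * 1)         # q = 1
  expect_equal(d[names(w)], w / sum(w), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("empirical step frequencies match the analytic law", {
  g <- quad_graph()
  pp <- walk_params(num_walks_per_node = 30000, walk_length = 3,
                    tau = 0, p = 2, q = 0.5, seed = 42)
  co <- sample_walks(g, params = pp, teleport = "none", start_nodes = "A")
  first <- vapply(co$walks, `[[`, "", 2)
  d1 <- step_distribution(g, NULL, "A", params = pp)
  for (x in names(d1)) {
    phat <- mean(first == x)
    se <- sqrt(d1[[x]] * (1 - d1[[x]]) / length(first))
    expect_lt(abs(phat - d1[[x]]), 3 * se + 1e-9)
  }
  # conditional second step given the walker moved A -> B (edge t1)
  sel <- first == "B"
  second <- vapply(co$walks[sel], `[[`, "", 3)
  d2 <- step_distribution(g, "A", "B", params = pp, prev_edge_type = "t1")
  for (x in names(d2)) {
    phat <- mean(second == x)
    se <- sqrt(d2[[x]] * (1 - d2[[x]]) / sum(sel))
    expect_lt(abs(phat - d2[[x]]), 3 * se + 1e-9)
  }
})

test_that("teleport bookkeeping in sampled corpora is exact", {
  fx <- small_fixture()
  g <- remove_edges_by_type(fx$graph, "treats")
  sd_ <- build_similarity_matrix(g, fx$drug_hierarchy, "drug")
  sz <- build_similarity_matrix(g, fx$disease_hierarchy, "disease")

  # tau = 0: no teleports at all
  co0 <- sample_walks(g, sim = list(drug = sd_, disease = sz),
                      params = walk_params(num_walks_per_node = 5, tau = 0))
  expect_equal(sum(unlist(co0$actions) == "teleport"), 0)

  # every walk has walk_length nodes and walk_length - 1 trace entries
  expect_true(all(lengths(co0$walks) == 4))
  expect_true(all(lengths(co0$actions) == 3))

  # tau = 1 on an all-drug clique with full similarity: every step teleports
  drugs <- paste0("D", 1:4)
  gg <- knowledge_graph(
    data.frame(source = rep(drugs, each = 4), target = rep(drugs, 4),
               edge_type = "x")[rep(drugs, each = 4) != rep(drugs, 4), ],
    stats::setNames(rep("drug", 4), drugs))
  full <- manual_sim(do.call(rbind, lapply(1:3, function(i)
    data.frame(a = drugs[i], b = drugs[(i + 1):4], sim = 1))))
  co1 <- sample_walks(gg, sim = list(drug = full),
                      params = walk_params(num_walks_per_node = 20, tau = 1))
  expect_true(all(unlist(co1$actions) == "teleport"))
  expect_true(all(is.na(unlist(co1$edge_types))))
})

test_that("walk sampling is reproducible under a fixed seed", {
  fx <- small_fixture()
  g <- remove_edges_by_type(fx$graph, "treats")
  sd_ <- build_similarity_matrix(g, fx$drug_hierarchy, "drug")
  pp <- walk_params(num_walks_per_node = 3, seed = 9)
  a <- sample_walks(g, sim = list(drug = sd_), params = pp)
  b <- sample_walks(g, sim = list(drug = sd_), params = pp)
  expect_identical(a$walks, b$walks)
  expect_identical(a$actions, b$actions)
  pp2 <- walk_params(num_walks_per_node = 3, seed = 10)
  c_ <- sample_walks(g, sim = list(drug = sd_), params = pp2)
  expect_false(identical(a$walks, c_$walks))
})

test_that("the step law is invariant under node relabeling", {
  g <- quad_graph()
  relabel <- c(A = "W", B = "X", C = "Y", D = "Z")
  e2 <- g$edges
  e2$source <- unname(relabel[e2$source])
  e2$target <- unname(relabel[e2$target])
  g2 <- knowledge_graph(e2, stats::setNames(rep("gene", 4), relabel))
  pp <- walk_params(tau = 0, p = 2, q = 0.5)
  d1 <- step_distribution(g, "A", "C", params = pp)
  d2 <- step_distribution(g2, "W", "Y", params = pp)
  expect_equal(as.numeric(d2[relabel[names(d1)]]), as.numeric(d1),
               tolerance = 1e-12)
})

test_that("EM training reproduces an independent straight-line recomputation", {
  # 2-edge-type toy graph, 20 walks, one EM iteration
  g <- knowledge_graph(
    data.frame(source = c("A", "B", "C", "D", "A"),
               target = c("B", "C", "D", "E", "C"),
               edge_type = c("t1", "t2", "t1", "t2", "t1")),
    stats::setNames(rep("gene", 5), c("A", "B", "C", "D", "E")))
  pp <- walk_params(num_walks_per_node = 4, walk_length = 4, seed = 17)
  etm <- train_transition_matrix(g, pp, n_iter = 1)

  # independent reconstruction: same derived seed, all-ones matrix, then
  # hand-counted occurrences + closed-form Pearson + logistic
  pp2 <- pp
  pp2$seed <- semwalk:::derive_seed(pp$seed, "etm-iter-1")
  ones <- structure(list(M = matrix(1, 2, 2), edge_types = c("t1", "t2"),
                         n_iter_run = 0L), class = "semwalk_etm")
  co <- sample_walks(g, M = ones, params = pp2, teleport = "none")
  expect_length(co$walks, 20)
  v1 <- vapply(co$edge_types, function(t) sum(t == "t1", na.rm = TRUE), 0)
  v2 <- vapply(co$edge_types, function(t) sum(t == "t2", na.rm = TRUE), 0)
  pearson <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
    if (den == 0) 0 else num / den
  }
  sigmoid <- function(z) 1 / (1 + exp(-z))
  want <- matrix(c(sigmoid(pearson(v1, v1)), sigmoid(pearson(v1, v2)),
                   sigmoid(pearson(v2, v1)), sigmoid(pearson(v2, v2))),
                 2, 2, byrow = TRUE, dimnames = list(c("t1", "t2"),
                                                     c("t1", "t2")))
  expect_equal(etm$M, want, tolerance = 1e-12)
  # identical occurrence vectors sit at sigmoid(1)
  expect_equal(unname(diag(etm$M)), rep(sigmoid(1), 2), tolerance = 1e-12)
  expect_equal(sigmoid(1), 0.7311, tolerance = 1e-4)
})

test_that("a single edge type makes transition training a no-op", {
  g <- knowledge_graph(
    data.frame(source = c("A", "B"), target = c("B", "C"), edge_type = "t"),
    c(A = "gene", B = "gene", C = "gene"))
  expect_warning(etm <- train_transition_matrix(g, walk_params()), "no-op")
  expect_equal(unname(etm$M), matrix(1, 1, 1))
})

test_that("walk corpus text round-trip preserves walks and traces", {
  fx <- small_fixture()
  g <- remove_edges_by_type(fx$graph, "treats")
  sd_ <- build_similarity_matrix(g, fx$drug_hierarchy, "drug")
  co <- sample_walks(g, sim = list(drug = sd_),
                     params = walk_params(num_walks_per_node = 2, seed = 4))
  wf <- tempfile(); tf <- tempfile()
  write_walks(co, wf, tf)
  co2 <- read_walks(wf, tf)
  expect_identical(co2$walks, co$walks)
  expect_identical(co2$actions, co$actions)
  expect_identical(co2$edge_types, co$edge_types)
})
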