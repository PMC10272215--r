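# deterministic synthetic embedding: drugs and diseases carry a module code
# in the first coordinates, so module-matched pairs are linearly separable
coded_embedding <- function(n_drugs = 30, n_diseases = 20, n_modules = 2,
                            dim = 8, noise = 0.05, seed = 1,
                            signal = TRUE) {
  set.seed(seed)
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  diseases <- sprintf("Z%02d", seq_len(n_diseases))
  mod_d <- rep_len(seq_len(n_modules), n_drugs)
  mod_z <- rep_len(seq_len(n_modules), n_diseases)
  mk <- function(mod) {
    v <- rnorm(dim, sd = noise)
    if (signal) v[mod] <- v[mod] + 1
    v
  }
  m <- rbind(t(vapply(mod_d, mk, numeric(dim))),
             t(vapply(mod_z, mk, numeric(dim))))
  rownames(m) <- c(drugs, diseases)
  e <- manual_embedding(m, stats::setNames(
    c(rep("drug", n_drugs), rep("disease", n_diseases)), c(drugs, diseases)))
  pos <- do.call(rbind, lapply(seq_len(n_drugs), function(i) {
    z <- diseases[mod_z == mod_d[i]]
    data.frame(drug = drugs[i], disease = z, label = 1L,
               stringsAsFactors = FALSE)
  }))
  list(e = e, pos = pos, mod_d = stats::setNames(mod_d, drugs),
       mod_z = stats::setNames(mod_z, diseases))
}

test_that("pair features are drug-minus-disease subtractions", {
  m <- rbind(d1 = c(1, 2), z1 = c(0.5, 2), z2 = c(1, 2))
  e <- manual_embedding(m, c(d1 = "drug", z1 = "disease", z2 = "disease"))
  f <- make_pair_features(e, data.frame(drug = c("d1", "d1"),
                                        disease = c("z1", "z2"),
                                        label = c(1L, 0L)))
  x <- attr(f, "x")
  expect_equal(unname(x[1, ]), c(0.5, 0))
  expect_equal(unname(x[2, ]), c(0, 0))   # identical vectors -> zero vector
  # antisymmetry of the subtraction order
  expect_equal(unname(x[1, ]), -unname(m["z1", ] - m["d1", ]))
})

test_that("pairs with unembedded endpoints are skipped and reported", {
  m <- rbind(d1 = c(1, 0))
  e <- manual_embedding(m, c(d1 = "drug"))
  f <- make_pair_features(e, data.frame(drug = c("d1", "d2"),
                                        disease = c("d1", "d1"),
                                        label = c(1L, 1L)))
  expect_equal(nrow(f), 1)
  expect_equal(attr(f, "skipped")$drug, "d2")
})

test_that("negative sets are disjoint, positive-free and correctly sized", {
  ce <- coded_embedding(n_drugs = 50, n_diseases = 50)
  pos <- ce$pos[1:10, ]
  sets <- sample_negatives(ce$e, pos, n_sets = 10, seed = 3)
  expect_length(sets, 10)
  keys <- lapply(sets, function(s) paste(s$drug, s$disease))
  expect_true(all(lengths(keys) == 10))
  expect_equal(anyDuplicated(unlist(keys)), 0)         # pairwise disjoint
  expect_length(intersect(unlist(keys), paste(pos$drug, pos$disease)), 0)
  # demanding more pairs than exist errors with the counts
  expect_error(sample_negatives(ce$e, ce$pos, n_sets = 10),
               "need .* available")
})

test_that("rank-based AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- rep(c(1, 0), each = 40)
  s <- rnorm(80) + y
  ours <- semwalk:::auroc_score(s, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
  # average precision against a hand-enumerated toy
  # scores sorted desc: labels 1,0,1 -> AP = (1/1 + 2/3)/2
  expect_equal(semwalk:::aupr_score(c(0.9, 0.5, 0.7), c(1, 1, 0)),
               mean(c(1, 2 / 3)))
})

test_that("cross-validation behaves at the null and at separability", {
  ce <- coded_embedding(n_modules = 4)
  f <- make_pair_features(ce$e, ce$pos)
  plan <- cv_plan(n_repeats = 2, n_folds = 5, seed = 5)
  cv <- cross_validate(f, plan, e = ce$e, nrounds = 40)
  s <- attr(cv, "summary")
  expect_gt(s$mean[s$metric == "auroc"], 0.95)  # module code is separable
  expect_true(all(cv$auroc >= 0 & cv$auroc <= 1))

  # label-free geometry: pure-noise embeddings give chance-level AUROC
  ce0 <- coded_embedding(n_modules = 4, noise = 1, signal = FALSE, seed = 6)
  f0 <- make_pair_features(ce0$e, ce0$pos)
  cvp <- cross_validate(f0, plan, e = ce0$e, nrounds = 40)
  sp <- attr(cvp, "summary")
  expect_lt(abs(sp$mean[sp$metric == "auroc"] - 0.5), 0.12)
})

test_that("metrics are invariant to feature-row order", {
  ce <- coded_embedding(n_drugs = 16, n_diseases = 12, n_modules = 4)
  f <- make_pair_features(ce$e, ce$pos)
  plan <- cv_plan(n_repeats = 1, n_folds = 4, seed = 2)
  negs <- sample_negatives(ce$e, ce$pos, n_sets = 1, seed = 2)
  cv1 <- cross_validate(f, plan, e = ce$e, negatives = negs, nrounds = 30)
  ord <- rev(seq_len(nrow(f)))
  f2 <- f[ord, ]
  attr(f2, "x") <- attr(f, "x")[ord, , drop = FALSE]
  cv2 <- cross_validate(f2, plan, e = ce$e, negatives = negs, nrounds = 30)
  s1 <- attr(cv1, "summary"); s2 <- attr(cv2, "summary")
  expect_equal(s1$mean, s2$mean, tolerance = 1e-10)
})

test_that("disease-split folds never let a category span partitions", {
  ce <- coded_embedding(n_drugs = 20, n_diseases = 20, n_modules = 4)
  cats <- stats::setNames(paste0("C", rep_len(1:5, 20)), names(ce$mod_z))
  plan <- cv_plan("disease_split", n_repeats = 10, seed = 3)
  folds <- disease_split_folds(ce$pos, cats, plan)
  expect_length(folds, 10)
  for (fd in folds) {
    by_cat <- split(fd, cats[names(fd)])
    for (b in by_cat) expect_length(unique(b), 1)
    expect_setequal(unique(fd), c("train", "validation", "test"))
  }
  # approximate 8:1:1 at the category level
  fd <- folds[[1]]
  cat_part <- vapply(split(fd, cats[names(fd)]), `[[`, "", 1)
  expect_equal(sort(as.integer(table(cat_part))), c(1, 1, 3))
  expect_error(
    disease_split_folds(ce$pos, stats::setNames(rep("C1", 20),
                                                names(ce$mod_z)), plan),
    "at least 3")
})

test_that("disease-split CV evaluates only unseen categories", {
  ce <- coded_embedding(n_drugs = 24, n_diseases = 20, n_modules = 4)
  cats <- stats::setNames(paste0("C", rep_len(1:5, 20)), names(ce$mod_z))
  f <- make_pair_features(ce$e, ce$pos)
  plan <- cv_plan("disease_split", n_repeats = 3, seed = 9)
  cv <- cross_validate(f, plan, e = ce$e, disease_category = cats,
                       nrounds = 30)
  expect_true(all(c("accuracy", "auroc", "aupr") %in% names(cv)))
  expect_true(all(cv$n_test > 0))
})

test_that("candidate ranking averages models, sorts, and breaks ties by id", {
  ce <- coded_embedding(n_drugs = 12, n_diseases = 8, n_modules = 4, seed = 2)
  # duplicate one drug's vector so two candidates tie exactly
  e <- ce$e
  e$vectors["D11", ] <- e$vectors["D03", ]
  models <- train_dda_models(e, ce$pos, n_models = 2, nrounds = 30, seed = 4)
  rk <- rank_candidates(models, e, "Z01", known = ce$pos)
  known_drugs <- ce$pos$drug[ce$pos$disease == "Z01"]
  expect_length(intersect(rk$drug, known_drugs), 0)
  expect_setequal(rk$drug, setdiff(names(ce$mod_d), known_drugs))
  expect_true(all(rk$mean_prob >= 0 & rk$mean_prob <= 1))
  expect_true(!is.unsorted(rev(rk$mean_prob)))
  i3 <- which(rk$drug == "D03"); i11 <- which(rk$drug == "D11")
  expect_equal(rk$mean_prob[i3], rk$mean_prob[i11])
  expect_lt(i3, i11)   # lexicographic tie-break
  expect_error(rank_candidates(models, e, "ZZZ"), "not embedded")
})
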