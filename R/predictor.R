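#' Pair features by element-wise vector subtraction
#'
#' Each (drug, disease) pair is featurized as `vector(drug) -
#' vector(disease)`, always in that order. Pairs with an unembedded endpoint
#' are skipped and reported in the `skipped` attribute.
#'
#' @param e an embedding space.
#' @param pairs data.frame with columns drug, disease and optionally label.
#' @return data.frame with columns drug, disease, label (NA when unlabeled)
#'   and a matrix attribute `x` of feature rows; attribute `skipped` lists
#'   dropped pairs.
#' @export
make_pair_features <- function(e, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$label)) pairs$label <- NA_integer_
  emb <- rownames(e$vectors)
  ok <- pairs$drug %in% emb & pairs$disease %in% emb
  skipped <- pairs[!ok, , drop = FALSE]
  kept <- pairs[ok, , drop = FALSE]
  x <- e$vectors[kept$drug, , drop = FALSE] -
    e$vectors[kept$disease, , drop = FALSE]
  rownames(x) <- NULL
  rownames(kept) <- NULL
  out <- kept[, c("drug", "disease", "label")]
  attr(out, "x") <- x
  attr(out, "skipped") <- skipped
  out
}

#' Sample disjoint negative drug-disease pair sets
#'
#' Draws `n_sets` sets of candidate negatives, each the size of the positive
#' set, from the full drug x disease grid minus the known positives. The
#' sets are pairwise disjoint, so repeated cross-validation rounds never
#' share a negative sample. Unlabeled pairs are eligible as negatives: no
#' reliable true negatives exist for treatment associations.
#'
#' @param g a knowledge graph (supplies the drug and disease node sets), or
#'   an embedding space.
#' @param positives data.frame with columns drug, disease (label 1 pairs).
#' @param n_sets number of disjoint negative sets.
#' @param seed integer seed.
#' @return list of `n_sets` data.frames with columns drug, disease, label=0.
#' @export
sample_negatives <- function(g, positives, n_sets = 10, seed = 1) {
  nt <- if (inherits(g, "semwalk_emb")) g$node_type else g$node_type
  drugs <- names(nt)[nt == "drug"]
  diseases <- names(nt)[nt == "disease"]
  grid_n <- length(drugs) * length(diseases)
  pos_key <- paste(positives$drug, positives$disease, sep = "\r")
  need <- n_sets * nrow(positives)
  avail <- grid_n - length(unique(pos_key))
  if (avail < need) {
    stop(sprintf("insufficient negative candidates: need %d, available %d",
                 need, avail))
  }
  all_d <- rep(drugs, times = length(diseases))
  all_z <- rep(diseases, each = length(drugs))
  keep <- !(paste(all_d, all_z, sep = "\r") %in% pos_key)
  cand_d <- all_d[keep]; cand_z <- all_z[keep]
  pick <- with_seed(seed, sample.int(length(cand_d), need))
  lapply(seq_len(n_sets), function(s) {
    i <- pick[((s - 1) * nrow(positives) + 1):(s * nrow(positives))]
    data.frame(drug = cand_d[i], disease = cand_z[i], label = 0L,
               stringsAsFactors = FALSE)
  })
}

# ---- metrics -------------------------------------------------------------

# rank-based AUROC (Wilcoxon formula, ties get half credit)
auroc_score <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

# area under the precision-recall curve as average precision
aupr_score <- function(scores, labels) {
  np <- sum(labels == 1)
  if (np == 0 || sum(labels == 0) == 0) return(NA_real_)
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab == 1)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / np
}

#' Cross-validation plan
#'
#' @param scheme `"random_kfold"` (pairs shuffled into folds) or
#'   `"disease_split"` (whole disease categories held out).
#' @param n_repeats repeats, each with its own disjoint negative set.
#' @param n_folds folds per repeat (random_kfold).
#' @param ratios train/validation/test category ratio for disease_split.
#' @param seed integer seed.
#' @export
cv_plan <- function(scheme = c("random_kfold", "disease_split"),
                    n_repeats = 10, n_folds = 10, ratios = c(8, 1, 1),
                    seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n_repeats >= 1, n_folds >= 2, length(ratios) == 3)
  structure(list(scheme = scheme, n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds), ratios = ratios,
                 seed = as.integer(seed)),
            class = "semwalk_cv_plan")
}

# one xgboost fit with the study hyperparameters
fit_booster <- function(x, y, nrounds = 500, max_depth = 5, nthread = 1) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  nthread = nthread),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

predict_booster <- function(fit, x, nthread = 1) {
  predict(fit, xgboost::xgb.DMatrix(x, nthread = nthread))
}

#' Repeated cross-validated drug-disease association prediction
#'
#' Runs the treatment-link classifier under the plan's scheme. For
#' `random_kfold`, each of the `n_repeats` repeats pairs the positives with
#' its own disjoint negative set and runs stratified `n_folds`-fold CV; for
#' `disease_split`, each repeat partitions disease *categories* into
#' train/validation/test (approximate 8:1:1) so that no test-category
#' disease is seen in training, and evaluates on the test partition.
#' Accuracy (threshold 0.5), AUROC and AUPR are reported per fold, with the
#' mean and a 95% t-interval over the repeat means.
#'
#' @param features output of [make_pair_features()] on the positive pairs.
#' @param plan a [cv_plan()].
#' @param e the embedding space (for negative-pair features).
#' @param negatives optional list of negative-pair data.frames (one per
#'   repeat), e.g. from [sample_negatives()]; generated from `e` when NULL.
#' @param disease_category named character vector disease -> category
#'   (required for `disease_split`).
#' @param nrounds,max_depth boosting rounds (default 500) and maximum tree
#'   depth (default 5, i.e. below six).
#' @return Object of class `"semwalk_cv"`: data.frame of per-fold metrics
#'   plus a `summary` attribute (mean, ci_lo, ci_hi per metric over repeat
#'   means).
#' @export
cross_validate <- function(features, plan = cv_plan(), e = NULL,
                           negatives = NULL, disease_category = NULL,
                           nrounds = 500, max_depth = 5) {
  if (is.null(attr(features, "x"))) stop("features must come from make_pair_features()")
  pos <- features[!is.na(features$label) & features$label == 1, , drop = FALSE]
  xpos <- attr(features, "x")[!is.na(features$label) & features$label == 1, ,
                              drop = FALSE]
  if (nrow(pos) == 0) stop("no positive pairs")
  if (is.null(negatives)) {
    if (is.null(e)) stop("supply either negatives or an embedding space")
    negatives <- sample_negatives(e, pos, n_sets = plan$n_repeats,
                                  seed = derive_seed(plan$seed, "negatives"))
  }
  if (length(negatives) < plan$n_repeats) stop("one negative set per repeat required")

  rows <- list()
  for (r in seq_len(plan$n_repeats)) {
    neg <- negatives[[r]]
    if (is.null(e) && is.null(attr(neg, "x"))) {
      stop("negative sets need feature rows or an embedding space")
    }
    fneg <- if (!is.null(attr(neg, "x"))) neg else make_pair_features(e, neg)
    xneg <- attr(fneg, "x")
    x <- rbind(xpos, xneg)
    y <- c(rep(1L, nrow(xpos)), rep(0L, nrow(xneg)))
    dz <- c(pos$disease, fneg$disease)
    # canonical row order: folds and metrics do not depend on how the
    # caller happened to order the feature rows
    key <- paste(c(pos$drug, fneg$drug), dz, y)
    ord <- order(key)
    x <- x[ord, , drop = FALSE]; y <- y[ord]; dz <- dz[ord]

    if (plan$scheme == "random_kfold") {
      fold <- with_seed(derive_seed(plan$seed, paste0("fold-", r)), {
        f <- integer(length(y))
        f[y == 1] <- sample(rep_len(seq_len(plan$n_folds), sum(y == 1)))
        f[y == 0] <- sample(rep_len(seq_len(plan$n_folds), sum(y == 0)))
        f
      })
      for (k in seq_len(plan$n_folds)) {
        te <- fold == k
        if (length(unique(y[te])) < 2) {
          warning(sprintf("repeat %d fold %d has a single class; skipped", r, k))
          next
        }
        fit <- fit_booster(x[!te, , drop = FALSE], y[!te],
                           nrounds = nrounds, max_depth = max_depth)
        pr <- predict_booster(fit, x[te, , drop = FALSE])
        rows[[length(rows) + 1]] <- data.frame(
          rep = r, fold = k, n_test = sum(te),
          accuracy = mean((pr > 0.5) == (y[te] == 1)),
          auroc = auroc_score(pr, y[te]),
          aupr = aupr_score(pr, y[te]))
      }
    } else {
      if (is.null(disease_category)) stop("disease_split needs disease_category")
      part <- disease_split_partition(
        unique(dz), disease_category, plan$ratios,
        seed = derive_seed(plan$seed, paste0("split-", r)))
      grp <- part[dz]
      te <- grp == "test"
      tr <- grp == "train"
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
        warning(sprintf("repeat %d split has a single class; skipped", r))
        next
      }
      fit <- fit_booster(x[tr, , drop = FALSE], y[tr],
                         nrounds = nrounds, max_depth = max_depth)
      pr <- predict_booster(fit, x[te, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, fold = 1L, n_test = sum(te),
        accuracy = mean((pr > 0.5) == (y[te] == 1)),
        auroc = auroc_score(pr, y[te]),
        aupr = aupr_score(pr, y[te]))
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "summary") <- cv_summary(res)
  class(res) <- c("semwalk_cv", class(res))
  res
}

cv_summary <- function(res) {
  per_rep <- stats::aggregate(res[, c("accuracy", "auroc", "aupr")],
                              by = list(rep = res$rep), FUN = mean,
                              na.rm = TRUE)
  out <- lapply(c("accuracy", "auroc", "aupr"), function(mname) {
    v <- per_rep[[mname]]
    m <- mean(v)
    if (length(v) > 1 && stats::sd(v) > 0) {
      ci <- stats::t.test(v)$conf.int
    } else {
      ci <- c(m, m)
    }
    data.frame(metric = mname, mean = m, ci_lo = ci[1], ci_hi = ci[2],
               n_repeats = length(v))
  })
  do.call(rbind, out)
}

#' @export
print.semwalk_cv <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Cross-validation over %d repeats (%d fold rows):\n",
              length(unique(x$rep)), nrow(x)))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %.4f  (95%% CI %.4f-%.4f)\n",
                s$metric[i], s$mean[i], s$ci_lo[i], s$ci_hi[i]))
  }
  invisible(x)
}

# partition categories into train/validation/test by the given ratios
disease_split_partition <- function(diseases, disease_category, ratios,
                                    seed = 1) {
  miss <- setdiff(diseases, names(disease_category))
  if (length(miss) > 0) {
    stop(sprintf("disease '%s' has no category", miss[1]))
  }
  cats <- unique(unname(disease_category[diseases]))
  if (length(cats) < 3) stop("disease_split needs at least 3 categories")
  shuf <- with_seed(seed, sample(cats))
  n <- length(shuf)
  n_test <- max(1L, round(n * ratios[3] / sum(ratios)))
  n_val <- max(1L, round(n * ratios[2] / sum(ratios)))
  if (n_test + n_val >= n) { n_test <- 1L; n_val <- 1L }
  lab <- rep("train", n)
  lab[seq_len(n_test)] <- "test"
  lab[n_test + seq_len(n_val)] <- "validation"
  cat_part <- stats::setNames(lab, shuf)
  stats::setNames(unname(cat_part[unname(disease_category[diseases])]),
                  diseases)
}

#' Category-held-out fold assignments for the disease split
#'
#' Splits at the disease-*category* level (e.g. top MeSH category) so that
#' every category lands wholly in train, validation or test, with an
#' approximate 8:1:1 category ratio, repeated `n_repeats` times under
#' different shuffles.
#'
#' @param pairs data.frame with columns drug, disease.
#' @param disease_category named character vector disease -> category.
#' @param plan a [cv_plan()] (`scheme` is ignored; repeats/ratios/seed used).
#' @return list of length `n_repeats`; each element is a named character
#'   vector disease -> `"train"`/`"validation"`/`"test"`.
#' @export
disease_split_folds <- function(pairs, disease_category, plan = cv_plan()) {
  diseases <- unique(pairs$disease)
  lapply(seq_len(plan$n_repeats), function(r) {
    disease_split_partition(diseases, disease_category, plan$ratios,
                            seed = derive_seed(plan$seed, paste0("split-", r)))
  })
}

#' Train an ensemble of association classifiers
#'
#' Fits `n_models` boosted-tree classifiers, each on the positive pairs plus
#' its own disjoint negative set; [rank_candidates()] averages their
#' probabilities.
#'
#' @param e embedding space.
#' @param positives data.frame with columns drug, disease (known treatments).
#' @param n_models ensemble size (default 10).
#' @param nrounds,max_depth boosting hyperparameters.
#' @param seed integer seed.
#' @return list of fitted classifiers.
#' @export
train_dda_models <- function(e, positives, n_models = 10, nrounds = 500,
                             max_depth = 5, seed = 1) {
  fpos <- make_pair_features(e, transform(positives, label = 1L))
  xpos <- attr(fpos, "x")
  negs <- sample_negatives(e, fpos, n_sets = n_models,
                           seed = derive_seed(seed, "ensemble-negatives"))
  lapply(seq_len(n_models), function(i) {
    fneg <- make_pair_features(e, negs[[i]])
    x <- rbind(xpos, attr(fneg, "x"))
    y <- c(rep(1L, nrow(xpos)), rep(0L, nrow(fneg)))
    fit_booster(x, y, nrounds = nrounds, max_depth = max_depth)
  })
}

#' Rank repurposing candidates for a disease
#'
#' Scores every drug not already positively linked to the query disease with
#' each classifier in the ensemble, averages the probabilities, and returns
#' the candidates sorted by mean probability (ties broken by drug id).
#'
#' @param models list of classifiers from [train_dda_models()] or
#'   cross-validation.
#' @param e embedding space.
#' @param query_disease embedded disease node id.
#' @param known data.frame of known pairs (columns drug, disease, label);
#'   drugs with label 1 for the query are excluded from the candidate set.
#' @return data.frame with columns rank, drug, mean_prob, sd.
#' @export
rank_candidates <- function(models, e, query_disease, known = NULL) {
  if (!query_disease %in% rownames(e$vectors)) {
    stop(sprintf("query disease '%s' is not embedded", query_disease))
  }
  if (length(models) == 0) stop("no trained models")
  drugs <- names(e$node_type)[e$node_type == "drug"]
  if (!is.null(known)) {
    lab <- if (is.null(known$label)) rep(1L, nrow(known)) else known$label
    exclude <- known$drug[known$disease == query_disease & lab == 1]
    drugs <- setdiff(drugs, exclude)
  }
  drugs <- sort(drugs)
  if (length(drugs) == 0) stop("no candidate drugs")
  x <- e$vectors[drugs, , drop = FALSE] -
    matrix(e$vectors[query_disease, ], nrow = length(drugs),
           ncol = e$dim, byrow = TRUE)
  probs <- vapply(models, function(m) predict_booster(m, x), numeric(length(drugs)))
  probs <- matrix(probs, nrow = length(drugs))
  mp <- rowMeans(probs)
  sdp <- apply(probs, 1, stats::sd)
  if (length(models) == 1) sdp <- rep(0, length(drugs))
  ord <- order(-mp, drugs)
  data.frame(rank = seq_along(drugs), drug = drugs[ord],
             mean_prob = mp[ord], sd = sdp[ord],
             stringsAsFactors = FALSE)
}

#' Write cross-validation metrics / rankings as TSV
#'
#' @param x a `semwalk_cv` table or [rank_candidates()] output; `path` TSV.
#' @export
write_metrics <- function(x, path) {
  write_tsv_commented(as.data.frame(x), path, names(as.data.frame(x)))
  invisible(x)
}
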