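#' Fit the semantic-teleport walk embedding and association model
#'
#' End-to-end fit on a knowledge graph: (1) strips treatment edges so the
#' embedding never sees the labels, (2) builds drug and disease semantic
#' similarity matrices from the hierarchies, (3) trains the edge-type
#' transition matrix by EM, (4) samples teleport-guided random walks,
#' (5) trains node-type-aware skip-gram embeddings, and (6) fits an ensemble
#' of boosted-tree treatment classifiers on subtracted pair vectors, each
#' with its own disjoint negative set.
#'
#' @param graph a [knowledge_graph()].
#' @param drug_hierarchy,disease_hierarchy [ontology()] objects with entity
#'   maps for drug/disease nodes; either may be `NULL` (no teleport for that
#'   type).
#' @param pairs labeled positive (drug, disease) pairs for the classifier.
#' @param treat_edge_type treatment edge type to remove before embedding
#'   (skipped when absent from the graph).
#' @param cutoff similarity mask threshold (default 0.4).
#' @param teleport `"semantic"`, `"none"` or `"random"` (ablations).
#' @param params a [walk_params()].
#' @param dim,window,negatives,epochs skip-gram settings (defaults 128, 4,
#'   5, 5).
#' @param n_models classifier ensemble size (default 10).
#' @param nrounds,max_depth boosting rounds (500) and maximum depth (5).
#' @param n_iter_em EM iterations for the transition matrix.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return Object of class `"semwalk"` with elements `embedding`, `models`,
#'   `similarity` (list drug/disease), `transition`, `corpus`, `pairs`,
#'   `unreachable`, and the call parameters in `settings`.
#' @seealso [predict.semwalk()], [rank_candidates()], [cross_validate()]
#' @export
semwalk <- function(graph, drug_hierarchy = NULL, disease_hierarchy = NULL,
                    pairs = NULL, treat_edge_type = "treats", cutoff = 0.4,
                    teleport = c("semantic", "none", "random"),
                    params = NULL, dim = 128, window = 4, negatives = 5,
                    epochs = 5, n_models = 10, nrounds = 500, max_depth = 5,
                    n_iter_em = 5, seed = 1) {
  teleport <- match.arg(teleport)
  if (is.null(params)) params <- walk_params(seed = derive_seed(seed, "walk"))

  g <- graph
  if (!is.null(treat_edge_type) && treat_edge_type %in% g$edges$edge_type) {
    g <- remove_edges_by_type(g, treat_edge_type)
  }

  sim <- list()
  if (teleport != "none") {
    if (!is.null(drug_hierarchy)) {
      sim$drug <- build_similarity_matrix(g, drug_hierarchy, "drug", cutoff)
    }
    if (!is.null(disease_hierarchy)) {
      sim$disease <- build_similarity_matrix(g, disease_hierarchy, "disease",
                                             cutoff)
    }
  }

  etm <- train_transition_matrix(g, params, n_iter = n_iter_em)
  corpus <- sample_walks(g, M = etm, sim = sim, params = params,
                         teleport = teleport)
  emb <- train_embeddings(corpus, g$node_type, dim = dim, window = window,
                          negatives = negatives, epochs = epochs,
                          seed = derive_seed(seed, "embed"))

  models <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pos <- pairs[is.na(pairs$label) | pairs$label == 1, c("drug", "disease")]
    models <- train_dda_models(emb, pos, n_models = n_models,
                               nrounds = nrounds, max_depth = max_depth,
                               seed = derive_seed(seed, "models"))
  }

  structure(list(
    embedding = emb, models = models, similarity = sim, transition = etm,
    corpus = corpus, pairs = pairs, graph = g,
    unreachable = corpus$unreachable,
    settings = list(teleport = teleport, cutoff = cutoff, params = params,
                    dim = dim, window = window, negatives = negatives,
                    epochs = epochs, n_models = n_models, nrounds = nrounds,
                    max_depth = max_depth, n_iter_em = n_iter_em,
                    seed = seed)),
    class = "semwalk")
}

#' @export
print.semwalk <- function(x, ...) {
  cat(sprintf("Semantic-teleport walk model (teleport: %s, tau = %g, cutoff = %g)\n",
              x$settings$teleport, x$settings$params$tau, x$settings$cutoff))
  print(x$embedding)
  if (!is.null(x$models)) {
    cat(sprintf("Classifier ensemble: %d boosted-tree models (%d rounds, depth %d)\n",
                length(x$models), x$settings$nrounds, x$settings$max_depth))
  }
  invisible(x)
}

#' @export
summary.semwalk <- function(object, ...) {
  x <- object
  cat("Stages:\n")
  for (ty in names(x$similarity)) {
    cat(sprintf("  similarity (%s): %d pairs above cutoff %.2f\n",
                ty, nrow(x$similarity[[ty]]$entries), x$settings$cutoff))
  }
  cat(sprintf("  transition matrix: %d edge types, %d EM iterations\n",
              length(x$transition$edge_types), x$transition$n_iter_run))
  print(x$corpus)
  print(x$embedding)
  if (!is.null(x$models)) {
    cat(sprintf("  ensemble: %d classifiers on %d positive pairs\n",
                length(x$models), sum(x$pairs$label == 1, na.rm = TRUE)))
  }
  invisible(x)
}

#' Predict treatment probabilities or rank candidates
#'
#' With `disease` given, returns the full repurposing ranking for that
#' disease ([rank_candidates()]); with `pairs` given, returns the
#' ensemble-mean treatment probability per pair.
#'
#' @param object a fitted [semwalk()] model (with classifiers).
#' @param disease a disease node id to rank candidate drugs for.
#' @param pairs data.frame of (drug, disease) pairs to score.
#' @param ... unused.
#' @export
predict.semwalk <- function(object, disease = NULL, pairs = NULL, ...) {
  if (is.null(object$models)) stop("model was fitted without labeled pairs")
  if (!is.null(disease)) {
    return(rank_candidates(object$models, object$embedding, disease,
                           known = object$pairs))
  }
  if (is.null(pairs)) stop("supply either a disease or a pair table")
  f <- make_pair_features(object$embedding, pairs)
  x <- attr(f, "x")
  probs <- vapply(object$models, function(m) predict_booster(m, x),
                  numeric(nrow(f)))
  probs <- matrix(probs, nrow = nrow(f))
  f$mean_prob <- rowMeans(probs)
  f$sd <- apply(probs, 1, stats::sd)
  f
}

#' Plot a 2-D principal-component view of the embedding
#'
#' @param x a fitted model or embedding space.
#' @param ... passed to [graphics::plot()].
#' @export
plot.semwalk <- function(x, ...) {
  e <- if (inherits(x, "semwalk")) x$embedding else x
  pc <- stats::prcomp(e$vectors, rank. = 2)
  types <- factor(e$node_type[rownames(e$vectors)])
  graphics::plot(pc$x[, 1], pc$x[, 2], col = as.integer(types),
                 pch = 16, cex = 0.6, xlab = "PC1", ylab = "PC2", ...)
  graphics::legend("topright", legend = levels(types),
                   col = seq_along(levels(types)), pch = 16, cex = 0.8)
  invisible(pc)
}

#' Run the full pipeline from a configuration and write all artifacts
#'
#' Reads the inputs named in the configuration, fits [semwalk()], and writes
#' every intermediate artifact (similarity matrices, transition matrix, walk
#' corpus and traces, embeddings, cross-validation metrics) plus a manifest
#' recording the configuration, seeds, package version and an MD5 checksum
#' of every artifact. Re-running with an identical configuration reproduces
#' identical artifacts.
#'
#' @param config a YAML file path or a named list. Recognized keys:
#'   `edge_file`, `node_type_file`, `pair_file`, `drug_hierarchy_file`,
#'   `drug_mapping_file`, `disease_hierarchy_file`, `disease_mapping_file`,
#'   `output_dir`, `seed`, and any of `tau`, `cutoff`, `num_walks_per_node`,
#'   `walk_length`, `p`, `q`, `dim`, `window`, `negatives`, `epochs`,
#'   `n_models`, `nrounds`, `max_depth`, `n_iter_em`, `teleport`
#'   (`semantic`/`none`/`random`), `treat_edge_type`, `run_cv`,
#'   `cv_repeats`, `cv_folds`.
#' @return the output directory, invisibly; artifacts and `manifest.json`
#'   inside it.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  req <- c("edge_file", "node_type_file", "output_dir")
  for (k in req) {
    if (is.null(cfg[[k]])) stop(sprintf("config key '%s' is required", k))
  }
  for (k in c("edge_file", "node_type_file", "pair_file",
              "drug_hierarchy_file", "drug_mapping_file",
              "disease_hierarchy_file", "disease_mapping_file")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop(sprintf("input path not found: %s (config key '%s')", cfg[[k]], k))
    }
  }
  seed <- as.integer(cfg[["seed"]] %||% 1)
  out <- cfg[["output_dir"]]
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  g <- stage("read_graph", read_graph(cfg[["edge_file"]], cfg[["node_type_file"]]))
  dh <- zh <- NULL
  if (!is.null(cfg[["drug_hierarchy_file"]])) {
    dh <- stage("read_drug_hierarchy",
                read_hierarchy(cfg[["drug_hierarchy_file"]], cfg[["drug_mapping_file"]]))
  }
  if (!is.null(cfg[["disease_hierarchy_file"]])) {
    zh <- stage("read_disease_hierarchy",
                read_hierarchy(cfg[["disease_hierarchy_file"]],
                               cfg[["disease_mapping_file"]]))
  }
  pairs <- if (!is.null(cfg[["pair_file"]])) {
    stage("read_pairs", read_pairs(cfg[["pair_file"]]))
  } else NULL

  params <- walk_params(
    num_walks_per_node = cfg[["num_walks_per_node"]] %||% 100,
    walk_length = cfg[["walk_length"]] %||% 4,
    tau = cfg[["tau"]] %||% 0.3, p = cfg[["p"]] %||% 1, q = cfg[["q"]] %||% 1,
    seed = derive_seed(seed, "walk"))
  fit <- stage("fit", semwalk(
    g, dh, zh, pairs,
    treat_edge_type = cfg[["treat_edge_type"]] %||% "treats",
    cutoff = cfg[["cutoff"]] %||% 0.4,
    teleport = cfg[["teleport"]] %||% "semantic",
    params = params,
    dim = cfg[["dim"]] %||% 128, window = cfg[["window"]] %||% 4,
    negatives = cfg[["negatives"]] %||% 5, epochs = cfg[["epochs"]] %||% 5,
    n_models = cfg[["n_models"]] %||% 10, nrounds = cfg[["nrounds"]] %||% 500,
    max_depth = cfg[["max_depth"]] %||% 5, n_iter_em = cfg[["n_iter_em"]] %||% 5,
    seed = seed))

  arts <- character(0)
  add <- function(path) arts <<- c(arts, path)
  for (ty in names(fit$similarity)) {
    p <- file.path(out, sprintf("similarity_%s.tsv", ty))
    write_similarity(fit$similarity[[ty]], p); add(p)
  }
  p <- file.path(out, "transition_matrix.tsv")
  utils::write.table(fit$transition$M, p, sep = "\t", quote = FALSE)
  add(p)
  write_walks(fit$corpus, file.path(out, "walks.txt"),
              file.path(out, "walk_traces.txt"))
  add(file.path(out, "walks.txt")); add(file.path(out, "walk_traces.txt"))
  p <- file.path(out, "embeddings.tsv")
  write_embeddings(fit$embedding, p); add(p)

  if (!is.null(pairs) && isTRUE(cfg[["run_cv"]] %||% TRUE)) {
    f <- make_pair_features(fit$embedding, pairs)
    plan <- cv_plan(n_repeats = cfg[["cv_repeats"]] %||% 10,
                    n_folds = cfg[["cv_folds"]] %||% 10,
                    seed = derive_seed(seed, "cv"))
    cv <- stage("cross_validate",
                cross_validate(f, plan, e = fit$embedding,
                               nrounds = cfg[["nrounds"]] %||% 500,
                               max_depth = cfg[["max_depth"]] %||% 5))
    p <- file.path(out, "metrics.tsv")
    write_metrics(cv, p); add(p)
    p <- file.path(out, "metrics_summary.tsv")
    write_metrics(attr(cv, "summary"), p); add(p)
  }

  # output_dir is not part of the scientific configuration: two runs into
  # different directories must yield identical manifests
  mcfg <- cfg[setdiff(names(cfg), "output_dir")]
  manifest <- list(
    config = mcfg[order(names(mcfg))], seed = seed,
    package_version = as.character(utils::packageVersion("semwalk")),
    unreachable_nodes = fit$unreachable,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(arts)), basename(arts))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
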