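#' Walk sampling parameters
#'
#' Bundles the knobs of the teleport-guided random walk. Defaults are the
#' study conditions: 100 walks of length 4 (nodes, i.e. 3 steps) started at
#' every node, teleport factor `tau = 0.3`, and neutral node2vec bias
#' `p = q = 1`.
#'
#' @param num_walks_per_node walks started at each node.
#' @param walk_length number of nodes per walk (a length-4 walk has 3 steps).
#' @param tau teleport factor in \[0, 1\]: probability of the teleport action
#'   at a drug/disease node whose similarity row is non-empty.
#' @param p node2vec return parameter (weight 1/p for stepping back).
#' @param q node2vec in-out parameter (weight 1/q for moving away).
#' @param seed integer seed; every walk consumes a substream derived from
#'   (seed, start node, walk index).
#' @return list of class `"semwalk_params"`.
#' @export
walk_params <- function(num_walks_per_node = 100, walk_length = 4,
                        tau = 0.3, p = 1, q = 1, seed = 1) {
  stopifnot(num_walks_per_node >= 1, walk_length >= 1,
            tau >= 0, tau <= 1, p > 0, q > 0)
  structure(list(num_walks_per_node = as.integer(num_walks_per_node),
                 walk_length = as.integer(walk_length),
                 tau = tau, p = p, q = q, seed = as.integer(seed)),
            class = "semwalk_params")
}

# teleport-eligible node types
TELEPORT_TYPES <- c("drug", "disease")

# Build the teleport CSR rows for the sampler. mode "semantic" uses the
# similarity matrices; "none" leaves all rows empty; "random" replaces each
# drug/disease node's row by seeded uniform weights over all other nodes of
# the same type (ablation control).
tele_csr <- function(idx, sim, mode, seed = 1) {
  n <- idx$n
  rows <- vector("list", n)
  if (mode == "semantic") {
    for (s in sim) {
      if (is.null(s)) next
      e <- s$entries
      if (nrow(e) == 0) next
      ia <- idx$id[e$a]; ib <- idx$id[e$b]
      for (k in seq_len(nrow(e))) {
        rows[[ia[k] + 1L]] <- c(rows[[ia[k] + 1L]],
                                stats::setNames(e$sim[k], ib[k]))
        rows[[ib[k] + 1L]] <- c(rows[[ib[k] + 1L]],
                                stats::setNames(e$sim[k], ia[k]))
      }
    }
  } else if (mode == "random") {
    with_seed(seed, {
      for (ty in TELEPORT_TYPES) {
        members <- which(idx$node_type == ty) - 1L
        if (length(members) < 2) next
        for (v in members) {
          others <- setdiff(members, v)
          rows[[v + 1L]] <- stats::setNames(stats::runif(length(others)), others)
        }
      }
    })
  }
  lens <- vapply(rows, length, integer(1))
  ptr <- c(0L, cumsum(lens))
  nbr <- as.integer(unlist(lapply(rows, function(r) as.integer(names(r)))))
  w <- as.numeric(unlist(rows, use.names = FALSE))
  list(ptr = as.integer(ptr), nbr = nbr %||% integer(0), w = w %||% numeric(0))
}

#' Next-node distribution of the teleport-guided walk
#'
#' Reference implementation of the per-step law; the compiled sampler in
#' [sample_walks()] draws from exactly this distribution. At a drug/disease
#' node with a non-empty similarity row, mass `tau` teleports proportionally
#' to that row; the remaining mass `1 - tau` (all mass elsewhere) traverses
#' graph edges with unnormalized weight
#' `w_vn * M[type(u,v), type(v,n)] * alpha_pq(n, u)`, where the node2vec
#' bias `alpha_pq` is `1/p` for returning to the previous node, 1 for moving
#' to a neighbour of the previous node and `1/q` otherwise. At a walk start
#' or right after a teleport there is no previous node: the transition-matrix
#' factor and `alpha` both drop out.
#'
#' @param g a [knowledge_graph()].
#' @param prev previous node id, or `NULL` at a walk start / after teleport.
#' @param curr current node id.
#' @param M edge-type transition matrix from [train_transition_matrix()], or
#'   `NULL` for an all-ones (untrained) matrix.
#' @param sim named list of similarity matrices keyed by node type (e.g.
#'   `list(drug = ..., disease = ...)`), or `NULL`/empty for no teleport.
#' @param params a [walk_params()].
#' @param prev_edge_type edge type of the arriving step; required when `prev`
#'   is given and the pair (prev, curr) is connected by edges of several
#'   types.
#' @return named numeric vector of probabilities over candidate next nodes
#'   (teleport targets and graph neighbours pooled), summing to 1, with
#'   attributes `teleport_mass` and `actions` (per-entry `"teleport"` /
#'   `"traverse"`).
#' @export
step_distribution <- function(g, prev = NULL, curr, M = NULL, sim = NULL,
                              params = walk_params(),
                              prev_edge_type = NULL) {
  stopifnot(curr %in% g$nodes)
  e <- g$edges
  nb <- e[e$source == curr | e$target == curr, , drop = FALSE]
  nb$other <- ifelse(nb$source == curr, nb$target, nb$source)

  row <- numeric(0)
  if (g$node_type[[curr]] %in% TELEPORT_TYPES && length(sim) > 0) {
    s <- sim[[g$node_type[[curr]]]]
    if (!is.null(s)) row <- sim_row(s, curr)
  }
  tau_eff <- if (length(row) > 0) params$tau else 0
  if (nrow(nb) == 0) {
    if (length(row) == 0) stop(sprintf("dead-end node '%s'", curr))
    tau_eff <- 1
  }

  out <- stats::setNames(numeric(0), character(0))
  act <- character(0)
  if (tau_eff > 0) {
    tp <- tau_eff * row / sum(row)
    out <- c(out, tp)
    act <- c(act, rep("teleport", length(tp)))
  }
  if (tau_eff < 1 && nrow(nb) > 0) {
    w <- nb$weight
    if (!is.null(prev)) {
      if (inherits(M, "semwalk_etm")) M <- M$M
      if (is.null(M)) {
        m <- length(g$edge_types)
        M <- matrix(1, m, m, dimnames = list(g$edge_types, g$edge_types))
      }
      if (is.null(prev_edge_type)) {
        cand <- e[(e$source == prev & e$target == curr) |
                  (e$source == curr & e$target == prev), , drop = FALSE]
        if (nrow(cand) == 0) stop("prev is not adjacent to curr")
        if (length(unique(cand$edge_type)) > 1) {
          stop("multiple edge types between prev and curr; supply prev_edge_type")
        }
        prev_edge_type <- cand$edge_type[1]
      }
      w <- w * M[prev_edge_type, nb$edge_type]
      prev_nbrs <- unique(c(
        e$target[e$source == prev], e$source[e$target == prev]))
      alpha <- ifelse(nb$other == prev, 1 / params$p,
                      ifelse(nb$other %in% prev_nbrs, 1, 1 / params$q))
      w <- w * alpha
    }
    tr <- (1 - tau_eff) * w / sum(w)
    names(tr) <- nb$other
    out <- c(out, tr)
    act <- c(act, rep("traverse", length(tr)))
  }
  # pool duplicate candidate nodes (multi-edges / teleport-and-traverse)
  pooled <- tapply(out, names(out), sum)
  res <- stats::setNames(as.numeric(pooled), names(pooled))
  attr(res, "teleport_mass") <- tau_eff
  attr(res, "entries") <- data.frame(node = names(out), prob = unname(out),
                                     action = act, stringsAsFactors = FALSE)
  res
}

#' Sample a corpus of teleport-guided random walks
#'
#' Starts `num_walks_per_node` walks at every node (regardless of type) and
#' grows each to `walk_length` nodes by drawing steps from
#' [step_distribution()]. A teleport step has no edge type and resets the
#' walk's memory: the following step behaves like a fresh start (no node2vec
#' bias, no transition-matrix factor). Start nodes with neither graph
#' neighbours nor a similarity row are skipped and reported in the
#' `unreachable` element.
#'
#' @param g a [knowledge_graph()].
#' @param M edge-type transition matrix ([train_transition_matrix()]) or
#'   `NULL` for all-ones.
#' @param sim named list of similarity matrices by node type (used when
#'   `teleport = "semantic"`).
#' @param params a [walk_params()].
#' @param teleport `"semantic"` (default), `"none"` (tau forced to 0), or
#'   `"random"` (similarity rows replaced by seeded random weights over
#'   same-type nodes; ablation control).
#' @param start_nodes optional subset of nodes to start from; defaults to
#'   all nodes.
#' @return Object of class `"semwalk_corpus"`: list with `walks` (list of
#'   character vectors of node ids), `actions` and `edge_types` (parallel
#'   per-step traces, `NA` edge type for teleports), `params`, and
#'   `unreachable` (skipped start nodes).
#' @export
sample_walks <- function(g, M = NULL, sim = NULL, params = walk_params(),
                         teleport = c("semantic", "none", "random"),
                         start_nodes = NULL) {
  teleport <- match.arg(teleport)
  idx <- kg_index(g)
  m <- length(idx$edge_types)
  if (is.null(M)) {
    Mm <- matrix(1, max(m, 1), max(m, 1))
  } else {
    Mm <- M$M
    if (!identical(M$edge_types, idx$edge_types)) {
      ord <- match(idx$edge_types, M$edge_types)
      if (anyNA(ord)) stop("transition matrix edge types do not cover the graph")
      Mm <- Mm[ord, ord, drop = FALSE]
    }
  }
  tele <- tele_csr(idx, sim, mode = if (teleport == "none") "none" else teleport,
                   seed = derive_seed(params$seed, "random-teleport"))
  use_tele <- teleport != "none" && params$tau > 0

  starts <- if (is.null(start_nodes)) idx$nodes else start_nodes
  sidx <- idx$id[starts]
  deg <- diff(idx$adj_ptr)[sidx + 1L]
  tdeg <- if (use_tele) diff(tele$ptr)[sidx + 1L] else rep(0L, length(sidx))
  ok <- deg > 0 | tdeg > 0
  unreachable <- starts[!ok]
  sidx <- sidx[ok]
  if (length(sidx) == 0) stop("no start node has a valid first step")

  res <- .cpp_sample_walks(idx$adj_ptr, idx$adj_nbr, idx$adj_et, idx$adj_w,
                           Mm, tele$ptr, tele$nbr, tele$w,
                           if (use_tele) params$tau else 0,
                           params$p, params$q,
                           as.integer(sidx),
                           params$num_walks_per_node, params$walk_length,
                           as.double(params$seed), use_tele)
  wm <- res$walks
  am <- res$actions; em <- res$etypes
  nw <- nrow(wm)
  # vectorized matrix -> ragged-list conversion (dead-end truncations are
  # padded with -1 and dropped here)
  wv <- as.integer(t(wm)); wg <- rep(seq_len(nw), each = ncol(wm))
  keep <- wv >= 0
  walks <- split(idx$nodes[wv[keep] + 1L], wg[keep])
  av <- as.integer(t(am)); ag <- rep(seq_len(nw), each = ncol(am))
  akeep <- av >= 0
  actions <- split(c("traverse", "teleport")[av[akeep] + 1L], ag[akeep])
  ev <- as.integer(t(em))[akeep]
  edge_types <- split(ifelse(ev >= 0, idx$edge_types[ev + 1L],
                             NA_character_), ag[akeep])
  # walks with zero recorded steps vanish from split(); restore empties
  fix_empty <- function(lst, template) {
    out <- vector("list", nw)
    out[as.integer(names(lst))] <- lst
    out[vapply(out, is.null, logical(1))] <- list(template)
    out
  }
  walks <- fix_empty(walks, character(0))
  actions <- fix_empty(actions, character(0))
  edge_types <- fix_empty(edge_types, character(0))
  names(walks) <- names(actions) <- names(edge_types) <- NULL
  structure(list(walks = walks, actions = actions, edge_types = edge_types,
                 params = params, teleport = teleport,
                 unreachable = unreachable),
            class = "semwalk_corpus")
}

#' @export
print.semwalk_corpus <- function(x, ...) {
  nt <- sum(vapply(x$actions, function(a) sum(a == "teleport"), numeric(1)))
  ns <- sum(lengths(x$actions))
  cat(sprintf("Walk corpus: %d walks, %d steps (%.1f%% teleports), teleport mode '%s'\n",
              length(x$walks), ns, if (ns > 0) 100 * nt / ns else 0, x$teleport))
  if (length(x$unreachable) > 0) {
    cat(sprintf("  %d unreachable start nodes skipped\n", length(x$unreachable)))
  }
  invisible(x)
}

#' Fraction of teleport actions among eligible step decisions
#'
#' A decision is eligible when taken at a node in `eligible_nodes` —
#' typically the drug/disease nodes with a non-empty similarity row. With
#' teleport factor `tau`, the expected fraction is `tau`.
#'
#' @param corpus a [sample_walks()] corpus.
#' @param eligible_nodes character vector of node ids.
#' @return list with `n_decisions`, `n_teleports`, `fraction`.
#' @export
teleport_fraction <- function(corpus, eligible_nodes) {
  ns <- lengths(corpus$actions)
  origin <- unlist(mapply(function(w, k) w[seq_len(k)], corpus$walks, ns,
                          SIMPLIFY = FALSE), use.names = FALSE)
  action <- unlist(corpus$actions, use.names = FALSE)
  el <- origin %in% eligible_nodes
  n_dec <- sum(el)
  n_tel <- sum(el & action == "teleport")
  list(n_decisions = n_dec, n_teleports = n_tel,
       fraction = if (n_dec > 0) n_tel / n_dec else NA_real_)
}

#' Train the edge-type transition matrix by expectation-maximization
#'
#' Learns how likely the walker is to follow an edge of type `j` right after
#' arriving through an edge of type `i`. Starting from an all-ones matrix,
#' each iteration (maximization) samples a full walk set biased by the
#' current matrix — without teleport, since the matrix models edge-type
#' co-occurrence on the graph itself — and (expectation) re-estimates every
#' entry as `sigmoid(Pearson(v_i, v_j))`, where `v_i` holds the per-walk
#' occurrence counts of edge type `i`. Zero-variance count vectors get
#' correlation 0 (a neutral `sigmoid(0) = 0.5`). Iteration stops after
#' `n_iter` rounds or when no entry moves by more than `tol`.
#'
#' @param g a [knowledge_graph()].
#' @param params a [walk_params()] (tau is ignored; training runs without
#'   teleport).
#' @param n_iter maximum EM iterations.
#' @param tol early-stopping threshold on `max |delta M|`.
#' @return Object of class `"semwalk_etm"`: list with `M` (m x m matrix,
#'   dimnames = edge types), `edge_types`, `n_iter_run`.
#' @export
train_transition_matrix <- function(g, params = walk_params(), n_iter = 5,
                                    tol = 1e-3) {
  ets <- g$edge_types
  m <- length(ets)
  if (m < 1) stop("graph has no edges")
  M <- matrix(1, m, m, dimnames = list(ets, ets))
  if (m == 1) {
    warning("single edge type: transition matrix training is a no-op")
    return(structure(list(M = M, edge_types = ets, n_iter_run = 0L),
                     class = "semwalk_etm"))
  }
  obj <- structure(list(M = M, edge_types = ets, n_iter_run = 0L),
                   class = "semwalk_etm")
  for (it in seq_len(n_iter)) {
    pp <- params
    pp$seed <- derive_seed(params$seed, paste0("etm-iter-", it))
    corpus <- sample_walks(g, M = obj, sim = NULL, params = pp,
                           teleport = "none")
    V <- edge_type_counts(corpus, ets)
    Mnew <- em_update(V)
    delta <- max(abs(Mnew - obj$M))
    obj$M <- Mnew
    obj$n_iter_run <- it
    if (delta < tol) break
  }
  dimnames(obj$M) <- list(ets, ets)
  obj
}

# per-walk occurrence counts of each edge type (walks x types)
edge_type_counts <- function(corpus, edge_types) {
  nw <- length(corpus$walks)
  et <- unlist(corpus$edge_types, use.names = FALSE)
  wid <- rep.int(seq_len(nw), lengths(corpus$edge_types))
  keep <- !is.na(et)
  tab <- table(factor(wid[keep], levels = seq_len(nw)),
               factor(et[keep], levels = edge_types))
  V <- matrix(as.integer(tab), nrow = nw, ncol = length(edge_types),
              dimnames = list(NULL, edge_types))
  V
}

# expectation step: sigmoid of pairwise Pearson correlation of count vectors
em_update <- function(V) {
  m <- ncol(V)
  M <- matrix(NA_real_, m, m)
  sds <- apply(V, 2, stats::sd)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      r <- if (sds[i] == 0 || sds[j] == 0) 0 else stats::cor(V[, i], V[, j])
      M[i, j] <- stats::plogis(r)
    }
  }
  M
}

#' @export
print.semwalk_etm <- function(x, ...) {
  cat(sprintf("Edge-type transition matrix (%d types, %d EM iterations)\n",
              length(x$edge_types), x$n_iter_run))
  print(round(x$M, 4))
  invisible(x)
}

#' Read / write a walk corpus as plain text
#'
#' Walks file: one walk per line, space-separated node ids. Trace file: one
#' line per walk with comma-separated `action:edge_type` tokens (`teleport:.`
#' for teleport steps).
#'
#' @param corpus a walk corpus; `walk_file`, `trace_file` paths.
#' @export
write_walks <- function(corpus, walk_file, trace_file = NULL) {
  writeLines(vapply(corpus$walks, paste, "", collapse = " "), walk_file)
  if (!is.null(trace_file)) {
    tr <- vapply(seq_along(corpus$actions), function(k) {
      a <- corpus$actions[[k]]; t <- corpus$edge_types[[k]]
      if (length(a) == 0) return("")
      paste(paste0(a, ":", ifelse(is.na(t), ".", t)), collapse = ",")
    }, "")
    writeLines(tr, trace_file)
  }
  invisible(corpus)
}

#' @rdname write_walks
#' @param walk_file,trace_file paths.
#' @export
read_walks <- function(walk_file, trace_file = NULL) {
  walks <- strsplit(readLines(walk_file), " ", fixed = TRUE)
  actions <- edge_types <- NULL
  if (!is.null(trace_file)) {
    tr <- readLines(trace_file)
    toks <- lapply(tr, function(x) {
      if (!nzchar(x)) return(character(0))
      strsplit(x, ",", fixed = TRUE)[[1]]
    })
    actions <- lapply(toks, function(t) sub(":.*$", "", t))
    edge_types <- lapply(toks, function(t) {
      et <- sub("^[^:]*:", "", t)
      ifelse(et == ".", NA_character_, et)
    })
  }
  structure(list(walks = walks, actions = actions, edge_types = edge_types,
                 params = NULL, teleport = NA_character_,
                 unreachable = character(0)),
            class = "semwalk_corpus")
}
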