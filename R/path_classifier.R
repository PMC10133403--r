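#' A directed pathway graph with drug-target and label annotations
#'
#' @param edges Data.frame `(from, to)` of directed edges between component
#'   identifiers (KEGG-style strings such as `"hsa:3065"`).
#' @param drug_targets Data.frame `(drug, target)`; every target must be a
#'   graph node.
#' @param ti,se Data.frames `(drug, label)` of therapeutic indications and
#'   side effects (may be empty).
#' @return A `pathway_graph`.
#' @export
pathway_graph <- function(edges, drug_targets,
                          ti = NULL, se = NULL) {
  stopifnot(all(c("from", "to") %in% names(edges)),
            all(c("drug", "target") %in% names(drug_targets)))
  empty <- data.frame(drug = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(ti) || nrow(ti) == 0L) ti <- empty
  if (is.null(se) || nrow(se) == 0L) se <- empty
  names(ti) <- names(se) <- c("drug", "label")
  nodes <- sort(unique(c(edges$from, edges$to, drug_targets$target)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  missing_t <- setdiff(drug_targets$target, nodes)
  if (length(missing_t) > 0L) {
    stop("drug target(s) not in graph: ", paste(missing_t, collapse = ", "))
  }
  structure(list(graph = g, edges = edges, drug_targets = drug_targets,
                 ti = ti, se = se),
            class = "pathway_graph")
}

#' Read a pathway graph from edge-list and drug tables
#'
#' @param edges_path TSV `(from, to)`.
#' @param drug_targets_path TSV `(drug, target)`.
#' @param ti_path,se_path Optional TSVs `(drug, label)`.
#' @return A `pathway_graph`.
#' @export
read_pathway_graph <- function(edges_path, drug_targets_path,
                               ti_path = NULL, se_path = NULL) {
  rd <- function(p) if (is.null(p)) NULL else
    utils::read.delim(p, colClasses = "character", check.names = FALSE)
  pathway_graph(rd(edges_path), rd(drug_targets_path),
                ti = rd(ti_path), se = rd(se_path))
}

#' Node identifiers labeled as drug targets for a given label
#'
#' @param graph A `pathway_graph`.
#' @param label A TI/SE label id.
#' @param kind `"ti"` or `"se"`.
#' @return Character vector of target node ids whose drugs carry the label.
#' @export
label_targets <- function(graph, label, kind = c("ti", "se")) {
  kind <- match.arg(kind)
  tab <- graph[[kind]]
  drugs <- tab$drug[tab$label == label]
  sort(unique(graph$drug_targets$target[graph$drug_targets$drug %in% drugs]))
}

adjacency_list <- function(graph) {
  g <- graph$graph
  nodes <- igraph::V(g)$name
  adj <- igraph::adjacent_vertices(g, igraph::V(g), mode = "out")
  out <- lapply(adj, function(a) sort(a$name))
  names(out) <- nodes
  out
}

#' Enumerate drug-target-rooted paths to outdegree-0 nodes
#'
#' Depth-first enumeration (sorted-neighbor order) of all simple paths from
#' `start` to any node with outdegree 0. Cycles are handled by the
#' simple-path rule (no node is revisited); branches longer than `max_len`
#' are abandoned, and enumeration stops with a warning once `max_paths`
#' paths have been collected.
#'
#' @param graph A `pathway_graph`.
#' @param start A node id (normally a drug target).
#' @param max_len Maximum path length in nodes.
#' @param max_paths Cap on the number of returned paths.
#' @return List of character vectors (node id sequences). A start node with
#'   outdegree 0 yields the single length-1 path.
#' @export
extract_paths <- function(graph, start, max_len = 30, max_paths = 10000) {
  adj <- adjacency_list(graph)
  if (!start %in% names(adj)) stop("start node not in graph: ", start)
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 64L)
  acc$n <- 0L
  acc$truncated <- FALSE
  visit <- function(node, path, visited) {
    if (acc$truncated) return()
    succ <- adj[[node]]
    succ <- succ[!(succ %in% visited)]
    if (length(adj[[node]]) == 0L) {
      if (acc$n >= max_paths) {
        acc$truncated <- TRUE
        return()
      }
      acc$n <- acc$n + 1L
      if (acc$n > length(acc$paths)) {
        length(acc$paths) <- 2L * length(acc$paths)
      }
      acc$paths[[acc$n]] <- path
      return()
    }
    if (length(path) >= max_len) return()
    for (s in succ) visit(s, c(path, s), c(visited, s))
  }
  visit(start, start, start)
  if (acc$truncated) {
    warning("path enumeration truncated at max_paths = ", max_paths)
  }
  acc$paths[seq_len(acc$n)]
}

#' Extract the full path set of a pathway graph
#'
#' Enumerates paths from every drug-target node and returns them with their
#' start nodes.
#'
#' @inheritParams extract_paths
#' @return A `path_set`: list with `components` (list of id sequences) and
#'   `start` (character vector).
#' @export
extract_all_paths <- function(graph, max_len = 30, max_paths = 10000) {
  targets <- sort(unique(graph$drug_targets$target))
  comp <- list()
  start <- character(0)
  for (t in targets) {
    p <- extract_paths(graph, t, max_len = max_len, max_paths = max_paths)
    comp <- c(comp, p)
    start <- c(start, rep(t, length(p)))
  }
  structure(list(components = comp, start = start), class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat("path_set:", length(x$components), "paths from",
      length(unique(x$start)), "start nodes\n")
  invisible(x)
}

#' Levenshtein edit distance between two identifier sequences
#'
#' Dynamic-programming edit distance with unit insertion, deletion and
#' substitution costs over whole component identifiers (a path is the word,
#' a component the character).
#'
#' @param n,m Character (or integer) vectors; may be empty.
#' @return Non-negative integer.
#' @export
edit_distance <- function(n, m) {
  ln <- length(n)
  lm <- length(m)
  if (ln == 0L) return(lm)
  if (lm == 0L) return(ln)
  jj <- seq_len(lm)
  prev <- 0:lm
  for (i in seq_len(ln)) {
    x <- as.numeric(n[i] != m)
    tmp <- pmin(prev[-1L] + 1, prev[-(lm + 1L)] + x)  # deletion, substitution
    # insertions propagate left to right: cost j - k on top of tmp[k]
    cur <- jj + cummin(c(i, tmp - jj))[-1L]
    prev <- c(i, cur)
  }
  as.integer(prev[lm + 1L])
}

#' Normalized path similarity
#'
#' `1 - EditDistance(N, M) / max(length(N), length(M))`; 1 iff the
#' component sequences are identical, 0 when every position must change.
#'
#' @param n,m Identifier sequences; at least one non-empty.
#' @return Real in `[0, 1]`.
#' @export
path_similarity <- function(n, m) {
  L <- max(length(n), length(m))
  if (L == 0L) stop("similarity of two empty paths is undefined")
  1 - edit_distance(n, m) / L
}

#' Pairwise similarity matrix between two path sets
#'
#' @param a,b Lists of identifier sequences (or `path_set` objects).
#' @return A `length(a) x length(b)` matrix of similarities.
#' @export
similarity_matrix <- function(a, b) {
  if (inherits(a, "path_set")) a <- a$components
  if (inherits(b, "path_set")) b <- b$components
  # integer-code the identifiers once; comparisons stay identifier-exact
  lev <- unique(unlist(c(a, b), use.names = FALSE))
  ai <- lapply(a, function(p) match(p, lev))
  bi <- lapply(b, function(p) match(p, lev))
  S <- matrix(0, length(a), length(b))
  for (i in seq_along(ai)) {
    pi <- ai[[i]]
    S[i, ] <- vapply(bi, function(pj) path_similarity(pi, pj), numeric(1))
  }
  S
}

#' Method A feature construction: PCA of the label similarity matrix
#'
#' Features of a path are its similarities to every reference path (the
#' paths whose start node is a drug target of the selected TI/SE), reduced
#' by PCA. Components are retained until the cumulative explained variance
#' reaches 99%; the centering vector and loadings are frozen at training
#' time and reapplied at prediction.
#'
#' At training time a query path may itself be one of the reference paths;
#' its self-similarity of exactly 1 would then mark "is a reference" rather
#' than anything about the label, and tree ensembles exploit that artifact
#' instead of the path structure. When `self_cols` identifies such
#' coincidences, the self-entry is replaced by the path's best non-self
#' similarity before fitting.
#'
#' @param query_paths List of identifier sequences (or `path_set`).
#' @param reference_paths Reference (label-start) paths; required when
#'   fitting.
#' @param recipe A frozen recipe from a previous fit; when supplied,
#'   `reference_paths` is taken from it and the stored loadings are applied.
#' @param self_cols Optional integer vector aligned to the query paths: the
#'   reference column that is the same path (NA when none); used only when
#'   fitting.
#' @return A list: `features` (matrix), `recipe` (`list(reference, center,
#'   rotation)`).
#' @export
features_method_a <- function(query_paths, reference_paths = NULL,
                              recipe = NULL, self_cols = NULL) {
  if (inherits(query_paths, "path_set")) query_paths <- query_paths$components
  if (!is.null(recipe)) {
    S <- similarity_matrix(query_paths, recipe$reference)
    if (ncol(S) != length(recipe$center)) stop("recipe dimension mismatch")
    F <- sweep(S, 2L, recipe$center) %*% recipe$rotation
    return(list(features = F, recipe = recipe))
  }
  if (inherits(reference_paths, "path_set")) {
    reference_paths <- reference_paths$components
  }
  if (is.null(reference_paths) || length(reference_paths) == 0L) {
    stop("no reference paths carry the selected label")
  }
  S <- similarity_matrix(query_paths, reference_paths)
  if (!is.null(self_cols)) S <- mask_self_similarity(S, self_cols)
  pr <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  v <- pr$sdev^2
  if (sum(v) <= 0) {
    ncomp <- 1L
  } else {
    ncomp <- which(cumsum(v) / sum(v) >= 0.99)[1]
  }
  rot <- pr$rotation[, seq_len(ncomp), drop = FALSE]
  recipe <- list(reference = reference_paths, center = pr$center,
                 rotation = rot)
  list(features = pr$x[, seq_len(ncomp), drop = FALSE], recipe = recipe)
}

#' Method B path clustering for one drug target
#'
#' Rows of the similarity matrix between the target's paths and all paths
#' are treated as path profiles; their Pearson correlation matrix is turned
#' into the distance `1 - r` and clustered by average-linkage hierarchical
#' clustering, cut at distance 0.2. Constant profiles (undefined
#' correlation) become singleton clusters with a warning.
#'
#' @param x_paths Paths starting at the target (list or `path_set`).
#' @param all_paths All paths (including `x_paths`).
#' @return Integer cluster id per path in `x_paths`.
#' @export
cluster_paths_method_b <- function(x_paths, all_paths) {
  if (inherits(x_paths, "path_set")) x_paths <- x_paths$components
  if (inherits(all_paths, "path_set")) all_paths <- all_paths$components
  n <- length(x_paths)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  B <- similarity_matrix(x_paths, all_paths)
  sds <- apply(B, 1L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  cl <- integer(n)
  ok <- which(!const)
  if (length(ok) >= 2L) {
    C <- stats::cor(t(B[ok, , drop = FALSE]))
    d <- stats::as.dist(1 - C)
    hc <- stats::hclust(d, method = "average")
    cl[ok] <- stats::cutree(hc, h = 0.2)
  } else if (length(ok) == 1L) {
    cl[ok] <- 1L
  }
  if (any(const)) {
    warning("constant similarity profile(s); assigned singleton clusters")
    cl[const] <- max(cl, 0L) + seq_len(sum(const))
  }
  cl
}

#' Method B reference sampling per (start node, cluster) pair
#'
#' With `n` distinct (start, cluster) pairs among the label's paths, each
#' pair keeps at most `ceiling(500 / n)` paths (seeded uniform sampling
#' without replacement); pairs at or under the cap keep all their paths.
#'
#' @param paths Labeled paths (list of identifier sequences).
#' @param start Start node per path.
#' @param cluster Cluster id per path.
#' @param budget Total reference budget (default 500).
#' @return Indices into `paths` of the retained reference paths.
#' @export
sample_reference_paths_method_b <- function(paths, start, cluster,
                                            budget = 500) {
  stopifnot(length(start) == length(paths), length(cluster) == length(paths))
  pair <- paste(start, cluster, sep = "\r")
  n <- length(unique(pair))
  cap <- ceiling(budget / n)
  keep <- integer(0)
  for (p in unique(pair)) {
    idx <- which(pair == p)
    if (length(idx) > cap) idx <- sort(sample(idx, cap))
    keep <- c(keep, idx)
  }
  sort(keep)
}

mask_self_similarity <- function(S, self_cols) {
  for (i in which(!is.na(self_cols))) {
    j <- self_cols[i]
    S[i, j] <- if (ncol(S) > 1L) max(S[i, -j]) else 0
  }
  S
}

# Build the feature recipe on the training paths and return the training
# feature matrix with self-similarity entries masked (a training path that
# is itself a reference must not see its own similarity of 1).
build_recipe <- function(train_paths, train_start, labeled_start, method) {
  lab_idx <- which(train_start %in% labeled_start)
  if (length(lab_idx) == 0L) {
    stop("no training path starts at a target of the selected label")
  }
  if (method == "A") {
    ref_ids <- lab_idx
    self_cols <- match(seq_along(train_paths), ref_ids)
    fa <- features_method_a(train_paths, train_paths[ref_ids],
                            self_cols = self_cols)
    list(recipe = list(method = "A", a = fa$recipe),
         features = fa$features)
  } else {
    cl <- integer(length(train_paths))
    for (x in unique(train_start)) {
      xi <- which(train_start == x)
      cl[xi] <- suppressWarnings(
        cluster_paths_method_b(train_paths[xi], train_paths))
    }
    ref_rel <- sample_reference_paths_method_b(train_paths[lab_idx],
                                               train_start[lab_idx],
                                               cl[lab_idx])
    ref_ids <- lab_idx[ref_rel]
    recipe <- list(method = "B", reference = train_paths[ref_ids])
    S <- similarity_matrix(train_paths, recipe$reference)
    S <- mask_self_similarity(S, match(seq_along(train_paths), ref_ids))
    list(recipe = recipe, features = S)
  }
}

apply_recipe <- function(recipe, paths) {
  if (inherits(paths, "path_set")) paths <- paths$components
  if (recipe$method == "A") {
    features_method_a(paths, recipe = recipe$a)$features
  } else {
    similarity_matrix(paths, recipe$reference)
  }
}

fit_gbt <- function(X, y, nrounds, max_depth, eta) {
  xgboost::xgboost(X, factor(y, levels = c(0, 1)), nrounds = nrounds,
                   max_depth = max_depth, learning_rate = eta,
                   nthreads = 1, verbosity = 0)
}

predict_gbt <- function(model, X) {
  as.numeric(stats::predict(model, X, type = "response"))
}

tune_gbt <- function(X, y, nrounds) {
  grid <- expand.grid(max_depth = c(3L, 5L), eta = c(0.1, 0.3))
  n <- nrow(X)
  idx <- sample.int(n)
  n_val <- max(1L, floor(0.2 * n))
  val <- idx[seq_len(n_val)]
  tr <- idx[-seq_len(n_val)]
  if (length(unique(y[tr])) < 2L || length(tr) < 4L) {
    return(list(max_depth = 3L, eta = 0.3))
  }
  best <- 1L
  best_ll <- Inf
  for (g in seq_len(nrow(grid))) {
    fit <- fit_gbt(X[tr, , drop = FALSE], y[tr],
                   nrounds = nrounds, max_depth = grid$max_depth[g],
                   eta = grid$eta[g])
    p <- predict_gbt(fit, X[val, , drop = FALSE])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- -mean(y[val] * log(p) + (1 - y[val]) * log(1 - p))
    if (ll < best_ll) {
      best_ll <- ll
      best <- g
    }
  }
  list(max_depth = grid$max_depth[best], eta = grid$eta[best])
}

#' Train the bagged path classifier for one TI/SE label
#'
#' Splits the paths 9:1 (stratified) into training and holdout, builds the
#' Method A or B feature recipe on the training paths, tunes the
#' gradient-boosted-tree hyperparameters once on 20% of a balanced
#' downsample, and fits ten models, each on an independent 1:1
#' under-sample of the majority class. Holdout performance of the 6-of-10
#' voting ensemble is reported.
#'
#' @param paths A `path_set` (or list of sequences with `start` given).
#' @param labels Logical vector: does each path carry the target label?
#' @param method `"A"` or `"B"`.
#' @param start Start node per path (taken from the `path_set` if absent).
#' @param n_models Ensemble size (default 10).
#' @param holdout_frac Held-out fraction (default 0.1).
#' @param nrounds Boosting rounds per model.
#' @param tune Tune `max_depth`/`eta` on a small fixed grid?
#' @param seed Integer seed.
#' @return A `label_ensemble`: recipe, fitted models, chosen parameters and
#'   holdout metrics (`accuracy`, `precision`, `recall`, `f1`).
#' @export
train_label_ensemble <- function(paths, labels, method = c("A", "B"),
                                 start = NULL, n_models = 10,
                                 holdout_frac = 0.1, nrounds = 60,
                                 tune = TRUE, seed = 1) {
  method <- match.arg(method)
  if (inherits(paths, "path_set")) {
    start <- paths$start
    paths <- paths$components
  }
  stopifnot(length(labels) == length(paths), !is.null(start))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("labels are single-class")
  set.seed(seed)

  pos <- which(labels)
  neg <- which(!labels)
  hold <- c(sample(pos, max(1L, round(holdout_frac * length(pos)))),
            sample(neg, max(1L, round(holdout_frac * length(neg)))))
  tr <- setdiff(seq_along(paths), hold)
  if (length(unique(labels[tr])) < 2L) {
    stop("training split is single-class; provide more paths")
  }

  labeled_start <- unique(start[labels])
  br <- build_recipe(paths[tr], start[tr], labeled_start, method)
  recipe <- br$recipe
  Xtr <- br$features
  ytr <- as.numeric(labels[tr])

  tr_pos <- which(ytr == 1)
  tr_neg <- which(ytr == 0)
  n_bal <- min(length(tr_pos), length(tr_neg))
  downsample <- function() {
    c(sample(tr_pos, n_bal), sample(tr_neg, n_bal))
  }
  params <- if (tune) {
    ds <- downsample()
    tune_gbt(Xtr[ds, , drop = FALSE], ytr[ds], nrounds)
  } else {
    list(max_depth = 3L, eta = 0.3)
  }

  models <- vector("list", n_models)
  for (b in seq_len(n_models)) {
    ds <- downsample()
    models[[b]] <- fit_gbt(Xtr[ds, , drop = FALSE], ytr[ds],
                           nrounds = nrounds, max_depth = params$max_depth,
                           eta = params$eta)
  }

  ens <- structure(list(method = method, recipe = recipe, models = models,
                        params = params, n_models = n_models, seed = seed),
                   class = "label_ensemble")
  pred <- predict_label(ens, paths[hold])
  truth <- labels[hold]
  tp <- sum(pred$verdict & truth)
  fp <- sum(pred$verdict & !truth)
  fn <- sum(!pred$verdict & truth)
  tn <- sum(!pred$verdict & !truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  ens$holdout <- list(accuracy = (tp + tn) / length(hold),
                      precision = precision, recall = recall, f1 = f1,
                      n = length(hold))
  ens
}

#' @export
print.label_ensemble <- function(x, ...) {
  cat(sprintf("label_ensemble: method %s, %d models", x$method, x$n_models))
  if (!is.null(x$holdout)) {
    cat(sprintf(" | holdout F1 = %.3f (n = %d)", x$holdout$f1, x$holdout$n))
  }
  cat("\n")
  invisible(x)
}

#' Apply the 6-of-10 voting rule to a model-score matrix
#'
#' A path is called positive when at least `min_votes` of the models score
#' it at or above 0.5.
#'
#' @param scores Paths x models matrix of predicted probabilities.
#' @param min_votes Vote threshold (default 6).
#' @return A list: `verdict` (logical), `votes` (integer),
#'   `fraction` (`votes / n_models`).
#' @export
vote_verdict <- function(scores, min_votes = 6) {
  votes <- as.integer(rowSums(scores >= 0.5))
  list(verdict = votes >= min_votes, votes = votes,
       fraction = votes / ncol(scores))
}

#' Predict a label for query paths with a trained ensemble
#'
#' @param ensemble A `label_ensemble`.
#' @param query_paths A `path_set` or list of identifier sequences.
#' @return A data.frame `(path_id, start, votes, fraction, verdict)`, with
#'   the per-model score matrix in attribute `scores`.
#' @export
predict_label <- function(ensemble, query_paths) {
  stopifnot(inherits(ensemble, "label_ensemble"))
  start <- if (inherits(query_paths, "path_set")) query_paths$start else NA
  X <- apply_recipe(ensemble$recipe, query_paths)
  scores <- vapply(ensemble$models,
                   function(m) predict_gbt(m, X),
                   numeric(nrow(X)))
  if (nrow(X) == 1L) scores <- matrix(scores, nrow = 1L)
  vv <- vote_verdict(scores, min_votes = ceiling(0.6 * ensemble$n_models))
  out <- data.frame(path_id = seq_len(nrow(X)),
                    start = start,
                    votes = vv$votes,
                    fraction = vv$fraction,
                    verdict = vv$verdict,
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}
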