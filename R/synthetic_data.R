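#' Specification for a synthetic multi-modal disease corpus
#'
#' Defines the generative conditions a synthetic corpus is drawn from:
#' per-disease topic weights from `Dirichlet(alpha_gen)`, per-topic
#' per-modality feature weights from `Dirichlet(beta_gen)` with a
#' `separation`-controlled block mask, and tokens drawn topic-first,
#' feature-second. `separation = 1` gives disjoint per-topic vocabularies;
#' `separation = 0` removes all topic structure from the feature weights.
#'
#' @param D Number of diseases.
#' @param K_true Number of generative topics.
#' @param modalities Named integer vector: modality tag -> vocabulary size.
#' @param alpha_gen,beta_gen Generative Dirichlet concentrations.
#' @param tokens_per_disease Integer or length-2 range; per disease per
#'   modality, drawn uniformly from the range.
#' @param separation Topic-overlap control in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(D = 60, K_true = 3,
                        modalities = c(Ae = 50, Bm = 50, Gv = 50),
                        alpha_gen = 0.1, beta_gen = 0.5,
                        tokens_per_disease = c(8, 15),
                        separation = 1, seed = 1) {
  stopifnot(D >= 1, K_true >= 1, length(modalities) >= 1,
            !is.null(names(modalities)), separation >= 0, separation <= 1,
            alpha_gen > 0, beta_gen > 0)
  if (separation == 1 && any(modalities < K_true)) {
    stop("every vocabulary must have at least K_true items when separation = 1")
  }
  structure(list(D = as.integer(D), K_true = as.integer(K_true),
                 modalities = modalities, alpha_gen = alpha_gen,
                 beta_gen = beta_gen,
                 tokens_per_disease = rep_len(as.integer(tokens_per_disease), 2L),
                 separation = separation, seed = as.integer(seed)),
            class = "corpus_spec")
}

mask_phi <- function(phi_raw, block, separation) {
  # separation interpolates between the uniform distribution (s = 0, no
  # topic signal at all) and the draw confined to the topic's block (s = 1,
  # disjoint per-topic vocabularies)
  p <- phi_raw * block
  s <- sum(p)
  p <- if (s > 0) p / s else as.numeric(block) / sum(block)
  separation * p + (1 - separation) / length(phi_raw)
}

#' Draw a synthetic corpus from the model's own generative process
#'
#' @param spec A [corpus_spec()].
#' @return A list with `corpus` (a `disease_corpus`), and `truth`:
#'   `theta` (D x K_true), `phi` (per modality, K_true x V), and
#'   `feature_sets` (per modality, per disease, the drawn feature ids).
#'   Repeated draws of a feature within one disease/modality collapse to a
#'   single token, matching the association-list data model.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  K <- spec$K_true
  D <- spec$D
  theta <- t(vapply(seq_len(D), function(d) rdirichlet1(rep(spec$alpha_gen, K)),
                    numeric(K)))
  diseases <- sprintf("disease%03d", seq_len(D))
  rownames(theta) <- diseases

  phi <- list()
  tables <- list()
  for (m in names(spec$modalities)) {
    V <- spec$modalities[[m]]
    vocab <- sprintf("%s_f%03d", m, seq_len(V))
    blocks <- rep(seq_len(K), length.out = V)  # item v belongs to topic block
    phi_m <- matrix(0, K, V, dimnames = list(NULL, vocab))
    for (k in seq_len(K)) {
      phi_m[k, ] <- mask_phi(rdirichlet1(rep(spec$beta_gen, V)),
                             blocks == k, spec$separation)
    }
    phi[[m]] <- phi_m
    lo <- spec$tokens_per_disease[1]
    hi <- spec$tokens_per_disease[2]
    rows_d <- character(0)
    rows_f <- character(0)
    for (d in seq_len(D)) {
      n_tok <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      zz <- rcat_rows(matrix(theta[d, ], n_tok, K, byrow = TRUE))
      vv <- vapply(zz, function(k) sample_missing_token(phi_m[k, ]), integer(1))
      vv <- unique(vv)
      rows_d <- c(rows_d, rep(diseases[d], length(vv)))
      rows_f <- c(rows_f, vocab[vv])
    }
    tables[[m]] <- modality_table(rows_d, rows_f, m)
  }
  corpus <- build_corpus(tables)
  feature_sets <- lapply(names(spec$modalities), function(m) {
    stats::setNames(lapply(seq_along(corpus$diseases), function(d)
      corpus$vocab[[m]][corpus$tokens[[m]][[d]]]), corpus$diseases)
  })
  names(feature_sets) <- names(spec$modalities)
  list(corpus = corpus,
       truth = list(theta = theta, phi = phi, feature_sets = feature_sets))
}

#' Plant a "hidden twin" disease and a pattern-matching decoy in a corpus
#'
#' Builds a well-separated synthetic corpus and rewrites one modality (`Ae`)
#' of the first topic's diseases into a tiered design around a target
#' disease:
#' * a block of `common` features carried by every disease of the topic,
#'   including the target (strongly imputable, but known to the target, so
#'   the known-feature filter removes them);
#' * a tier of `mid` features each carried by the target and exactly one
#'   other topic member (after the target's modality is held out, each has a
#'   single carrier, so its imputation score sits in the same tier as the
#'   planted latent features — which is what lets the Youden cut-off reach
#'   down to that tier);
#' * a block of twin-exclusive features carried only by the "twin" disease
#'   (not by the target): the planted latent signal;
#' * one decoy feature carried only by a topic member renamed
#'   `"synthetic heart failure"`, so the cardiovascular/renal name-pattern
#'   filter removes it.
#'
#' Holding out the target's `Ae` modality and running the
#' impute-threshold-filter pipeline should rank the twin first in the
#' latent-similarity table and drop the decoy.
#'
#' @param seed Integer seed.
#' @param n_twin_features Size of the twin-exclusive feature block.
#' @return A list: `corpus`, `target`, `twin`, `decoy_disease`,
#'   `decoy_feature`, `twin_features`, `modality` (the modality to hold
#'   out).
#' @export
generate_hidden_twin_corpus <- function(seed = 1, n_twin_features = 8) {
  # a draw occasionally leaves the first topic with too few diseases to
  # host the tiers; advance the corpus seed until it does (deterministic)
  for (try in 0:24) {
    spec <- corpus_spec(D = 40, K_true = 3,
                        modalities = c(Ae = 63, Bm = 45, Gv = 45),
                        alpha_gen = 0.01, beta_gen = 0.5,
                        tokens_per_disease = c(8, 12), separation = 1,
                        seed = seed + 1000L * try)
    gen <- generate_corpus(spec)
    corpus <- gen$corpus
    theta1 <- gen$truth$theta[corpus$diseases, 1]
    topic_of <- apply(gen$truth$theta[corpus$diseases, , drop = FALSE], 1,
                      which.max)
    # the planted roles need cleanly topic-1 diseases: the score tiers the
    # Youden cut-off must resolve blur if the target's topic weight leaks
    t1 <- which(topic_of == 1L & theta1 > 0.9)
    if (length(t1) >= 6L) break
  }
  m <- "Ae"
  if (length(t1) < 6L) stop("could not draw enough first-topic diseases")
  t1 <- t1[order(-theta1[t1])]  # most concentrated first
  target_i <- t1[1]
  twin_i <- t1[2]
  decoy_i <- t1[3]
  helpers <- t1[-(1:3)]

  # work in the generative vocabulary (names), which keeps the topic blocks
  # aligned even for features the rebuilt corpus would drop as uncarried
  vg <- colnames(gen$truth$phi[[m]])
  blocks <- rep(seq_len(3L), length.out = length(vg))
  block1 <- vg[blocks == 1L]  # 21 features with V = 63
  n_mid <- min(6L, length(helpers))
  stopifnot(length(block1) >= 7L + n_mid + n_twin_features)
  common1 <- block1[seq_len(7L)]
  mid <- block1[7L + seq_len(n_mid)]
  twin_feats <- block1[7L + n_mid + seq_len(n_twin_features)]
  decoy_feat <- utils::tail(setdiff(vg, block1), 1L)

  tokens <- gen$truth$feature_sets[[m]]  # named by disease
  reserved <- c(block1, decoy_feat)
  tokens <- lapply(tokens, function(v) setdiff(v, reserved))
  tokens[[corpus$diseases[target_i]]] <- sort(c(common1, mid))
  tokens[[corpus$diseases[twin_i]]] <- sort(c(common1, twin_feats))
  tokens[[corpus$diseases[decoy_i]]] <- sort(c(common1, decoy_feat))
  for (j in seq_along(helpers)) {
    nm <- corpus$diseases[helpers[j]]
    extra <- if (j <= n_mid) mid[j] else character(0)
    tokens[[nm]] <- sort(unique(c(common1, extra, tokens[[nm]])))
  }
  fallback <- setdiff(vg, reserved)[1]
  tokens <- lapply(tokens, function(v) if (length(v) == 0L) fallback else v)

  diseases <- corpus$diseases
  diseases[decoy_i] <- "synthetic heart failure"
  tabs <- lapply(corpus$modalities, function(mm) {
    if (mm == m) {
      tk <- tokens[corpus$diseases]
      rows_f <- unlist(tk, use.names = FALSE)
    } else {
      tk <- corpus$tokens[[mm]]
      rows_f <- corpus$vocab[[mm]][unlist(tk, use.names = FALSE)]
    }
    modality_table(rep(diseases, lengths(tk)), rows_f, mm)
  })
  out <- build_corpus(tabs)
  list(corpus = out,
       target = corpus$diseases[target_i],
       twin = corpus$diseases[twin_i],
       decoy_disease = "synthetic heart failure",
       decoy_feature = decoy_feat,
       twin_features = twin_feats,
       modality = m)
}

#' Specification for a planted-motif pathway fixture
#'
#' @param n_targets Number of drug-target root nodes.
#' @param n_labels Number of therapeutic-indication/side-effect labels.
#' @param motif_length Length of each label's planted node motif.
#' @param n_paths_per_target Planted paths rooted at each target.
#' @param noise_rate Probability that a path's motif status is flipped.
#' @param prefix_length Range of the path-specific prefix length.
#' @param seed Integer seed.
#' @return A `graph_spec` list.
#' @export
graph_spec <- function(n_targets = 200, n_labels = 1, motif_length = 4,
                       n_paths_per_target = 1, noise_rate = 0.05,
                       prefix_length = c(2, 5), seed = 1) {
  stopifnot(n_targets >= 2, n_labels >= 1, motif_length >= 2,
            n_paths_per_target >= 1, noise_rate >= 0, noise_rate <= 1)
  structure(list(n_targets = as.integer(n_targets),
                 n_labels = as.integer(n_labels),
                 motif_length = as.integer(motif_length),
                 n_paths_per_target = as.integer(n_paths_per_target),
                 noise_rate = noise_rate,
                 prefix_length = rep_len(as.integer(prefix_length), 2L),
                 seed = as.integer(seed)),
            class = "graph_spec")
}

#' Generate a pathway graph with planted path-motif/label associations
#'
#' Builds a directed identifier graph in which each drug target roots a set
#' of planted paths. Paths of targets whose drug carries label `L` run into
#' the label's motif: a shared, sink-terminated chain of `motif_length`
#' nodes, with probability `1 - noise_rate`; other paths end at their own
#' private sinks, but are routed into the motif with probability
#' `noise_rate`. Because each motif chain ends at an outdegree-0 node,
#' depth-first path extraction returns exactly the planted paths. A few
#' back-edges to path ancestors add cycles without creating new
#' root-to-sink simple paths.
#'
#' @param spec A [graph_spec()].
#' @return A list: `graph` (a `pathway_graph`, see [pathway_graph()]),
#'   `truth` (label -> motif node ids, and per-path motif status), and the
#'   drug/label tables used to build it.
#' @export
generate_pathway_fixture <- function(spec) {
  stopifnot(inherits(spec, "graph_spec"))
  set.seed(spec$seed)
  labels <- sprintf("TI%02d", seq_len(spec$n_labels))
  targets <- sprintf("hsa:t%03d", seq_len(spec$n_targets))
  drugs <- sprintf("DB%05d", seq_len(spec$n_targets))
  # assign each target's drug 0 or 1 labels, roughly half labeled
  drug_label <- ifelse(stats::runif(spec$n_targets) < 0.5,
                       sample(labels, spec$n_targets, replace = TRUE),
                       NA_character_)
  if (all(is.na(drug_label))) drug_label[1] <- labels[1]
  if (all(!is.na(drug_label))) drug_label[1] <- NA_character_

  motif <- lapply(labels, function(l)
    sprintf("hsa:m_%s_%02d", l, seq_len(spec$motif_length)))
  names(motif) <- labels

  edges_from <- character(0)
  edges_to <- character(0)
  node_counter <- 0L
  new_node <- function() {
    node_counter <<- node_counter + 1L
    sprintf("hsa:n%05d", node_counter)
  }
  path_truth <- list()
  for (i in seq_len(spec$n_targets)) {
    lab <- drug_label[i]
    for (j in seq_len(spec$n_paths_per_target)) {
      has_motif <- if (!is.na(lab)) {
        stats::runif(1) >= spec$noise_rate
      } else {
        stats::runif(1) < spec$noise_rate
      }
      motif_lab <- if (has_motif) {
        if (!is.na(lab)) lab else sample(labels, 1L)
      } else NA_character_
      plen <- spec$prefix_length
      n_pre <- sample.int(plen[2] - plen[1] + 1L, 1L) + plen[1] - 1L
      prefix <- vapply(seq_len(n_pre), function(x) new_node(), character(1))
      chain <- c(targets[i], prefix)
      if (has_motif) {
        chain <- c(chain, motif[[motif_lab]])
      } else {
        chain <- c(chain, new_node())  # private sink
      }
      edges_from <- c(edges_from, chain[-length(chain)])
      edges_to <- c(edges_to, chain[-1])
      # occasional back-edge within the prefix (cycle, no new simple path)
      if (n_pre >= 3L && stats::runif(1) < 0.2) {
        edges_from <- c(edges_from, prefix[n_pre])
        edges_to <- c(edges_to, prefix[1])
      }
      path_truth[[length(path_truth) + 1L]] <-
        list(target = targets[i], has_motif = has_motif, label = lab)
    }
  }
  edges <- unique(data.frame(from = edges_from, to = edges_to,
                             stringsAsFactors = FALSE))
  drug_targets <- data.frame(drug = drugs, target = targets,
                             stringsAsFactors = FALSE)
  drug_ti <- data.frame(drug = drugs[!is.na(drug_label)],
                        label = drug_label[!is.na(drug_label)],
                        stringsAsFactors = FALSE)
  graph <- pathway_graph(edges, drug_targets, ti = drug_ti,
                         se = drug_ti[0, , drop = FALSE])
  list(graph = graph,
       truth = list(motif = motif, paths = path_truth),
       edges = edges, drug_targets = drug_targets, drug_ti = drug_ti)
}

#' Generate a feature-annotation table with an optional planted enrichment
#'
#' Assigns each background feature one category at the base rate, then
#' boosts a designated subset's membership in the enriched category by
#' `fold` (fold 1 = null).
#'
#' @param features Character vector of background feature ids.
#' @param categories Character vector of category names.
#' @param enriched Optional `list(category =, fold =, subset =)`; `subset`
#'   is the character vector of features whose enriched-category odds are
#'   multiplied by `fold`.
#' @param seed Integer seed.
#' @return A data.frame `(feature, category)`.
#' @export
generate_annotation_fixture <- function(features, categories,
                                        enriched = NULL, seed = 1) {
  set.seed(seed)
  base <- rep(1, length(categories))
  names(base) <- categories
  cat_of <- character(length(features))
  for (i in seq_along(features)) {
    w <- base
    if (!is.null(enriched) && features[i] %in% enriched$subset) {
      stopifnot(enriched$fold >= 1, enriched$category %in% categories)
      w[enriched$category] <- w[enriched$category] * enriched$fold
    }
    cs <- cumsum(w)
    cat_of[i] <- categories[1L + sum(cs[-length(cs)] < stats::runif(1) * cs[length(cs)])]
  }
  data.frame(feature = features, category = cat_of, stringsAsFactors = FALSE)
}
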