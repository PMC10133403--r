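#' Build the shared-feature disease graph for one modality
#'
#' Undirected graph on the corpus diseases; two diseases are connected iff
#' they share at least one feature in the modality, with edge weight equal
#' to the number of shared features. Diseases sharing nothing remain as
#' isolated nodes.
#'
#' @param corpus A `disease_corpus`.
#' @param modality Modality tag present in the corpus.
#' @return An [igraph::graph] with vertex names and an edge `weight`
#'   attribute.
#' @export
build_shared_feature_graph <- function(corpus, modality) {
  validate_corpus(corpus)
  if (!modality %in% corpus$modalities) {
    stop("modality not in corpus: ", modality)
  }
  D <- length(corpus$diseases)
  V <- length(corpus$vocab[[modality]])
  tk <- corpus$tokens[[modality]]
  # disease x feature incidence; shared-feature counts are its Gram matrix
  X <- matrix(0L, D, V)
  for (d in seq_len(D)) X[d, tk[[d]]] <- 1L
  S <- tcrossprod(X)
  S[lower.tri(S, diag = TRUE)] <- 0L
  idx <- which(S > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = D, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = corpus$diseases)
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]),
                           weight = S[idx])
  }
  g
}

#' Most frequent Louvain community count over repeated runs
#'
#' Applies weighted Louvain modularity optimization `runs` times with
#' distinct seeds and returns the mode of the community counts. Ties are
#' broken toward the larger count (an overshoot of the topic number is
#' benign under the sparse prior; an undershoot is not). A graph without
#' edges yields one singleton community per node, reported with a warning.
#'
#' @param graph An undirected igraph with optional edge weights.
#' @param runs Number of Louvain repetitions (default 20).
#' @param seed Base seed; run `r` uses `seed + r`.
#' @return Integer community count.
#' @export
community_count <- function(graph, runs = 20, seed = 1) {
  stopifnot(igraph::vcount(graph) > 0)
  if (igraph::ecount(graph) == 0L) {
    warning("graph has no edges; every node is its own community")
    return(igraph::vcount(graph))
  }
  counts <- integer(runs)
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    cl <- igraph::cluster_louvain(graph, resolution = 1)
    counts[r] <- length(unique(igraph::membership(cl)))
  }
  tab <- table(counts)
  modes <- as.integer(names(tab)[tab == max(tab)])
  max(modes)
}

#' Select the topic number from a corpus
#'
#' Builds the per-modality shared-feature graphs, takes the modal Louvain
#' community count of each, and returns the maximum over modalities.
#'
#' @param corpus A `disease_corpus`.
#' @param runs Louvain repetitions per modality.
#' @param seed Base seed.
#' @return A list: `K` (the selected topic count) and `per_modality`
#'   (named integer vector of community counts).
#' @export
select_topic_number <- function(corpus, runs = 20, seed = 1) {
  counts <- vapply(corpus$modalities, function(m) {
    g <- build_shared_feature_graph(corpus, m)
    community_count(g, runs = runs, seed = seed)
  }, integer(1))
  names(counts) <- corpus$modalities
  list(K = max(counts), per_modality = counts)
}

#' Export a shared-feature graph as a weighted edge-list TSV
#'
#' @param graph Graph from [build_shared_feature_graph()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(from = el[, 1], to = el[, 2],
                   weight = igraph::E(graph)$weight,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
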