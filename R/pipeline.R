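#' Run the end-to-end latent-similarity pipeline for one target disease
#'
#' Chains the full flow: topic-number selection (unless `K` is given in the
#' config), leave-one-modality-out imputation of each requested modality of
#' the target, Youden thresholding of the likeliness scores, the
#' known-feature and related-disease filters, and the latent
#' disease-similarity table. Every intermediate is written to `out_dir`
#' as TSV, together with a JSON manifest (seed, configuration hash, package
#' version) sufficient to reproduce the run.
#'
#' @param corpus A `disease_corpus`.
#' @param target Target disease id.
#' @param out_dir Output directory (created if needed).
#' @param patterns A [name_pattern_set()] of related-disease name patterns.
#' @param config Optional [model_config()]; when `NULL`, `K` is selected by
#'   [select_topic_number()] and defaults are used otherwise.
#' @param modalities Modalities to impute (default: all).
#' @param iterations,burn_in,seed Used to build the default config.
#' @param carrier_rule Passed to [filter_related()].
#' @return Invisibly, a list with `K`, per-modality `evaluation`, `latent`
#'   feature tables, and the combined `similarity` table.
#' @export
run_pipeline <- function(corpus, target, out_dir,
                         patterns = default_ckd_mi_patterns(),
                         config = NULL, modalities = corpus$modalities,
                         iterations = 5000, burn_in = 2000, seed = 1,
                         carrier_rule = "any") {
  validate_corpus(corpus)
  if (!target %in% corpus$diseases) stop("unknown target disease: ", target)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config)) {
    sel <- select_topic_number(corpus, seed = seed)
    config <- model_config(K = sel$K, iterations = iterations,
                           burn_in = burn_in, seed = seed)
  } else {
    sel <- list(K = config$K, per_modality = NULL)
  }

  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  evaluation <- list()
  latent <- list()
  sim_rows <- list()
  for (m in modalities) {
    message("imputing ", target, " / ", m)
    sl <- loo_modality_scores(corpus, target, m, config)
    roc <- roc_with_youden(sl$scores, sl$labels)
    lik <- data.frame(feature = names(sl$scores),
                      likeliness = unname(sl$scores),
                      label = unname(sl$labels), stringsAsFactors = FALSE)
    lik <- lik[order(-lik$likeliness, lik$feature, method = "radix"), ]
    wtsv(lik, paste0("likeliness_", m, ".tsv"))
    pos <- positive_features(sl$scores, roc$youden_threshold)
    unk <- filter_known(pos, corpus, target, m)
    lat <- filter_related(unk, corpus, patterns, m, target = target,
                          carrier_rule = carrier_rule)
    wtsv(lat, paste0("latent_", m, ".tsv"))
    sim <- latent_similarity(lat, corpus, m, target = target)
    if (nrow(sim) > 0L) sim$modality <- m
    sim_rows[[m]] <- sim
    evaluation[[m]] <- data.frame(modality = m, auc = roc$auc,
                                  youden_threshold = roc$youden_threshold,
                                  n_positive = nrow(pos),
                                  n_latent = nrow(lat),
                                  stringsAsFactors = FALSE)
    latent[[m]] <- lat
  }
  eval_tab <- do.call(rbind, evaluation)
  rownames(eval_tab) <- NULL
  wtsv(eval_tab, "evaluation.tsv")

  sim_all <- do.call(rbind, sim_rows[lengths(sim_rows) > 0])
  if (is.null(sim_all) || nrow(sim_all) == 0L) {
    sim_tab <- data.frame(disease = character(0), count = integer(0))
  } else {
    agg <- stats::aggregate(count ~ disease, data = sim_all, FUN = sum)
    sim_tab <- agg[order(-agg$count, agg$disease, method = "radix"), ]
    rownames(sim_tab) <- NULL
  }
  wtsv(sim_tab, "latent_similarity.tsv")

  manifest <- list(
    package = "mmlda",
    version = as.character(utils::packageVersion("mmlda")),
    target = target, modalities = modalities,
    K = config$K, per_modality_k = as.list(sel$per_modality),
    iterations = config$iterations, burn_in = config$burn_in,
    seed = config$seed,
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(K = config$K, evaluation = eval_tab, latent = latent,
                 similarity = sim_tab))
}

config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                     digits = NA))
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
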