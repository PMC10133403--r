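#' Leave-one-modality-out imputation scores and presence labels
#'
#' Removes one disease's tokens in one modality, refits the model with
#' imputed slots for that modality, and returns the per-vocabulary-item
#' likeliness scores together with binary labels marking which items the
#' disease actually carried in the full corpus.
#'
#' @param corpus Full `disease_corpus`.
#' @param disease Disease id.
#' @param modality Modality tag.
#' @param config A [model_config()].
#' @return A list: `scores` (named numeric over the modality vocabulary),
#'   `labels` (0/1 integer vector aligned to `scores`), and `fit`.
#' @export
loo_modality_scores <- function(corpus, disease, modality, config) {
  d <- match(disease, corpus$diseases)
  if (is.na(d)) stop("unknown disease: ", disease)
  fit <- run_gibbs(corpus, config,
                   missing = list(disease = disease, modality = modality))
  n_avg <- config$iterations - config$burn_in
  scores <- fit$freq / n_avg
  labels <- integer(length(scores))
  labels[corpus$tokens[[modality]][[d]]] <- 1L
  names(labels) <- names(scores)
  if (all(labels == 1L)) {
    stop("disease carries the entire vocabulary; labels are one-class")
  }
  list(scores = scores, labels = labels, fit = fit)
}

#' ROC curve, AUC and Youden-index threshold
#'
#' Builds the ROC over all distinct score values as thresholds (an item is
#' called positive when its score is greater than or equal to the
#' threshold), computes the area under the curve by the trapezoidal rule,
#' and selects the threshold maximizing the Youden index `TPR - FPR`. Ties
#' in the Youden index are broken toward the highest threshold (the most
#' conservative positive set).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return A `roc_result`: `thresholds` (descending), `tpr`, `fpr`, `auc`,
#'   `youden_threshold`, `youden_index`.
#' @export
roc_with_youden <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("labels must contain both classes")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1))
  auc <- sum(diff(c(0, fpr)) * (utils::head(c(0, tpr), -1) +
                                  utils::tail(c(0, tpr), -1)) / 2)
  # close the curve to (1, 1); with threshold = min(scores) it is already
  # there, so this adds nothing, but keep the arithmetic explicit
  j <- tpr - fpr
  best <- which(j == max(j))[1]  # thr is descending: first max = highest thr
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 youden_threshold = thr[best], youden_index = j[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f, Youden cut-off = %g (J = %.4f)\n",
              x$auc, x$youden_threshold, x$youden_index))
  invisible(x)
}

#' Leave-one-modality-out evaluation over a test-disease set
#'
#' For each test disease and each requested modality, removes that single
#' (disease, modality) block (all other diseases keep all modalities),
#' refits, and reports the imputation AUC and Youden cut-off. Per-disease
#' failures (for example one-class labels) are reported as flagged rows
#' rather than aborting the sweep.
#'
#' @param corpus Full `disease_corpus`.
#' @param config A [model_config()]; each run derives its own seed from
#'   `config$seed` and the row index.
#' @param test_diseases Character vector of disease ids.
#' @param modalities Modalities to evaluate (default: all in the corpus).
#' @return A data.frame `(disease, modality, auc, youden_threshold, note)`.
#' @export
evaluate_corpus <- function(corpus, config, test_diseases,
                            modalities = corpus$modalities) {
  stopifnot(length(test_diseases) > 0L)
  rows <- list()
  i <- 0L
  for (dz in test_diseases) {
    for (m in modalities) {
      i <- i + 1L
      cfg <- config
      cfg$seed <- (config$seed + 1009L * i) %% .Machine$integer.max
      res <- tryCatch({
        sl <- loo_modality_scores(corpus, dz, m, cfg)
        roc <- roc_with_youden(sl$scores, sl$labels)
        data.frame(disease = dz, modality = m, auc = roc$auc,
                   youden_threshold = roc$youden_threshold,
                   note = "", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(disease = dz, modality = m, auc = NA_real_,
                   youden_threshold = NA_real_,
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
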