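#' Features above the Youden cut-off, ranked by likeliness
#'
#' @param result Imputation table from [imputation_result()], or a named
#'   likeliness vector.
#' @param threshold Youden cut-off from [roc_with_youden()].
#' @return A data.frame `(feature, likeliness)`, descending.
#' @export
positive_features <- function(result, threshold) {
  if (is.numeric(result) && !is.null(names(result))) {
    result <- data.frame(feature = names(result),
                         likeliness = unname(result),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("feature", "likeliness") %in% names(result)))
  keep <- result$likeliness >= threshold
  out <- result[keep, c("feature", "likeliness"), drop = FALSE]
  out <- out[order(-out$likeliness, out$feature, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop features already recorded for the disease
#'
#' Correctly re-predicted features (those present in the disease's original
#' modality set) are not "latent"; they are removed first.
#'
#' @param features Data.frame with a `feature` column (or character vector).
#' @param corpus Full `disease_corpus`.
#' @param disease,modality The held-out block.
#' @return The features not recorded for the disease, same shape as input.
#' @export
filter_known <- function(features, corpus, disease, modality) {
  d <- match(disease, corpus$diseases)
  if (is.na(d)) stop("unknown disease: ", disease)
  known <- corpus$vocab[[modality]][corpus$tokens[[modality]][[d]]]
  if (is.character(features)) return(setdiff(features, known))
  out <- features[!(features$feature %in% known), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compile a related-disease name-pattern set
#'
#' Patterns are lowercase substrings; a trailing `**` wildcard (any
#' characters) is equivalent to plain substring matching and is accepted for
#' readability. Matching is case-insensitive on the canonicalized disease
#' name.
#'
#' @param patterns Character vector, or a path to a one-pattern-per-line
#'   text file.
#' @return A `name_pattern_set`.
#' @export
name_pattern_set <- function(patterns) {
  if (length(patterns) == 1L &&
        (file.exists(patterns) || grepl("[/\\\\]", patterns) ||
           grepl("\\.(txt|tsv|lst)$", patterns))) {
    if (!file.exists(patterns)) {
      stop("pattern file cannot be read: ", patterns)
    }
    patterns <- readLines(patterns, warn = FALSE)
  }
  patterns <- trimws(patterns)
  patterns <- patterns[nzchar(patterns) & !startsWith(patterns, "#")]
  if (length(patterns) == 0L) stop("empty pattern set")
  structure(list(patterns = tolower(gsub("\\*", "", patterns))),
            class = "name_pattern_set")
}

#' Which disease names match a pattern set?
#'
#' @param names Character vector of disease names.
#' @param patterns A [name_pattern_set()].
#' @return Logical vector.
#' @export
matches_pattern <- function(names, patterns) {
  stopifnot(inherits(patterns, "name_pattern_set"))
  low <- tolower(names)
  hit <- rep(FALSE, length(low))
  for (p in patterns$patterns) hit <- hit | grepl(p, low, fixed = TRUE)
  hit
}

#' The default cardiovascular/renal related-disease pattern set
#'
#' The pattern list used to screen candidate latent features of chronic
#' kidney disease and myocardial infarction for derivation from obviously
#' related diseases.
#'
#' @return A `name_pattern_set`.
#' @export
default_ckd_mi_patterns <- function() {
  name_pattern_set(system.file("extdata", "ckd_mi_patterns.txt",
                               package = "mmlda", mustWork = TRUE))
}

feature_carriers <- function(corpus, modality, features) {
  vocab <- corpus$vocab[[modality]]
  idx <- match(features, vocab)
  tk <- corpus$tokens[[modality]]
  lapply(idx, function(v) {
    if (is.na(v)) return(character(0))
    corpus$diseases[vapply(tk, function(t) v %in% t, logical(1))]
  })
}

#' Remove features derived from apparently related diseases
#'
#' A candidate latent feature is traced back to the training diseases that
#' carry it; under the default strict rule the feature is removed if any
#' carrying disease (other than the target itself) matches the pattern set,
#' since derivation from even one related disease taints it. The lenient
#' alternative (`carrier_rule = "all"`) removes a feature only when every
#' carrier matches.
#'
#' @param features Data.frame with a `feature` column (or character vector).
#' @param corpus Full `disease_corpus`.
#' @param patterns A [name_pattern_set()].
#' @param modality Modality of the features.
#' @param target Disease id excluded from the carrier sets.
#' @param carrier_rule `"any"` (strict, default) or `"all"`.
#' @return A `latent_feature_set`: data.frame `(feature, likeliness?)` with
#'   a `carriers` attribute listing each retained feature's non-matching
#'   carriers.
#' @export
filter_related <- function(features, corpus, patterns, modality,
                           target = NULL, carrier_rule = c("any", "all")) {
  carrier_rule <- match.arg(carrier_rule)
  feats <- if (is.character(features)) features else features$feature
  carriers <- feature_carriers(corpus, modality, feats)
  if (!is.null(target)) {
    carriers <- lapply(carriers, function(cs) setdiff(cs, target))
  }
  hit <- vapply(seq_along(feats), function(i) {
    cs <- carriers[[i]]
    if (length(cs) == 0L) return(FALSE)
    mm <- matches_pattern(cs, patterns)
    if (carrier_rule == "any") any(mm) else all(mm)
  }, logical(1))
  keep <- !hit
  out <- if (is.character(features)) {
    data.frame(feature = features[keep], stringsAsFactors = FALSE)
  } else {
    features[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  kept_carriers <- lapply(which(keep), function(i) {
    cs <- carriers[[i]]
    cs[!matches_pattern(cs, patterns)]
  })
  names(kept_carriers) <- out$feature
  attr(out, "carriers") <- kept_carriers
  class(out) <- c("latent_feature_set", "data.frame")
  out
}

#' Latent disease similarity: which training diseases carry the latent set?
#'
#' For each training disease, counts how many of the latent features it
#' carries (the target itself and pattern-matching carriers are excluded by
#' construction of the latent set). The descending count ranks the diseases
#' whose similarity to the target is latent.
#'
#' @param latent A `latent_feature_set` from [filter_related()] (or a
#'   data.frame/character vector of features).
#' @param corpus Full `disease_corpus`.
#' @param modality Modality of the features.
#' @param target Disease id to exclude from the counts.
#' @return A data.frame `(disease, count)`, descending, count >= 1 rows.
#' @export
latent_similarity <- function(latent, corpus, modality, target = NULL) {
  feats <- if (is.character(latent)) latent else latent$feature
  if (length(feats) == 0L) {
    return(data.frame(disease = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  carriers <- feature_carriers(corpus, modality, feats)
  all_c <- unlist(carriers, use.names = FALSE)
  if (!is.null(target)) all_c <- all_c[all_c != target]
  if (length(all_c) == 0L) {
    return(data.frame(disease = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- sort(table(all_c), decreasing = TRUE)
  data.frame(disease = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Chi-square enrichment of a feature set over annotation categories
#'
#' For each category, a 2x2 contingency table (in-set/out-of-set versus
#' in-category/not) is tested for independence with the chi-square test
#' (Yates continuity correction, the 2x2 default), and p-values are adjusted
#' across categories by Benjamini-Hochberg.
#'
#' @param features Character vector, a subset of `background`.
#' @param annotations Data.frame `(feature, category)`; a feature may have
#'   several category rows.
#' @param background Character vector defining the tested universe.
#' @return A data.frame `(category, count, chi2, p, q)` ordered by `p`.
#' @export
chi_square_enrichment <- function(features, annotations, background) {
  stopifnot(all(c("feature", "category") %in% names(annotations)))
  features <- unique(features)
  background <- unique(background)
  if (!all(features %in% background)) {
    stop("features must be a subset of the background")
  }
  ann <- annotations[annotations$feature %in% background, , drop = FALSE]
  cats <- sort(unique(ann$category))
  n_set <- length(features)
  n_bg <- length(background)
  rows <- lapply(cats, function(cat) {
    in_cat <- unique(ann$feature[ann$category == cat])
    a <- sum(features %in% in_cat)
    b <- n_set - a
    c_ <- sum(!(in_cat %in% features))
    d <- (n_bg - n_set) - c_
    tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
    if (a + c_ == 0L) {
      warning("category with a zero margin skipped: ", cat)
      return(NULL)
    }
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      # feature set equals (or covers) the background, or the category spans
      # it: the table cannot deviate from independence
      return(data.frame(category = cat, count = a, chi2 = 0, p = 1,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    data.frame(category = cat, count = a,
               chi2 = unname(ct$statistic), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(category = character(0), count = integer(0),
                      chi2 = numeric(0), p = numeric(0), q = numeric(0)))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$category, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
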