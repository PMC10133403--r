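#' Read a disease-feature association table for one modality
#'
#' Reads a tab-separated association export (one row per disease-feature
#' attribution, as in DisGeNET- or Disbiome-style downloads) and returns a
#' deduplicated modality table. Feature identifiers are treated as
#' case-sensitive opaque strings; disease names keep their input form until
#' [canonicalize_diseases()] is applied.
#'
#' @param path Path to a TSV file with a header row.
#' @param modality Modality tag, e.g. `"Ae"`, `"Bm"`, `"Gv"`, `"Mb"`.
#' @param disease_col,feature_col Names of the disease and feature columns.
#' @return A `modality_table`: a data.frame with columns `disease` and
#'   `feature`, deduplicated, with the modality tag in attribute `modality`.
#' @export
read_modality_table <- function(path, modality,
                                disease_col = "disease",
                                feature_col = "feature") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("empty modality table: ", path)
  missing_cols <- setdiff(c(disease_col, feature_col), names(df))
  if (length(missing_cols) > 0L) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  modality_table(df[[disease_col]], df[[feature_col]], modality)
}

#' Construct a modality table from vectors
#'
#' @param disease,feature Character vectors of equal length.
#' @param modality Modality tag.
#' @return A deduplicated `modality_table`.
#' @export
modality_table <- function(disease, feature, modality) {
  stopifnot(length(disease) == length(feature), is.character(modality),
            length(modality) == 1L, nzchar(modality))
  disease <- as.character(disease)
  feature <- as.character(feature)
  bad <- which(is.na(disease) | is.na(feature) |
                 !nzchar(trimws(disease)) | !nzchar(trimws(feature)))
  if (length(bad) > 0L) {
    stop("empty disease or feature field in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  df <- unique(data.frame(disease = disease, feature = feature,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  attr(df, "modality") <- modality
  class(df) <- c("modality_table", "data.frame")
  df
}

#' Merge disease names onto canonical identifiers
#'
#' Applies the exact-name merging rule used when assembling multi-source
#' disease tables: the possessive "'s" (both the typographic and the ASCII
#' apostrophe) is replaced by a blank space, whitespace is collapsed, and an
#' optional synonym map then sends names to canonical identifiers. Names
#' absent from the map pass through unchanged, so with an empty map only
#' exactly matching names are combined.
#'
#' @param table A `modality_table`.
#' @param map Named character vector or two-column data.frame
#'   (`name`, `canonical`) mapping disease names to canonical ids; may be
#'   `NULL` or empty.
#' @return The table with diseases canonicalized and rows re-deduplicated.
#' @export
canonicalize_diseases <- function(table, map = NULL) {
  stopifnot(inherits(table, "modality_table"))
  nm <- normalize_disease_name(table$disease)
  if (!is.null(map) && length(map) > 0L) {
    if (is.data.frame(map)) {
      stopifnot(all(c("name", "canonical") %in% names(map)))
      map <- stats::setNames(as.character(map$canonical), map$name)
    }
    if (any(!nzchar(map))) stop("canonical ids must be non-empty")
    keys <- normalize_disease_name(names(map))
    hit <- match(nm, keys)
    nm[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  }
  modality_table(nm, table$feature, attr(table, "modality"))
}

normalize_disease_name <- function(x) {
  x <- gsub("’s|'s", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Assemble a multi-modal disease corpus
#'
#' Restricts the input modality tables to diseases annotated in every
#' modality and builds per-modality vocabularies over the retained
#' diseases. Disease and vocabulary orderings are lexicographic so repeated
#' builds are platform-reproducible.
#'
#' @param tables List of `modality_table` objects (distinct modalities).
#' @return A `disease_corpus` with fields `diseases`, `modalities`, `vocab`
#'   (per-modality character vectors) and `tokens` (per-modality list of
#'   integer vocabulary-index vectors, one per disease).
#' @export
build_corpus <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  mods <- vapply(tables, function(t) attr(t, "modality"), character(1))
  if (anyDuplicated(mods)) stop("duplicated modality tags: ",
                                paste(mods[duplicated(mods)], collapse = ", "))
  per_mod_diseases <- lapply(tables, function(t) unique(t$disease))
  diseases <- Reduce(intersect, per_mod_diseases)
  if (length(diseases) == 0L) {
    smallest <- mods[which.min(lengths(per_mod_diseases))]
    stop("no disease is annotated in every modality; fewest diseases in ",
         "modality ", smallest)
  }
  diseases <- sort(diseases, method = "radix")
  vocab <- list()
  tokens <- list()
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    t <- t[t$disease %in% diseases, , drop = FALSE]
    vocab[[mods[i]]] <- sort(unique(t$feature), method = "radix")
    v_idx <- match(t$feature, vocab[[mods[i]]])
    d_idx <- match(t$disease, diseases)
    tokens[[mods[i]]] <- lapply(seq_along(diseases),
                                function(d) sort(v_idx[d_idx == d]))
  }
  corpus <- structure(list(diseases = diseases, modalities = mods,
                           vocab = vocab, tokens = tokens),
                      class = "disease_corpus")
  validate_corpus(corpus)
  corpus
}

validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "disease_corpus"))
  for (m in corpus$modalities) {
    V <- length(corpus$vocab[[m]])
    counts <- lengths(corpus$tokens[[m]])
    if (any(counts == 0L)) {
      stop("disease(s) without tokens in modality ", m, ": ",
           paste(utils::head(corpus$diseases[counts == 0L], 5L),
                 collapse = ", "))
    }
    idx <- unlist(corpus$tokens[[m]], use.names = FALSE)
    stopifnot(all(idx >= 1L), all(idx <= V))
  }
  invisible(corpus)
}

#' @export
print.disease_corpus <- function(x, ...) {
  cat("disease_corpus:", length(x$diseases), "diseases,",
      length(x$modalities), "modalities\n")
  for (m in x$modalities) {
    cat(sprintf("  %s: V=%d, %d tokens\n", m, length(x$vocab[[m]]),
                sum(lengths(x$tokens[[m]]))))
  }
  invisible(x)
}

#' Export a corpus as one association TSV per modality
#'
#' @param corpus A `disease_corpus`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths (named by modality).
#' @export
export_corpus <- function(corpus, dir) {
  validate_corpus(corpus)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in corpus$modalities) {
    rows <- do.call(rbind, lapply(seq_along(corpus$diseases), function(d) {
      v <- corpus$tokens[[m]][[d]]
      if (length(v) == 0L) return(NULL)
      data.frame(disease = corpus$diseases[d],
                 feature = corpus$vocab[[m]][v],
                 stringsAsFactors = FALSE)
    }))
    p <- file.path(dir, paste0(m, ".tsv"))
    utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[m] <- p
  }
  invisible(paths)
}

#' Rebuild a corpus from its own TSV export
#'
#' @param dir Directory written by [export_corpus()].
#' @param modalities Modality tags to read (file names without `.tsv`).
#' @return A `disease_corpus`.
#' @export
import_corpus <- function(dir, modalities) {
  tables <- lapply(modalities, function(m)
    read_modality_table(file.path(dir, paste0(m, ".tsv")), m))
  build_corpus(tables)
}

MODEL_FORMAT_VERSION <- "mmlda-model-1"

#' Serialize a fitted model state to JSON
#'
#' Posterior means, sampling-frequency counters and the configuration are
#' written as full-precision decimals, so a load/save round trip reproduces
#' the imputation ranking bit for bit.
#'
#' @param fit A fit object returned by [run_gibbs()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "mmlda_fit"))
  obj <- list(
    format = MODEL_FORMAT_VERSION,
    config = fit$config,
    diseases = fit$diseases,
    modalities = fit$modalities,
    vocab = fit$vocab,
    theta = fit$theta,
    phi = lapply(fit$phi, identity),
    missing = fit$missing,
    freq = as.list(fit$freq)  # named list keeps feature ids in the JSON
  )
  # I(17) significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Load a fitted model state saved by [save_model()]
#'
#' @param path JSON path.
#' @return An `mmlda_fit` object.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(obj$format) || !identical(obj$format, MODEL_FORMAT_VERSION)) {
    stop("model format version mismatch: expected ", MODEL_FORMAT_VERSION,
         ", found ", if (is.null(obj$format)) "<none>" else obj$format)
  }
  fit <- list(
    config = obj$config,
    diseases = obj$diseases,
    modalities = obj$modalities,
    vocab = obj$vocab,
    theta = as.matrix(obj$theta),
    phi = lapply(obj$phi, as.matrix),
    missing = obj$missing,
    freq = if (!is.null(obj$freq)) unlist(obj$freq)
  )
  dimnames(fit$theta) <- list(fit$diseases, NULL)
  for (m in names(fit$phi)) colnames(fit$phi[[m]]) <- fit$vocab[[m]]
  class(fit) <- "mmlda_fit"
  fit
}
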