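# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms.

# Recursive Levenshtein with memoization on the (i, j) call grid; no
# iterative DP table fill.
lev_oracle <- function(n, m) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    x <- as.integer(n[i] != m[j])
    val <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
               rec(i - 1L, j - 1L) + x)
    memo[[key]] <- val
    val
  }
  rec(length(n), length(m))
}

# AUC as the normalized Mann-Whitney all-pairs concordance count.
auc_oracle <- function(scores, labels) {
  s_pos <- scores[labels == 1]
  s_neg <- scores[labels == 0]
  tot <- 0
  for (sp in s_pos) tot <- tot + sum(sp > s_neg) + 0.5 * sum(sp == s_neg)
  tot / (length(s_pos) * length(s_neg))
}

# Exhaustive Youden maximizer over all distinct scores, ties broken toward
# the highest threshold.
youden_oracle <- function(scores, labels) {
  best_j <- -Inf
  best_t <- NA_real_
  for (t in sort(unique(scores), decreasing = TRUE)) {
    tpr <- mean(scores[labels == 1] >= t)
    fpr <- mean(scores[labels == 0] >= t)
    if (tpr - fpr > best_j) {
      best_j <- tpr - fpr
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Exhaustive simple-path enumeration from start to every outdegree-0 node,
# via igraph's independent path machinery.
paths_oracle <- function(pg, start) {
  g <- pg$graph
  sinks <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0]
  out <- list()
  for (s in sinks) {
    if (s == start) {
      out <- c(out, list(start))
      next
    }
    ps <- igraph::all_simple_paths(g, from = start, to = s, mode = "out")
    out <- c(out, lapply(ps, function(p) igraph::V(g)$name[p]))
  }
  out
}

canon_paths <- function(paths) {
  sort(vapply(paths, paste, character(1), collapse = ">"))
}

# A tiny corpus built directly from in-memory tables.
tiny_corpus <- function(spec_list) {
  tabs <- lapply(names(spec_list), function(m) {
    rows <- spec_list[[m]]
    modality_table(rep(names(rows), lengths(rows)),
                   unlist(rows, use.names = FALSE), m)
  })
  build_corpus(tabs)
}

# Two-group, single-modality corpus with disjoint vocabulary halves.
two_block_corpus <- function(n_per_block = 5, v_per_block = 10) {
  va <- sprintf("a%02d", seq_len(v_per_block))
  vb <- sprintf("b%02d", seq_len(v_per_block))
  set.seed(99)
  rows <- list()
  for (i in seq_len(n_per_block)) {
    rows[[paste0("dA", i)]] <- sample(va, 6)
    rows[[paste0("dB", i)]] <- sample(vb, 6)
  }
  tiny_corpus(list(Ae = rows))
}

expect_close <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y)), tol)
}

random_path <- function(len, alphabet = c("a", "b", "c", "d")) {
  sample(alphabet, len, replace = TRUE)
}
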