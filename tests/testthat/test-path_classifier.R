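simple_graph <- function(edges, targets = NULL) {
  ed <- data.frame(from = edges[, 1], to = edges[, 2],
                   stringsAsFactors = FALSE)
  if (is.null(targets)) targets <- unique(ed$from)
  dt <- data.frame(drug = paste0("D", seq_along(targets)), target = targets,
                   stringsAsFactors = FALSE)
  pathway_graph(ed, dt)
}

test_that("path extraction enumerates simple paths to sinks", {
  g <- simple_graph(rbind(c("a", "b"), c("b", "c"), c("a", "d")), "a")
  expect_equal(canon_paths(extract_paths(g, "a")),
               c("a>b>c", "a>d"))

  gc <- simple_graph(rbind(c("a", "b"), c("b", "a"), c("b", "c")), "a")
  expect_equal(canon_paths(extract_paths(gc, "a")), "a>b>c")

  gi <- pathway_graph(data.frame(from = "x", to = "y"),
                      data.frame(drug = "D1", target = "z"))
  expect_equal(extract_paths(gi, "z"), list("z"))

  expect_error(extract_paths(g, "nope"), "not in graph")

  # truncation cap
  wide <- simple_graph(cbind("r", paste0("s", 1:8)), "r")
  expect_warning(p <- extract_paths(wide, "r", max_paths = 3), "truncated")
  expect_equal(length(p), 3L)
})

test_that("path extraction agrees with exhaustive enumeration", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    nodes <- paste0("n", 1:n)
    el <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.3) el <- rbind(el, c(nodes[i], nodes[j]))
    }
    if (is.null(el)) next
    pg <- simple_graph(el, nodes[1])
    mine <- canon_paths(extract_paths(pg, nodes[1]))
    oracle <- canon_paths(paths_oracle(pg, nodes[1]))
    expect_equal(mine, oracle)
  }
})

test_that("edit distance matches the recursive oracle and known cases", {
  expect_equal(edit_distance(c("a", "b", "c"), c("a", "b", "c")), 0L)
  expect_equal(edit_distance(c("a", "b", "c"), c("a", "x", "c")), 1L)
  expect_equal(edit_distance(c("a", "b"), character(0)), 2L)
  expect_equal(edit_distance(character(0), c("q")), 1L)

  set.seed(23)
  for (rep in 1:200) {
    n <- random_path(sample(0:6, 1))
    m <- random_path(sample(0:6, 1))
    expect_equal(edit_distance(n, m), lev_oracle(n, m))
  }
})

test_that("edit distance agrees with an independent implementation", {
  # utils::adist computes Levenshtein on strings; identifiers map to
  # single characters
  set.seed(24)
  for (rep in 1:100) {
    n <- random_path(sample(1:8, 1), letters[1:6])
    m <- random_path(sample(1:8, 1), letters[1:6])
    expect_equal(edit_distance(n, m),
                 as.integer(utils::adist(paste(n, collapse = ""),
                                         paste(m, collapse = ""))))
  }
})

test_that("edit distance is a metric", {
  set.seed(25)
  for (rep in 1:200) {
    a <- random_path(sample(0:6, 1))
    b <- random_path(sample(0:6, 1))
    c_ <- random_path(sample(0:6, 1))
    expect_equal(edit_distance(a, a), 0L)
    expect_equal(edit_distance(a, b), edit_distance(b, a))
    expect_lte(edit_distance(a, c_),
               edit_distance(a, b) + edit_distance(b, c_))
  }
})

test_that("normalized similarity behaves per its definition", {
  p5 <- c("a", "b", "c", "d", "e")
  expect_equal(path_similarity(p5, p5), 1.0)
  expect_equal(path_similarity(c("a", "b", "c"), c("a", "x", "c")), 2 / 3)
  expect_equal(path_similarity(c("a", "b"), c("x", "y")), 0.0)
  expect_error(path_similarity(character(0), character(0)), "undefined")

  # similarity 1 iff identical; invariant under consistent renaming
  set.seed(26)
  for (rep in 1:50) {
    a <- random_path(sample(1:6, 1))
    b <- random_path(sample(1:6, 1))
    s <- path_similarity(a, b)
    expect_equal(s == 1, identical(a, b))
    ren <- c(a = "W", b = "X", c = "Y", d = "Z")
    expect_equal(path_similarity(unname(ren[a]), unname(ren[b])), s)
  }
})

test_that("Method A retains components to 99% cumulative variance", {
  set.seed(27)
  paths <- lapply(1:20, function(i) random_path(sample(3:8, 1), letters[1:8]))
  refs <- paths[sample(20, 8)]
  fa <- features_method_a(paths, refs)
  S <- similarity_matrix(paths, refs)
  v <- eigen(stats::cov(S) * (nrow(S) - 1) / nrow(S), symmetric = TRUE,
             only.values = TRUE)$values
  v_pr <- stats::prcomp(S)$sdev^2
  oracle_ncomp <- which(cumsum(v_pr) / sum(v_pr) >= 0.99)[1]
  expect_equal(ncol(fa$features), oracle_ncomp)
  expect_lte(ncol(fa$features), min(length(paths), length(refs)))

  # retained components reconstruct at least 99% of the variance
  expect_gte(sum(v_pr[seq_len(ncol(fa$features))]) / sum(v_pr), 0.99)

  # identical query set under the frozen recipe reproduces the features
  fa2 <- features_method_a(paths, recipe = fa$recipe)
  expect_equal(fa2$features, fa$features, tolerance = 1e-12)

  # rank-1 similarity structure keeps exactly one component
  same <- lapply(1:6, function(i) c("a", "b", "c"))
  fa1 <- features_method_a(same, same[1:2])
  expect_equal(ncol(fa1$features), 1L)

  expect_error(features_method_a(paths, list()), "no reference")
})

test_that("Method B clustering groups identical and splits unrelated paths", {
  all_paths <- lapply(1:12, function(i) random_path(6, letters[1:10]))
  x_same <- list(c("a", "b", "c"), c("a", "b", "c"))
  cl <- cluster_paths_method_b(x_same, c(x_same, all_paths))
  expect_equal(cl[1], cl[2])

  # two planted motif groups among 6 paths
  m1 <- c("p", "q", "r", "s")
  m2 <- c("w", "x", "y", "z")
  grp <- c(lapply(1:3, function(i) c(sprintf("u%d", i), m1)),
           lapply(1:3, function(i) c(sprintf("v%d", i), m2)))
  pool <- c(grp, lapply(1:10, function(i) c(sprintf("t%d", i), if (i <= 5) m1 else m2)))
  cl2 <- cluster_paths_method_b(grp, pool)
  expect_equal(length(unique(cl2[1:3])), 1L)
  expect_equal(length(unique(cl2[4:6])), 1L)
  expect_false(cl2[1] == cl2[4])

  expect_equal(cluster_paths_method_b(list(c("a")), list(c("a"))), 1L)
})

test_that("Method B reference sampling caps multiplicity at ceil(500/n)", {
  paths <- lapply(1:703, function(i) c("a", "b"))
  # n = 1 pair, 700 paths at one (start, cluster), 3 at another -> n = 2
  start <- c(rep("s1", 700), rep("s2", 3))
  cluster <- c(rep(1L, 700), rep(1L, 3))
  set.seed(28)
  keep <- sample_reference_paths_method_b(paths, start, cluster)
  expect_equal(sum(start[keep] == "s1"), 250L)  # ceil(500/2)
  expect_equal(sum(start[keep] == "s2"), 3L)    # under the cap: kept as-is

  set.seed(28)
  keep1 <- sample_reference_paths_method_b(paths[1:700], start[1:700],
                                           cluster[1:700])
  expect_equal(length(keep1), 500L)  # ceil(500/1)

  expect_equal(ceiling(500 / 5), 100)
})

test_that("the 6-of-10 voting rule matches hand-computed verdicts", {
  s1 <- matrix(c(rep(0.6, 6), rep(0.4, 4)), 1)
  expect_true(vote_verdict(s1)$verdict)
  s2 <- matrix(c(rep(0.9, 5), rep(0.1, 5)), 1)
  expect_false(vote_verdict(s2)$verdict)
  s3 <- matrix(rep(0.5, 10), 1)
  expect_true(vote_verdict(s3)$verdict)
  expect_equal(vote_verdict(s3)$fraction, 1)

  # monotonicity: raising any score never flips a true verdict to false
  set.seed(29)
  for (rep in 1:50) {
    sc <- matrix(runif(10), 1)
    v <- vote_verdict(sc)$verdict
    j <- sample(10, 1)
    sc2 <- sc
    sc2[j] <- min(1, sc2[j] + runif(1))
    if (v) expect_true(vote_verdict(sc2)$verdict)
  }
})

test_that("ensemble training is seeded and rejects degenerate labels", {
  fx <- generate_pathway_fixture(graph_spec(n_targets = 40, seed = 30))
  ps <- extract_all_paths(fx$graph)
  labels <- ps$start %in% label_targets(fx$graph, "TI01", "ti")
  ens1 <- train_label_ensemble(ps, labels, method = "A", seed = 6,
                               nrounds = 20, tune = FALSE)
  ens2 <- train_label_ensemble(ps, labels, method = "A", seed = 6,
                               nrounds = 20, tune = FALSE)
  q <- ps$components[1:10]
  expect_equal(predict_label(ens1, q), predict_label(ens2, q))

  expect_error(train_label_ensemble(ps, rep(TRUE, length(labels)),
                                    method = "A", start = ps$start),
               "single-class")
})
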