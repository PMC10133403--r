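test_that("the per-token topic conditional matches hand arithmetic", {
  expect_equal(conditional_topic_probs(c(0.5, 0.5), c(0.2, 0.2)), c(0.5, 0.5))
  expect_equal(conditional_topic_probs(c(0.9, 0.1), c(0.5, 0.5)), c(0.9, 0.1))
  expect_equal(conditional_topic_probs(c(0.6, 0.4), c(0.1, 0.3)),
               c(1 / 3, 2 / 3))
  expect_error(conditional_topic_probs(c(1, 0), c(0, 1)), "degenerate")
})

test_that("Dirichlet draws for theta and phi match their closed-form means", {
  set.seed(31)
  n <- 1e4
  draws <- t(replicate(n, sample_theta(c(0.1, 0.1), c(3, 1))))
  m <- 3.1 / 4.2
  expect_lt(abs(mean(draws[, 1]) - m), 3 * stats::sd(draws[, 1]) / sqrt(n))
  expect_close(rowSums(draws[1:50, ]), rep(1, 50))

  # counts pooled over two modalities add before the draw
  expect_equal(length(sample_theta(0.1, c(1, 0) + c(1, 0))), 2L)

  draws_phi <- t(replicate(n, sample_phi(rep(0.1, 3), c(2, 0, 0))))
  m1 <- 2.1 / 2.3
  expect_lt(abs(mean(draws_phi[, 1]) - m1),
            3 * stats::sd(draws_phi[, 1]) / sqrt(n))
})

test_that("missing-token draws follow the topic's feature distribution", {
  one_hot <- c(0, 0, 1, 0)
  set.seed(7)
  expect_true(all(replicate(50, sample_missing_token(one_hot)) == 3L))

  p <- c(0.7, 0.2, 0.1)
  set.seed(8)
  draws <- replicate(1e4, sample_missing_token(p))
  freqs <- tabulate(draws, 3) / 1e4
  for (v in 1:3) {
    se <- sqrt(p[v] * (1 - p[v]) / 1e4)
    expect_lt(abs(freqs[v] - p[v]), 3 * se + 1e-6)
  }
})

test_that("missing-slot counts follow the truncated binomial MLE model", {
  set.seed(9)
  # all diseases have 5 tokens, V = 50 -> p_hat = 0.1, mean approx 5
  draws <- replicate(1e4, draw_missing_count(rep(5, 10), 50))
  expect_lt(abs(mean(draws) - 5) / (sqrt(50 * 0.1 * 0.9) / sqrt(1e4)), 4)

  # single observation MLE
  set.seed(10)
  d1 <- replicate(2000, draw_missing_count(1, 10))
  expect_gte(min(d1), 1)

  # goodness of fit against the zero-truncated Binomial(V, p_hat) pmf
  V <- 20; p <- 4 / V
  set.seed(11)
  draws <- replicate(1e4, draw_missing_count(rep(4, 8), V))
  pmf <- stats::dbinom(1:V, V, p) / (1 - stats::dbinom(0, V, p))
  obs <- tabulate(draws, V)
  keep <- pmf * 1e4 >= 5
  chi <- sum((obs[keep] - 1e4 * pmf[keep])^2 / (1e4 * pmf[keep]))
  expect_lt(chi, stats::qchisq(0.99, df = sum(keep) - 1))

  expect_error(draw_missing_count(c(0, 0), 10), "all-zero")
})

test_that("degenerate one-token corpora are fit deterministically", {
  corpus <- tiny_corpus(list(Ae = list(d1 = "A")))
  expect_error(model_config(K = 0), "positive")
  expect_error(model_config(K = 1, iterations = 10, burn_in = 10), "burn_in")

  # force a second vocabulary item so phi has something to compare
  corpus2 <- tiny_corpus(list(Ae = list(d1 = "A", d2 = c("A", "B"))))
  cfg <- model_config(K = 1, iterations = 60, burn_in = 10, seed = 1)
  fit <- run_gibbs(corpus2, cfg)
  expect_equal(unname(fit$theta[, 1]), c(1, 1))
  phi <- model_phi(fit, "Ae")
  expect_gt(phi[1, "A"], phi[1, "B"])  # A observed twice, B once
})

test_that("two diseases with disjoint vocabularies separate into topics", {
  corpus <- tiny_corpus(list(Ae = list(
    d1 = c("a1", "a2", "a3", "a4", "a5"),
    d2 = c("b1", "b2", "b3", "b4", "b5"))))
  cfg <- model_config(K = 2, iterations = 600, burn_in = 200, seed = 21)
  fit <- run_gibbs(corpus, cfg)
  expect_gt(max(fit$theta[1, ]), 0.9)
  expect_gt(max(fit$theta[2, ]), 0.9)
  expect_true(which.max(fit$theta[1, ]) != which.max(fit$theta[2, ]))
})

test_that("the sampler is reproducible under a fixed seed", {
  gen <- generate_corpus(corpus_spec(D = 10, K_true = 2,
                                     modalities = c(Ae = 15, Bm = 15),
                                     seed = 3))
  cfg <- model_config(K = 2, iterations = 120, burn_in = 40, seed = 17)
  miss <- list(disease = gen$corpus$diseases[1], modality = "Ae")
  f1 <- run_gibbs(gen$corpus, cfg, missing = miss)
  f2 <- run_gibbs(gen$corpus, cfg, missing = miss)
  expect_identical(f1$freq, f2$freq)
  expect_identical(f1$theta, f2$theta)
})

test_that("simplex normalization and token counts hold at every sweep", {
  gen <- generate_corpus(corpus_spec(D = 12, K_true = 2,
                                     modalities = c(Ae = 15, Bm = 15),
                                     seed = 4))
  cfg <- model_config(K = 2, iterations = 60, burn_in = 20, seed = 5)
  fit <- run_gibbs(gen$corpus, cfg,
                   missing = list(disease = gen$corpus$diseases[2],
                                  modality = "Bm"),
                   diagnostics = TRUE)
  expect_equal(nrow(fit$diagnostics), 60L)
  expect_lt(max(fit$diagnostics$row_err), 1e-9)
  expect_true(all(fit$diagnostics$tokens_conserved == 1))

  # frequency counters are bounded by averaged sweeps x slot count
  n_avg <- cfg$iterations - cfg$burn_in
  expect_lte(max(fit$freq), n_avg * fit$missing$n_slots)
  expect_equal(sum(fit$freq), n_avg * fit$missing$n_slots)
})

test_that("a plain per-token reference sampler reproduces the batched sweep", {
  # mirror implementation: same conditionals, same RNG consumption order,
  # but computed token-by-token with explicit loops
  reference_gibbs <- function(corpus, cfg) {
    K <- cfg$K
    D <- length(corpus$diseases)
    mods <- corpus$modalities
    set.seed(cfg$seed)
    tok <- lapply(mods, function(m) {
      tk <- corpus$tokens[[m]]
      list(d = rep.int(seq_along(tk), lengths(tk)),
           v = unlist(tk, use.names = FALSE))
    })
    names(tok) <- mods
    theta <- matrix(1 / K, D, K)
    phi <- lapply(mods, function(m)
      matrix(1 / length(corpus$vocab[[m]]), K, length(corpus$vocab[[m]])))
    names(phi) <- mods
    z <- lapply(mods, function(m)
      as.integer(ceiling(stats::runif(length(tok[[m]]$d)) * K)))
    names(z) <- mods
    theta_sum <- matrix(0, D, K)
    for (it in seq_len(cfg$iterations)) {
      for (m in mods) {
        n <- length(tok[[m]]$d)
        u <- stats::runif(n)
        for (i in seq_len(n)) {
          w <- theta[tok[[m]]$d[i], ] * phi[[m]][, tok[[m]]$v[i]]
          cs <- cumsum(w)
          z[[m]][i] <- 1L + sum(cs[-K] < u[i] * cs[K])
        }
      }
      cnt <- matrix(0L, D, K)
      for (m in mods) {
        for (i in seq_along(z[[m]])) {
          cnt[tok[[m]]$d[i], z[[m]][i]] <- cnt[tok[[m]]$d[i], z[[m]][i]] + 1L
        }
      }
      for (d in seq_len(D)) theta[d, ] <- sample_theta(rep(0.1, K), cnt[d, ])
      for (m in mods) {
        V <- ncol(phi[[m]])
        ckv <- matrix(0L, K, V)
        for (i in seq_along(z[[m]])) {
          ckv[z[[m]][i], tok[[m]]$v[i]] <- ckv[z[[m]][i], tok[[m]]$v[i]] + 1L
        }
        for (k in seq_len(K)) phi[[m]][k, ] <- sample_phi(rep(0.1, V), ckv[k, ])
      }
      if (it > cfg$burn_in) theta_sum <- theta_sum + theta
    }
    theta_sum / (cfg$iterations - cfg$burn_in)
  }

  corpus <- tiny_corpus(list(
    Ae = list(d1 = c("a1", "a2", "a3"), d2 = c("b1", "b2")),
    Bm = list(d1 = c("x1", "x2"), d2 = c("y1", "y2", "y3"))))
  cfg <- model_config(K = 2, iterations = 25, burn_in = 5, seed = 13)
  fit <- run_gibbs(corpus, cfg)
  ref <- reference_gibbs(corpus, cfg)
  expect_equal(unname(fit$theta), unname(ref), tolerance = 1e-12)
})

test_that("imputed slots can be excluded from the phi statistics", {
  gen <- generate_corpus(corpus_spec(D = 8, K_true = 2,
                                     modalities = c(Ae = 12, Bm = 12),
                                     seed = 6))
  miss <- list(disease = gen$corpus$diseases[1], modality = "Ae")
  f_incl <- run_gibbs(gen$corpus,
                      model_config(K = 2, iterations = 80, burn_in = 20,
                                   seed = 2),
                      missing = miss)
  f_excl <- run_gibbs(gen$corpus,
                      model_config(K = 2, iterations = 80, burn_in = 20,
                                   seed = 2, include_imputed_in_phi = FALSE),
                      missing = miss)
  expect_false(identical(f_incl$phi$Ae, f_excl$phi$Ae))
})
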