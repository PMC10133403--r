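#' Model configuration for the multi-modal topic model
#'
#' @param K Number of topics (use [select_topic_number()] to choose it from
#'   the data).
#' @param alpha Dirichlet concentration for the per-disease topic weights;
#'   scalar or length-`K` vector. Default 0.1.
#' @param beta Dirichlet concentration for the per-topic feature weights;
#'   scalar, or a named list of per-modality scalars/vectors. Default 0.1.
#' @param iterations Total Gibbs sweeps. Default 5000.
#' @param burn_in Sweeps discarded before averaging; the topic distribution
#'   typically stabilizes within 1000-2000 sweeps, so the default is 2000.
#' @param seed Integer seed; every stochastic step of the sampler derives
#'   from it.
#' @param include_imputed_in_phi Should currently imputed tokens contribute
#'   to the topic-feature count statistics? Default `TRUE`.
#' @return A `model_config` list.
#' @export
model_config <- function(K, alpha = 0.1, beta = 0.1, iterations = 5000,
                         burn_in = 2000, seed = 1,
                         include_imputed_in_phi = TRUE) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (iterations < 1L) stop("iterations must be positive")
  if (burn_in < 0L || burn_in >= iterations) {
    stop("burn_in must be non-negative and smaller than iterations")
  }
  if (any(alpha <= 0)) stop("alpha must be positive")
  structure(list(K = K, alpha = alpha, beta = beta, iterations = iterations,
                 burn_in = burn_in, seed = as.integer(seed),
                 include_imputed_in_phi = isTRUE(include_imputed_in_phi)),
            class = "model_config")
}

#' Per-token conditional topic distribution
#'
#' The conditional probability of assigning a token with feature `v` to each
#' topic, given the current per-disease topic weights and the topic-feature
#' weights of the token's modality:
#' `p(z = k) = theta_dk * phi_kv / sum_k' theta_dk' * phi_k'v`.
#'
#' @param theta_d Length-`K` topic-weight vector of the token's disease.
#' @param phi_col_v Length-`K` vector of `phi[k, v]` for the token's feature.
#' @return A length-`K` probability vector.
#' @export
conditional_topic_probs <- function(theta_d, phi_col_v) {
  stopifnot(length(theta_d) == length(phi_col_v))
  num <- theta_d * phi_col_v
  tot <- sum(num)
  if (!is.finite(tot) || tot <= 0) {
    stop("degenerate conditional: theta * phi is zero for every topic")
  }
  num / tot
}

#' Draw per-disease topic weights from their conditional
#'
#' `theta_d | z ~ Dirichlet(alpha + n_d)`, where `n_dk` counts the disease's
#' tokens currently assigned to topic `k`, pooled over all modalities (the
#' modalities share one topic-weight vector per disease).
#'
#' @param alpha Prior concentration, scalar or length-`K`.
#' @param topic_counts_d Length-`K` non-negative integer counts.
#' @return A draw from the Dirichlet posterior (length-`K` simplex).
#' @export
sample_theta <- function(alpha, topic_counts_d) {
  rdirichlet1(alpha + topic_counts_d)
}

#' Draw topic-feature weights for one topic of one modality
#'
#' `phi_k | z, w ~ Dirichlet(beta + m_k)`, where `m_kv` counts tokens of the
#' modality (observed and, by default, imputed) with feature `v` assigned to
#' topic `k`.
#'
#' @param beta Prior concentration, scalar or length-`V`.
#' @param feature_counts_k Length-`V` non-negative integer counts.
#' @return A draw from the Dirichlet posterior (length-`V` simplex).
#' @export
sample_phi <- function(beta, feature_counts_k) {
  rdirichlet1(beta + feature_counts_k)
}

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  s <- sum(g)
  if (!is.finite(s) || s <= 0) return(rep(1 / length(shape), length(shape)))
  g / s
}

#' Sample one imputed token from its topic's feature distribution
#'
#' @param phi_k Length-`V` probability vector of the slot's current topic.
#' @return A vocabulary index in `1:V`.
#' @export
sample_missing_token <- function(phi_k) {
  cs <- cumsum(phi_k)
  tot <- cs[length(cs)]
  if (!is.finite(tot) || tot <= 0) stop("degenerate phi row")
  1L + sum(cs[-length(cs)] < stats::runif(1) * tot)
}

#' Draw the number of imputed token slots for a missing modality
#'
#' The slot count is binomial with size equal to the modality vocabulary and
#' success probability estimated by maximum likelihood from the observed
#' per-disease token counts (`p_hat = mean(count) / V`). Draws of zero are
#' rejected: a disease must receive at least one slot to be scoreable.
#'
#' @param observed_counts Per-disease token counts for the modality.
#' @param V Vocabulary size of the modality.
#' @return A positive integer.
#' @export
draw_missing_count <- function(observed_counts, V) {
  if (length(observed_counts) == 0L || all(observed_counts == 0)) {
    stop("cannot estimate a missing-token count from all-zero observations")
  }
  p_hat <- mean(observed_counts) / V
  p_hat <- min(max(p_hat, 0), 1)
  repeat {
    n <- stats::rbinom(1L, size = V, prob = p_hat)
    if (n >= 1L) return(n)
  }
}

# Vectorized categorical draws: one draw per row of the non-negative weight
# matrix P. Consumes runif(nrow(P)) in row order.
rcat_rows <- function(P) {
  n <- nrow(P)
  K <- ncol(P)
  if (K == 1L) {
    stats::runif(n)  # keep RNG consumption uniform across K
    return(rep(1L, n))
  }
  U <- upper.tri(matrix(0, K, K), diag = TRUE) * 1
  cum <- P %*% U
  tot <- cum[, K]
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop("degenerate conditional: zero total weight for some token")
  }
  u <- stats::runif(n) * tot
  1L + as.integer(rowSums(cum[, -K, drop = FALSE] < u))
}

flatten_tokens <- function(corpus, m) {
  tk <- corpus$tokens[[m]]
  list(d = rep.int(seq_along(tk), lengths(tk)),
       v = unlist(tk, use.names = FALSE))
}

#' Fit the multi-modal topic model by uncollapsed Gibbs sampling
#'
#' Runs the systematic-scan Gibbs sampler: each sweep resamples every token's
#' topic assignment from its conditional, then the per-disease topic weights
#' `theta` (one Dirichlet draw per disease, counts pooled over modalities),
#' then the per-topic feature weights `phi` for every modality, and finally
#' the imputed tokens of the missing modality, each drawn from its topic's
#' current `phi` row. After `burn_in` sweeps, `theta`, `phi` and the
#' imputed-token sampling frequencies are accumulated; the fit reports their
#' post-burn-in means, and the sampling frequency normalized by the number of
#' averaged sweeps is the imputation "likeliness" score of each feature.
#'
#' @param corpus A `disease_corpus`.
#' @param config A [model_config()].
#' @param missing Optional `list(disease =, modality =)`: that disease's
#'   tokens in that modality are removed before fitting and replaced by
#'   imputed slots whose count is drawn by [draw_missing_count()].
#' @param diagnostics If `TRUE`, record per-sweep simplex-normalization error
#'   and token-count conservation checks (in `fit$diagnostics`).
#' @return An `mmlda_fit` with posterior-mean `theta` (diseases x K) and
#'   `phi` (per modality, K x V), the missing-slot description, and for the
#'   missing modality the per-feature sampling-frequency counters `freq`.
#' @export
run_gibbs <- function(corpus, config, missing = NULL, diagnostics = FALSE) {
  validate_corpus(corpus)
  stopifnot(inherits(config, "model_config"))
  K <- config$K
  D <- length(corpus$diseases)
  mods <- corpus$modalities
  alpha <- rep_len(config$alpha, K)

  if (!is.null(missing)) {
    stopifnot(is.list(missing), !is.null(missing$disease),
              !is.null(missing$modality))
    if (!missing$modality %in% mods) {
      stop("unknown modality: ", missing$modality)
    }
    miss_d <- match(missing$disease, corpus$diseases)
    if (is.na(miss_d)) stop("unknown disease: ", missing$disease)
    miss_m <- missing$modality
  }

  set.seed(config$seed)

  beta <- list()
  tok <- list()
  for (m in mods) {
    V <- length(corpus$vocab[[m]])
    b <- if (is.list(config$beta)) config$beta[[m]] else config$beta
    beta[[m]] <- rep_len(b, V)
    tok[[m]] <- flatten_tokens(corpus, m)
    tok[[m]]$miss <- rep(FALSE, length(tok[[m]]$d))
  }

  n_slots <- 0L
  if (!is.null(missing)) {
    keep <- tok[[miss_m]]$d != miss_d
    obs_counts <- lengths(corpus$tokens[[miss_m]])[-miss_d]
    V_m <- length(corpus$vocab[[miss_m]])
    n_slots <- draw_missing_count(obs_counts, V_m)
    # uniform initial phi: initial imputed features are uniform draws
    init_v <- as.integer(ceiling(stats::runif(n_slots) * V_m))
    tok[[miss_m]] <- list(d = c(tok[[miss_m]]$d[keep], rep(miss_d, n_slots)),
                          v = c(tok[[miss_m]]$v[keep], init_v),
                          miss = c(rep(FALSE, sum(keep)),
                                   rep(TRUE, n_slots)))
  }

  theta <- matrix(1 / K, D, K)
  phi <- lapply(mods, function(m) {
    V <- length(corpus$vocab[[m]])
    matrix(1 / V, K, V)
  })
  names(phi) <- mods
  z <- lapply(mods, function(m)
    as.integer(ceiling(stats::runif(length(tok[[m]]$d)) * K)))
  names(z) <- mods

  n_avg <- config$iterations - config$burn_in
  theta_sum <- matrix(0, D, K)
  phi_sum <- lapply(phi, function(p) p * 0)
  freq <- NULL
  if (!is.null(missing)) freq <- numeric(length(corpus$vocab[[miss_m]]))
  diag_rows <- if (diagnostics) vector("list", config$iterations) else NULL

  for (it in seq_len(config$iterations)) {
    # (1) token-topic assignments, batched form of the per-token conditional
    for (m in mods) {
      P <- theta[tok[[m]]$d, , drop = FALSE] *
        t(phi[[m]])[tok[[m]]$v, , drop = FALSE]
      z[[m]] <- rcat_rows(P)
    }
    # (2) per-disease topic weights, counts pooled over modalities
    cnt_dk <- matrix(0L, D, K)
    for (m in mods) {
      tab <- tabulate(tok[[m]]$d + D * (z[[m]] - 1L), nbins = D * K)
      cnt_dk <- cnt_dk + matrix(tab, D, K)
    }
    for (d in seq_len(D)) theta[d, ] <- sample_theta(alpha, cnt_dk[d, ])
    # (3) per-topic feature weights, one modality at a time
    for (m in mods) {
      V <- length(corpus$vocab[[m]])
      use <- if (config$include_imputed_in_phi) TRUE else !tok[[m]]$miss
      zz <- z[[m]][use]
      vv <- tok[[m]]$v[use]
      cnt_kv <- matrix(tabulate(zz + K * (vv - 1L), nbins = K * V), K, V)
      for (k in seq_len(K)) phi[[m]][k, ] <- sample_phi(beta[[m]], cnt_kv[k, ])
    }
    # (4) imputed tokens from their topics' phi rows
    if (!is.null(missing) && n_slots > 0L) {
      slot_idx <- which(tok[[miss_m]]$miss)
      for (s in slot_idx) {
        tok[[miss_m]]$v[s] <- sample_missing_token(phi[[miss_m]][z[[miss_m]][s], ])
      }
    }
    if (it > config$burn_in) {
      theta_sum <- theta_sum + theta
      for (m in mods) phi_sum[[m]] <- phi_sum[[m]] + phi[[m]]
      if (!is.null(missing) && n_slots > 0L) {
        slot_v <- tok[[miss_m]]$v[tok[[miss_m]]$miss]
        freq <- freq + tabulate(slot_v, nbins = length(freq))
      }
    }
    if (diagnostics) {
      row_err <- max(abs(rowSums(theta) - 1),
                     max(vapply(phi, function(p) max(abs(rowSums(p) - 1)),
                                numeric(1))))
      tok_ok <- all(vapply(mods, function(m) {
        sum(tabulate(z[[m]], nbins = K)) == length(tok[[m]]$d)
      }, logical(1)))
      diag_rows[[it]] <- c(row_err = row_err, tokens_conserved = tok_ok)
    }
  }

  fit <- list(
    config = unclass(config),
    diseases = corpus$diseases,
    modalities = mods,
    vocab = corpus$vocab,
    theta = theta_sum / n_avg,
    phi = lapply(phi_sum, function(p) p / n_avg),
    missing = if (is.null(missing)) NULL else
      list(disease = missing$disease, modality = miss_m, n_slots = n_slots),
    freq = if (is.null(missing)) NULL else
      stats::setNames(as.numeric(freq), corpus$vocab[[miss_m]])
  )
  dimnames(fit$theta) <- list(fit$diseases, NULL)
  for (m in mods) colnames(fit$phi[[m]]) <- corpus$vocab[[m]]
  if (diagnostics) {
    fit$diagnostics <- as.data.frame(do.call(rbind, diag_rows))
  }
  class(fit) <- "mmlda_fit"
  fit
}

#' @export
print.mmlda_fit <- function(x, ...) {
  cat("mmlda_fit: D =", length(x$diseases), ", K =", x$config$K,
      ", modalities:", paste(x$modalities, collapse = "/"), "\n")
  if (!is.null(x$missing)) {
    cat("  imputed:", x$missing$disease, "/", x$missing$modality,
        sprintf("(%d slots)\n", x$missing$n_slots))
  }
  invisible(x)
}

#' Posterior-mean topic-feature weights of one modality
#'
#' @param fit An `mmlda_fit`.
#' @param modality Modality tag; must be one of the modalities the model
#'   was fitted with.
#' @return The K x V posterior-mean weight matrix.
#' @export
model_phi <- function(fit, modality) {
  stopifnot(inherits(fit, "mmlda_fit"))
  if (!modality %in% fit$modalities) {
    stop("model has no modality ", modality, "; fitted with: ",
         paste(fit$modalities, collapse = ", "))
  }
  fit$phi[[modality]]
}

#' Imputation likeliness of a fitted model with a held-out modality
#'
#' The likeliness of each vocabulary feature is its imputed-slot sampling
#' frequency divided by the number of averaged sweeps. With several slots it
#' can exceed 1; only the ranking and the Youden threshold are consumed
#' downstream.
#'
#' @param fit An `mmlda_fit` produced with a `missing` argument.
#' @return A data.frame `(feature, likeliness, rank)`, descending.
#' @export
imputation_result <- function(fit) {
  stopifnot(inherits(fit, "mmlda_fit"))
  if (is.null(fit$missing)) stop("fit has no held-out modality")
  n_avg <- fit$config$iterations - fit$config$burn_in
  lik <- fit$freq / n_avg
  ord <- order(-lik, names(lik), method = "radix")
  data.frame(feature = names(lik)[ord],
             likeliness = unname(lik[ord]),
             rank = seq_along(lik),
             stringsAsFactors = FALSE)
}
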