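#' Configuration for the LDA Gibbs sampler
#'
#' Defaults follow common practice for symptom-pattern topic models:
#' K = 4 topics, topic-pattern prior eta = 0.1, diary-topic prior
#' alpha = 50 / K, a chain of 10000 sweeps with a burn-in of 2000, every
#' 10th post-burn-in sweep retained, and hyperparameters updated along
#' the chain by a fixed-point step.
#'
#' @param K Number of topics.
#' @param eta Symmetric Dirichlet prior on topic-pattern distributions.
#' @param alpha Symmetric Dirichlet prior on diary-topic proportions.
#' @param iterations Total Gibbs sweeps.
#' @param burnin Sweeps discarded before posterior draws are collected.
#' @param thin Spacing between retained draws.
#' @param hyper_update Update alpha and eta along the chain (fixed-point
#'   step every `hyper_every` sweeps).
#' @param hyper_every Sweeps between hyperparameter updates.
#' @param seed Integer seed.
#' @return A validated list of class `lda_config`.
#' @export
lda_config <- function(K = 4, eta = 0.1, alpha = 50 / K,
                       iterations = 10000, burnin = 2000, thin = 10,
                       hyper_update = TRUE, hyper_every = 50, seed = 1) {
  if (K < 1) stop("lda_config: K must be >= 1")
  if (eta <= 0 || alpha <= 0) stop("lda_config: priors must be positive")
  if (burnin >= iterations) stop("lda_config: burnin must be < iterations")
  if (thin < 1) stop("lda_config: thin must be >= 1")
  structure(list(K = as.integer(K), eta = eta, alpha = alpha,
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 hyper_update = isTRUE(hyper_update),
                 hyper_every = as.integer(hyper_every),
                 seed = as.integer(seed)),
            class = "lda_config")
}

#' Expand a frequency matrix into a token corpus
#'
#' Each diary-year row becomes a bag of tokens: `F[j, g]` copies of
#' pattern g, in deterministic order (patterns in column order, then
#' replicates). Empty rows are retained as empty documents whose topic
#' proportions fall back to the prior mean.
#'
#' @param F Non-negative integer matrix (diary-years x patterns), e.g.
#'   from [build_frequency_matrix()].
#' @return A list of class `lda_corpus`: `doc` and `word` (1-based
#'   integer vectors, one entry per token), `J`, `G`, `doc_ids`,
#'   `vocab_codes`, `doc_lengths`.
#' @export
corpus_from_frequency <- function(F) {
  F <- as.matrix(F)
  if (any(F < 0) || any(F != round(F))) {
    stop("corpus_from_frequency: F must contain non-negative integers")
  }
  J <- nrow(F); G <- ncol(F)
  idx <- which(F > 0, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  reps <- F[idx]
  structure(list(doc = unname(rep(idx[, 1], reps)),
                 word = unname(rep(idx[, 2], reps)),
                 J = J, G = G,
                 doc_ids = rownames(F), vocab_codes = colnames(F),
                 doc_lengths = as.integer(rowSums(F))),
            class = "lda_corpus")
}

# Minka-style fixed point for a symmetric Dirichlet concentration given
# count rows `counts` (n x dim) with row totals `totals`.
dirichlet_fixed_point <- function(conc, counts, totals, dim_size,
                                  n_steps = 5, floor = 1e-6) {
  n <- nrow(counts)
  for (step in seq_len(n_steps)) {
    num <- sum(digamma(counts + conc)) - n * dim_size * digamma(conc)
    den <- dim_size *
      (sum(digamma(totals + dim_size * conc)) - n * digamma(dim_size * conc))
    if (!is.finite(num) || !is.finite(den) || den <= 0 || num <= 0) break
    conc <- max(conc * num / den, floor)
  }
  conc
}

lda_joint_loglik <- function(njk, nkg, nk, doc_lengths, alpha, eta) {
  K <- length(nk); G <- ncol(nkg)
  ll_w <- K * lgamma(G * eta) - K * G * lgamma(eta) +
    sum(lgamma(nkg + eta)) - sum(lgamma(nk + G * eta))
  J <- nrow(njk)
  ll_z <- J * lgamma(K * alpha) - J * K * lgamma(alpha) +
    sum(lgamma(njk + alpha)) - sum(lgamma(doc_lengths + K * alpha))
  ll_w + ll_z
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Runs a collapsed Gibbs chain over token-topic assignments z, with the
#' multinomial parameters integrated out; the full conditional for a
#' token in document j carrying pattern g is proportional to
#' `(n_jk + alpha) * (n_kg + eta) / (n_k + G * eta)`. After burn-in,
#' every `thin`-th sweep contributes a Rao-Blackwellized draw
#' `(n_kg + eta) / (n_k + G * eta)` for beta and
#' `(n_jk + alpha) / (n_j + K * alpha)` for theta; the point estimates
#' are the means over draws. Because averaging across sweeps can mix
#' label-switched states, the single last-draw estimates are returned as
#' well. When `hyper_update` is on, alpha and eta are re-estimated by a
#' Dirichlet fixed-point step at regular intervals along the chain.
#'
#' @param corpus An `lda_corpus` from [corpus_from_frequency()].
#' @param config An [lda_config()].
#' @return An object of class `lda_fit`: `beta` (K x G, rows sum to 1),
#'   `theta` (J x K, rows sum to 1), `beta_last`, `theta_last`, `z`
#'   (final assignments, 1-based), `loglik` (per-sweep-checkpoint joint
#'   log-likelihood trace), final `alpha`/`eta`, `n_draws`, `counts`
#'   (final n_jk, n_kg, n_k) and the `config`.
#' @export
fit_lda_gibbs <- function(corpus, config = lda_config()) {
  stopifnot(inherits(corpus, "lda_corpus"), inherits(config, "lda_config"))
  n <- length(corpus$doc)
  if (n == 0) stop("fit_lda_gibbs: empty corpus")
  K <- config$K; G <- corpus$G; J <- corpus$J
  if (K > n) warning("fit_lda_gibbs: more topics than tokens")
  set.seed(config$seed)
  doc0 <- as.integer(corpus$doc - 1L)
  word0 <- as.integer(corpus$word - 1L)
  z <- as.integer(sample.int(K, n, replace = TRUE) - 1L)
  njk <- matrix(0L, J, K)
  nkg <- matrix(0L, K, G)
  nk <- integer(K)
  for (i in seq_len(n)) {
    k <- z[i] + 1L
    njk[doc0[i] + 1L, k] <- njk[doc0[i] + 1L, k] + 1L
    nkg[k, word0[i] + 1L] <- nkg[k, word0[i] + 1L] + 1L
    nk[k] <- nk[k] + 1L
  }
  alpha <- config$alpha; eta <- config$eta
  doc_lengths <- corpus$doc_lengths

  beta_sum <- matrix(0, K, G)
  theta_sum <- matrix(0, J, K)
  n_draws <- 0L
  loglik <- numeric(0)
  alpha_trace <- alpha; eta_trace <- eta

  sweeps_done <- 0L
  # advance in chunks so that draws, the log-likelihood checkpoint and
  # hyperparameter updates all land on sweep boundaries
  chunk <- if (config$hyper_update) {
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    gcd(config$thin, config$hyper_every)
  } else config$thin
  while (sweeps_done < config$iterations) {
    step <- min(chunk, config$iterations - sweeps_done)
    lda_gibbs_sweeps(doc0, word0, z, njk, nkg, nk, alpha, eta, step)
    sweeps_done <- sweeps_done + step
    loglik <- c(loglik,
                lda_joint_loglik(njk, nkg, nk, doc_lengths, alpha, eta))
    if (config$hyper_update && sweeps_done %% config$hyper_every == 0L) {
      alpha <- dirichlet_fixed_point(alpha, njk, doc_lengths, K)
      eta <- dirichlet_fixed_point(eta, nkg, nk, G)
      alpha_trace <- c(alpha_trace, alpha)
      eta_trace <- c(eta_trace, eta)
    }
    if (sweeps_done > config$burnin &&
        (sweeps_done - config$burnin) %% config$thin == 0L) {
      beta_sum <- beta_sum + (nkg + eta) / (nk + G * eta)
      theta_sum <- theta_sum +
        (njk + alpha) / (doc_lengths + K * alpha)
      n_draws <- n_draws + 1L
    }
  }
  if (n_draws == 0L) stop("fit_lda_gibbs: no posterior draws retained")
  beta_last <- (nkg + eta) / (nk + G * eta)
  theta_last <- (njk + alpha) / (doc_lengths + K * alpha)
  dimnames(beta_last) <- list(NULL, corpus$vocab_codes)
  beta <- beta_sum / n_draws
  theta <- theta_sum / n_draws
  dimnames(beta) <- list(paste0("topic", seq_len(K)), corpus$vocab_codes)
  dimnames(theta) <- list(corpus$doc_ids, paste0("topic", seq_len(K)))
  structure(list(beta = beta, theta = theta,
                 beta_last = beta_last, theta_last = theta_last,
                 z = z + 1L, loglik = loglik,
                 alpha = alpha, eta = eta,
                 alpha_trace = alpha_trace, eta_trace = eta_trace,
                 n_draws = n_draws,
                 counts = list(njk = njk, nkg = nkg, nk = nk),
                 config = config),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("<lda_fit>", x$config$K, "topics,", ncol(x$beta), "patterns,",
      nrow(x$theta), "diary-years;", x$n_draws, "posterior draws",
      sprintf("(alpha %.3g, eta %.3g)\n", x$alpha, x$eta))
  invisible(x)
}

#' Top patterns per topic
#'
#' For each topic the `n` patterns with the largest estimated
#' topic-pattern probability, with human-readable labels; ties are
#' broken lexicographically by code.
#'
#' @param fit An `lda_fit`.
#' @param vocabulary The `pattern_vocabulary` the frequency matrix was
#'   built with (supplies labels); optional.
#' @param n Patterns per topic (default 5).
#' @param estimator `"mean"` (posterior-mean beta, default) or `"last"`
#'   (single final draw).
#' @return Data frame: topic, rank, code, label, weight.
#' @export
top_terms <- function(fit, vocabulary = NULL, n = 5,
                      estimator = c("mean", "last")) {
  estimator <- match.arg(estimator)
  beta <- if (estimator == "mean") fit$beta else fit$beta_last
  G <- ncol(beta)
  if (n > G) {
    warning("top_terms: n reduced to vocabulary size ", G)
    n <- G
  }
  codes <- colnames(beta)
  labels <- if (!is.null(vocabulary)) {
    vocabulary$label[match(codes, vocabulary$code)]
  } else codes
  out <- do.call(rbind, lapply(seq_len(nrow(beta)), function(k) {
    ord <- order(-beta[k, ], codes)[seq_len(n)]
    data.frame(topic = k, rank = seq_len(n), code = codes[ord],
               label = labels[ord], weight = beta[k, ord])
  }))
  rownames(out) <- NULL
  out
}

#' Format top terms as a topics-by-rank display table
#'
#' @param tt Result of [top_terms()].
#' @return Character matrix, rows = rank, columns = topics, cells
#'   `"label (weight)"` with two-decimal weights.
#' @export
format_topic_table <- function(tt) {
  topics <- sort(unique(tt$topic))
  n <- max(tt$rank)
  out <- matrix("", nrow = n, ncol = length(topics),
                dimnames = list(paste0("rank", seq_len(n)),
                                paste0("Topic ", topics)))
  for (k in topics) {
    sub <- tt[tt$topic == k, ]
    w <- ifelse(sub$weight < 0.005, "<0.01", sprintf("%.2f", sub$weight))
    out[sub$rank, which(topics == k)] <- paste0(sub$label, " (", w, ")")
  }
  out
}
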