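# Shared fixture builders and small independent oracles.

make_diary <- function(values, start = "2020-01-01", child_id = "c1",
                       symptoms = NULL) {
  values <- as.matrix(values)
  if (is.null(symptoms)) symptoms <- paste0("s", seq_len(ncol(values)))
  diary(child_id, as.Date(start) + seq_len(nrow(values)) - 1, values,
        symptoms)
}

# 1096 days from 2020-01-01 covers exactly 36 calendar months
full_diary <- function(fill = 0L, days = 1096, start = "2020-01-01",
                       M = 3, child_id = "c1", symptoms = NULL) {
  make_diary(matrix(as.integer(fill), days, M), start, child_id, symptoms)
}

# blank (all-NA) the given calendar dates of a diary
blank_days <- function(d, dates) {
  idx <- d$date %in% as.Date(dates)
  for (s in attr(d, "symptoms")) d[[s]][idx] <- NA_integer_
  d
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# best mean column-wise cosine between factor matrices over permutations
aligned_cosine <- function(A, B) {
  max(vapply(all_permutations(ncol(A)), function(p) {
    mean(vapply(seq_len(ncol(A)),
                function(r) cosine(A[, r], B[, p[r]]), numeric(1)))
  }, numeric(1)))
}

# minimum per-column Tucker congruence after the best permutation
aligned_congruence <- function(A, B) {
  max(vapply(all_permutations(ncol(A)), function(p) {
    min(vapply(seq_len(ncol(A)),
               function(r) abs(cosine(A[, r], B[, p[r]])), numeric(1)))
  }, numeric(1)))
}

# alternating non-negative least squares oracle for NMF (columnwise
# pracma::lsqnonneg), independent of the multiplicative-update path
anls_nmf <- function(X, U, V, tol = 1e-13, max_iter = 2000) {
  sse <- sum((X - U %*% t(V))^2)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(ncol(X))) {
      V[j, ] <- pracma::lsqnonneg(U, X[, j])$x
    }
    for (i in seq_len(nrow(X))) {
      U[i, ] <- pracma::lsqnonneg(V, X[i, ])$x
    }
    sse_new <- sum((X - U %*% t(V))^2)
    if (abs(sse - sse_new) <= tol * max(sse, 1e-12)) {
      sse <- sse_new
      break
    }
    sse <- sse_new
  }
  list(U = U, V = V, sse = sse)
}

# planted two-topic corpus with disjoint pattern supports
planted_corpus <- function(J = 200, len = 100, G = 20, seed = 1) {
  set.seed(seed)
  beta <- matrix(0, 2, G)
  b1 <- stats::rgamma(G / 2, 1)
  b2 <- stats::rgamma(G / 2, 1)
  beta[1, 1:(G / 2)] <- b1 / sum(b1)
  beta[2, (G / 2 + 1):G] <- b2 / sum(b2)
  theta <- matrix(stats::rbeta(J, 0.3, 0.3), J, 1)
  theta <- cbind(theta, 1 - theta)
  F_mat <- matrix(0L, J, G)
  for (j in seq_len(J)) {
    z <- stats::rbinom(len, 1, theta[j, 2]) + 1
    for (k in 1:2) {
      nk <- sum(z == k)
      if (nk > 0) {
        draws <- sample.int(G, nk, replace = TRUE, prob = beta[k, ])
        F_mat[j, ] <- F_mat[j, ] + tabulate(draws, G)
      }
    }
  }
  colnames(F_mat) <- sprintf("g%02d", seq_len(G))
  rownames(F_mat) <- sprintf("doc%03d", seq_len(J))
  list(F = F_mat, beta = beta, theta = theta)
}

# cached moderate cohorts so several test files can share one simulation
cohort_cache <- local({
  cache <- new.env(parent = emptyenv())
  function(key, config) {
    if (!exists(key, envir = cache)) {
      assign(key, simulate_cohort(config), envir = cache)
    }
    get(key, envir = cache)
  }
})
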