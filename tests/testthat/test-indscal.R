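random_tensor <- function(I, M, T = 36, seed = 1) {
  set.seed(seed)
  A <- array(runif(I * M * T), dim = c(I, M, T),
             dimnames = list(paste0("c", seq_len(I)),
                             paste0("s", seq_len(M)), NULL))
  class(A) <- c("symptom_tensor", "array")
  A
}

# well-separated planted INDSCAL structure
planted_indscal <- function(I = 20, L = 8, R = 2, seed = 2) {
  set.seed(seed)
  A <- qr.Q(qr(matrix(rnorm(I * R), I, R)))     # orthonormal coordinates
  C <- matrix(0, L, R)
  C[1:(L / 2), 1] <- runif(L / 2, 1, 2)
  C[(L / 2 + 1):L, 2] <- runif(L / 2, 1, 2)     # disjoint condition support
  D <- array(0, dim = c(I, I, L))
  for (l in seq_len(L)) {
    D[, , l] <- A %*% diag(C[l, ], R) %*% t(A)
  }
  list(A = A, C = C, D = D)
}

test_that("pointwise dissimilarities equal a brute-force triple loop", {
  tn <- random_tensor(4, 3, seed = 8)
  for (metric in c("abs", "sq")) {
    D <- build_dissimilarity(tn, metric = metric)
    I <- 4; M <- 3; T <- 36
    expect_equal(dim(D), c(I, I, M * T))
    for (i in 1:I) for (ip in 1:I) for (m in 1:M) for (t in c(1, 17, 36)) {
      l <- (m - 1) * T + t
      dif <- tn[i, m, t] - tn[ip, m, t]
      expect_equal(D[i, ip, l], if (metric == "abs") abs(dif) else dif^2)
    }
  }
  # symmetric, zero diagonal; identical children give a zero slice
  D <- build_dissimilarity(tn)
  expect_equal(D, aperm(D, c(2, 1, 3)), ignore_attr = TRUE)
  expect_true(all(abs(apply(D, 3, diag)) == 0))

  tn2 <- random_tensor(2, 2, seed = 9)
  tn2[2, , ] <- tn2[1, , ]
  expect_true(all(build_dissimilarity(tn2) == 0))

  tn3 <- random_tensor(2, 1, seed = 10)
  tn3[1, , ] <- 1; tn3[2, , ] <- 0
  D3 <- build_dissimilarity(tn3)
  expect_true(all(D3[1, 2, ] == 1))
})

test_that("planted symmetric factors are recovered with high congruence", {
  p <- planted_indscal()
  fit <- fit_indscal(p$D, R = 2, n_starts = 3, seed = 5)
  expect_gt(fit$explained_variance, 0.999)
  expect_gt(aligned_congruence(fit$A, p$A), 0.99)
  expect_gt(aligned_congruence(fit$C, p$C), 0.99)
  expect_true(all(fit$C >= 0))
})

test_that("a one-condition rank-1 fit matches the eigen oracle", {
  set.seed(12)
  a <- rnorm(15)
  D <- array(2.5 * outer(a, a), dim = c(15, 15, 1))
  fit <- fit_indscal(D, R = 1, n_starts = 3, seed = 4)
  ev <- eigen(D[, , 1], symmetric = TRUE)
  sse_opt <- sum(D^2) - ev$values[1]^2   # best PSD rank-1 approximation
  expect_equal(fit$sse, sse_opt, tolerance = 1e-6)
  expect_gt(abs(cosine(fit$A[, 1], ev$vectors[, 1])), 1 - 1e-6)
})

test_that("degenerate and invalid inputs are handled", {
  zero <- array(0, dim = c(4, 4, 3))
  f <- fit_indscal(zero, 2)
  expect_equal(f$sse, 0)
  expect_equal(f$explained_variance, 1)

  bad <- array(runif(4 * 4 * 2), dim = c(4, 4, 2))
  expect_error(fit_indscal(bad, 1), "not symmetric")
  p <- planted_indscal(I = 6)
  expect_error(fit_indscal(p$D, 9), "R must lie")
})

test_that("the ALS objective decreases and EV grows with rank", {
  p <- planted_indscal(I = 12, L = 6, seed = 3)
  noisy <- p$D + array(abs(rnorm(12 * 12 * 6, sd = 0.05)),
                       dim = dim(p$D))
  noisy <- (noisy + aperm(noisy, c(2, 1, 3))) / 2
  fit <- fit_indscal(noisy, 2, n_starts = 1, seed = 6, trace = TRUE)
  expect_true(all(diff(fit$sse_trace) <= 1e-10 * max(fit$sse_trace)))
  evs <- vapply(1:3, function(R) {
    fit_indscal(noisy, R, n_starts = 2, seed = 6)$explained_variance
  }, numeric(1))
  expect_true(all(diff(evs) > -1e-8))
})

test_that("condition weights join back to their symptom-month identity", {
  tn <- random_tensor(6, 2, seed = 14)
  D <- build_dissimilarity(tn)
  fit <- fit_indscal(D, 1, n_starts = 1, max_iter = 50, seed = 2)
  ct <- component_table(fit)
  expect_equal(nrow(ct$conditions), 2 * 36)
  expect_true(all(ct$conditions$weight >= 0))
  expect_equal(nrow(ct$children), 6)
  l <- 40  # condition 40 = symptom 2, slot 4
  key <- fit$condition_keys[l, ]
  row <- ct$conditions[ct$conditions$symptom == key$symptom &
                         ct$conditions$year == key$year &
                         ct$conditions$month == key$month, ]
  expect_equal(row$weight, fit$C[l, 1])
})
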