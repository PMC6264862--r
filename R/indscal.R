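#' Pointwise dissimilarity tensor between children
#'
#' For every condition — a (symptom, month-slot) combination l =
#' (m - 1) * T + t — computes the pointwise difference between each pair
#' of children's monthly proportions, yielding the I x I x L array fed
#' to INDSCAL. The default metric is the absolute difference
#' `|x_itm - x_i'tm|`; squared differences are available as an option.
#'
#' @param tensor A `symptom_tensor` from [build_tensor()] (no undefined
#'   cells).
#' @param metric `"abs"` (default) or `"sq"`.
#' @return An I x I x L array of class `dissimilarity_tensor`, symmetric
#'   with zero diagonal in its first two modes, with attribute
#'   `condition_keys` mapping l to (symptom, t, year, month).
#' @export
build_dissimilarity <- function(tensor, metric = c("abs", "sq")) {
  metric <- match.arg(metric)
  if (anyNA(tensor)) stop("build_dissimilarity: tensor has undefined cells")
  X <- matricize(tensor)            # I x L, condition-major order matches
  keys <- attr(X, "column_keys")
  I <- nrow(X); L <- ncol(X)
  D <- array(0, dim = c(I, I, L))
  for (l in seq_len(L)) {
    dif <- outer(X[, l], X[, l], "-")
    D[, , l] <- if (metric == "abs") abs(dif) else dif^2
  }
  names(keys)[names(keys) == "column"] <- "condition"
  structure(D, condition_keys = keys, metric = metric,
            child_ids = rownames(X),
            class = c("dissimilarity_tensor", "array"))
}

khatri_rao <- function(P, Q) {
  # columnwise Kronecker; rows ordered with Q's index varying fastest
  R <- ncol(P)
  out <- matrix(0, nrow(P) * nrow(Q), R)
  for (r in seq_len(R)) out[, r] <- P[, r] %x% Q[, r]
  out
}

# Rowwise non-negative least squares sharing one normal matrix:
# minimise c' G c - 2 h' c over c >= 0 for every row h of H. For small R
# the unique KKT point is found exactly by enumerating active sets
# (G positive definite); larger R falls back to pracma::lsqnonneg.
nnls_rows <- function(G, H) {
  R <- nrow(G)
  L <- nrow(H)
  out <- matrix(0, L, R)
  if (R > 10) {
    ch <- tryCatch(chol(G),
                   error = function(e) chol(G + 1e-10 * diag(R)))
    for (l in seq_len(L)) {
      y <- forwardsolve(t(ch), H[l, ])
      out[l, ] <- pracma::lsqnonneg(ch, y)$x
    }
    return(out)
  }
  unsolved <- rep(TRUE, L)
  # empty active set: c = 0 optimal iff all gradients -2h are >= 0
  free0 <- which(apply(H <= 1e-12, 1, all))
  unsolved[free0] <- FALSE
  subsets <- order(-vapply(
    seq_len(2^R - 1),
    function(s) sum(bitwAnd(s, bitwShiftL(1, 0:(R - 1))) > 0), numeric(1)))
  for (s in subsets) {
    if (!any(unsolved)) break
    S <- which(bitwAnd(s, bitwShiftL(1, 0:(R - 1))) > 0)
    Gi <- tryCatch(solve(G[S, S, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(Gi)) next
    rows <- which(unsolved)
    Cs <- H[rows, S, drop = FALSE] %*% Gi
    feas <- rowSums(Cs < -1e-10) == 0
    if (length(S) < R) {
      comp <- setdiff(seq_len(R), S)
      slack <- Cs %*% G[S, comp, drop = FALSE] - H[rows, comp, drop = FALSE]
      feas <- feas & rowSums(slack < -1e-8) == 0
    }
    hit <- rows[feas]
    if (length(hit) > 0) {
      out[hit, S] <- pmax(Cs[feas, , drop = FALSE], 0)
      unsolved[hit] <- FALSE
    }
  }
  if (any(unsolved)) {
    ch <- tryCatch(chol(G),
                   error = function(e) chol(G + 1e-10 * diag(R)))
    for (l in which(unsolved)) {
      y <- forwardsolve(t(ch), H[l, ])
      out[l, ] <- pracma::lsqnonneg(ch, y)$x
    }
  }
  out
}

#' Fit the INDSCAL model by alternating least squares
#'
#' Fits `x_ii'l = sum_r a_ir a_i'r c_lr + e_ii'l` to a stack of symmetric
#' dissimilarity matrices: a trilinear (PARAFAC-type) decomposition with
#' the two object modes constrained equal and the condition weights C
#' constrained non-negative. The practical coupling strategy is used:
#' each ALS sweep updates the two object-mode factors by unconstrained
#' least squares, sign-aligns and averages them, re-imposes the average
#' on both modes, and then updates each row of C by non-negative least
#' squares. Restarted from `n_starts` seeded uniform initialisations;
#' the lowest-SSE solution is kept. Columns of A are normalised to unit
#' Euclidean norm with the scale moved into C.
#'
#' @param D A `dissimilarity_tensor` (or plain I x I x L array symmetric
#'   in its first two modes).
#' @param R Number of components, `1 <= R <= I`.
#' @param n_starts Random restarts (default 5).
#' @param tol Relative SSE change convergence threshold (default 1e-8).
#' @param max_iter Maximum ALS sweeps per start (default 500).
#' @param seed Base seed.
#' @param trace Keep the per-iteration SSE trace of the best start.
#' @return An object of class `indscal_fit`: `A` (I x R child
#'   coordinates, unconstrained sign), `C` (L x R non-negative condition
#'   weights), `sse`, `explained_variance`, `iterations`, `converged`,
#'   `n_starts`, `best_start_seed`, optionally `sse_trace`.
#' @export
fit_indscal <- function(D, R, n_starts = 5, tol = 1e-8, max_iter = 500,
                        seed = 1, trace = FALSE) {
  dims <- dim(D)
  I <- dims[1]; L <- dims[3]
  if (dims[2] != I) stop("fit_indscal: first two modes must have equal size")
  if (R < 1 || R > I) stop("fit_indscal: R must lie in 1..I")
  asym <- max(abs(D - aperm(D, c(2, 1, 3))))
  if (asym > 1e-8) stop("fit_indscal: input not symmetric in (i, i')")

  X1 <- matrix(D, nrow = I)                 # I x (I*L), i' fastest
  X3 <- matrix(aperm(D, c(3, 1, 2)), nrow = L)  # L x I^2, i fastest
  normD2 <- sum(X1^2)
  if (normD2 == 0) {
    return(structure(list(A = matrix(0, I, R), C = matrix(0, L, R),
                          sse = 0, explained_variance = 1, iterations = 0L,
                          converged = TRUE, n_starts = n_starts,
                          best_start_seed = NA_integer_),
                     class = "indscal_fit"))
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    start_seed <- seed + s
    set.seed(start_seed)
    A <- matrix(runif(I * R), I, R)
    C <- matrix(runif(L * R), L, R)
    fit <- indscal_als_run(X1, X3, A, C, I, L, R, normD2, tol, max_iter,
                           trace)
    if (is.null(best) || fit$sse < best$sse) {
      best <- fit
      best$start_seed <- start_seed
    }
  }
  # unit-norm columns of A; scale (squared, A enters twice) moves into C
  nrm <- sqrt(colSums(best$A^2))
  nrm[nrm == 0] <- 1
  A <- sweep(best$A, 2, nrm, "/")
  C <- sweep(best$C, 2, nrm^2, "*")
  structure(list(A = A, C = C, sse = best$sse,
                 explained_variance = 1 - best$sse / normD2,
                 iterations = best$iterations, converged = best$converged,
                 n_starts = n_starts, best_start_seed = best$start_seed,
                 sse_trace = best$sse_trace,
                 condition_keys = attr(D, "condition_keys"),
                 child_ids = attr(D, "child_ids")),
            class = "indscal_fit")
}

indscal_als_run <- function(X1, X3, A, C, I, L, R, normD2, tol, max_iter,
                            trace = FALSE) {
  ridge <- function(G) {
    tryCatch(solve(G), error = function(e) solve(G + 1e-10 * diag(nrow(G))))
  }
  sse <- Inf
  sse_trace <- NULL
  converged <- FALSE
  iter <- 0L
  B <- A
  while (iter < max_iter) {
    iter <- iter + 1L
    # object modes (B is the mode-2 copy of A)
    W <- khatri_rao(C, B)
    A_new <- X1 %*% W %*% ridge(crossprod(C) * crossprod(B))
    W <- khatri_rao(C, A_new)
    B_new <- X1 %*% W %*% ridge(crossprod(C) * crossprod(A_new))
    # sign-align columns, then average and re-impose on both modes
    sgn <- sign(colSums(A_new * B_new))
    sgn[sgn == 0] <- 1
    A <- (A_new + sweep(B_new, 2, sgn, "*")) / 2
    B <- A
    # condition weights: rowwise NNLS on the shared normal matrix
    AtA <- crossprod(A)
    G <- AtA * AtA
    H <- X3 %*% khatri_rao(A, A)          # L x R
    C <- nnls_rows(G, H)
    sse_new <- normD2 - 2 * sum(C * H) + sum((C %*% G) * C)
    if (trace) sse_trace <- c(sse_trace, sse_new)
    if (is.finite(sse) && abs(sse - sse_new) <= tol * max(sse, 1e-12)) {
      sse <- sse_new
      converged <- TRUE
      break
    }
    sse <- sse_new
  }
  list(A = A, C = C, sse = sse, iterations = iter, converged = converged,
       sse_trace = sse_trace)
}

#' @export
print.indscal_fit <- function(x, ...) {
  cat("<indscal_fit>", ncol(x$A), "components - EV",
      sprintf("%.3f", x$explained_variance),
      "(best of", x$n_starts, "starts,", x$iterations, "sweeps)\n")
  invisible(x)
}

#' Long-format condition-weight table for INDSCAL components
#'
#' Joins the non-negative condition weights C back to their (symptom,
#' year, month) identity and exports the child coordinates, supporting
#' component-vs-component scatter interpretation (typically one general
#' prevalence component plus discriminative ones).
#'
#' @param fit An `indscal_fit`.
#' @param condition_keys Condition key table; defaults to the one stored
#'   in the fit.
#' @return List with `conditions` (symptom, year, month, component,
#'   weight; L x R rows) and `children` (child scores A).
#' @export
component_table <- function(fit, condition_keys = fit$condition_keys) {
  if (is.null(condition_keys) || nrow(fit$C) != nrow(condition_keys)) {
    stop("component_table: condition keys do not match C")
  }
  conditions <- do.call(rbind, lapply(seq_len(ncol(fit$C)), function(r) {
    data.frame(symptom = condition_keys$symptom,
               year = condition_keys$year, month = condition_keys$month,
               component = r, weight = fit$C[, r])
  }))
  rownames(conditions) <- NULL
  children <- as.data.frame(fit$A)
  names(children) <- paste0("component", seq_len(ncol(fit$A)))
  if (!is.null(fit$child_ids)) children <- cbind(child_id = fit$child_ids,
                                                 children)
  list(conditions = conditions, children = children)
}
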