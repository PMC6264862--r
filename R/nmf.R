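#' Non-negative matrix factorization by multiplicative updates
#'
#' Approximates a non-negative matrix X (children x symptom-month
#' features) as `U %*% t(V)` with `U >= 0` (I x R child scores) and
#' `V >= 0` (MT x R feature loadings), minimising squared Frobenius
#' error with the classical multiplicative update rules. Because the
#' objective is non-convex, the fit is restarted `n_starts` times from
#' independent uniform(0,1) initialisations (per-start seed =
#' `seed + start`) and the lowest-SSE solution is kept. Components are
#' not orthogonal; quality is reported per model via explained variance
#' `1 - ||X - U V'||^2 / ||X||^2`.
#'
#' A small epsilon (1e-12) in the update denominators guards against
#' zero-locking. On output the columns of V are normalised to unit
#' maximum, with the scale moved into U (the factorization itself is
#' scale-indeterminate).
#'
#' @param X Non-negative numeric matrix.
#' @param R Rank (number of components), `1 <= R <= min(dim(X))`.
#' @param n_starts Number of random restarts (default 25).
#' @param seed Base seed for the restarts.
#' @param tol Convergence threshold on the relative SSE change per
#'   iteration (default 1e-6).
#' @param max_iter Maximum iterations per start (default 2000).
#' @param trace Keep the per-iteration SSE trace of the best start.
#' @return An object of class `nmf_fit`: list with `U`, `V`, `R`, `sse`,
#'   `explained_variance`, `n_starts`, `best_start_seed`, `iterations`,
#'   `converged`, the best start's initial factors `U0`, `V0`, and
#'   optionally `sse_trace`.
#' @export
fit_nmf <- function(X, R, n_starts = 25, seed = 1, tol = 1e-6,
                    max_iter = 2000, trace = FALSE) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("fit_nmf: X must be non-negative")
  if (R < 1 || R > min(dim(X))) {
    stop("fit_nmf: R must lie in 1..min(I, MT)")
  }
  normX2 <- sum(X^2)
  if (normX2 == 0) {
    U <- matrix(0, nrow(X), R); V <- matrix(0, ncol(X), R)
    return(structure(list(U = U, V = V, R = R, sse = 0,
                          explained_variance = 1, n_starts = n_starts,
                          best_start_seed = NA_integer_, iterations = 0L,
                          converged = TRUE, U0 = U, V0 = V),
                     class = "nmf_fit"))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start_seed <- seed + s
    set.seed(start_seed)
    U0 <- matrix(runif(nrow(X) * R), nrow(X), R)
    V0 <- matrix(runif(ncol(X) * R), ncol(X), R)
    fit <- nmf_mu_run(X, U0, V0, tol, max_iter, trace)
    if (is.null(best) || fit$sse < best$sse) {
      best <- fit
      best$start_seed <- start_seed
      best$U0 <- U0; best$V0 <- V0
    }
  }
  # fix scale indeterminacy: unit-max columns of V
  scl <- apply(best$V, 2, max)
  scl[scl == 0] <- 1
  V <- sweep(best$V, 2, scl, "/")
  U <- sweep(best$U, 2, scl, "*")
  structure(list(U = U, V = V, R = R, sse = best$sse,
                 explained_variance = 1 - best$sse / normX2,
                 n_starts = n_starts, best_start_seed = best$start_seed,
                 iterations = best$iterations, converged = best$converged,
                 U0 = best$U0, V0 = best$V0,
                 sse_trace = best$sse_trace), class = "nmf_fit")
}

# One multiplicative-update run from a given initialisation.
nmf_mu_run <- function(X, U, V, tol, max_iter, trace = FALSE) {
  eps <- 1e-12
  sse <- sum((X - U %*% t(V))^2)
  sse_trace <- if (trace) sse else NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    U <- U * (X %*% V) / (U %*% crossprod(V) + eps)
    V <- V * (crossprod(X, U)) / (V %*% crossprod(U) + eps)
    sse_new <- sum((X - U %*% t(V))^2)
    if (trace) sse_trace <- c(sse_trace, sse_new)
    if (abs(sse - sse_new) <= tol * max(sse, eps)) {
      sse <- sse_new
      converged <- TRUE
      break
    }
    sse <- sse_new
  }
  list(U = U, V = V, sse = sse, iterations = iter, converged = converged,
       sse_trace = sse_trace)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("<nmf_fit> rank", x$R, "- EV",
      sprintf("%.3f", x$explained_variance),
      "(best of", x$n_starts, "starts,", x$iterations, "iterations)\n")
  invisible(x)
}

#' Rank sweep with additional-explained-variance scree
#'
#' Fits NMF models over a range of ranks (default 1..8, each the best of
#' `n_starts` restarts) and tabulates, per rank r, the explained
#' variance EV(r) and the additional explained variance
#' `EV(r) - EV(r - 1)` (with EV(0) = 0) — the scree used to choose the
#' number of components. Reported per model, not per component, since
#' components are not orthogonal.
#'
#' @inheritParams fit_nmf
#' @param ranks Integer vector of ranks to fit (default 1:8).
#' @return List with `fits` (one `nmf_fit` per rank) and `scree` (data
#'   frame: rank, sse, explained_variance, additional_ev).
#' @export
rank_sweep <- function(X, ranks = 1:8, n_starts = 25, seed = 1,
                       tol = 1e-6, max_iter = 2000) {
  fits <- lapply(ranks, function(r) {
    fit_nmf(X, r, n_starts = n_starts, seed = seed + 1000 * r,
            tol = tol, max_iter = max_iter)
  })
  ev <- vapply(fits, function(f) f$explained_variance, numeric(1))
  scree <- data.frame(rank = ranks,
                      sse = vapply(fits, function(f) f$sse, numeric(1)),
                      explained_variance = ev,
                      additional_ev = ev - c(0, ev[-length(ev)]))
  list(fits = setNames(fits, paste0("R", ranks)), scree = scree)
}

#' Long-format loading table for NMF components
#'
#' Joins the rows of V back to their (symptom, year, month) identity so
#' that every loading can be plotted or exported as a symptom,
#' month-year combination.
#'
#' @param fit An `nmf_fit`.
#' @param column_keys The `column_keys` attribute of the matricized
#'   matrix the model was fitted to.
#' @return Data frame: symptom, year, month, component, weight
#'   (MT x R rows).
#' @export
loading_table <- function(fit, column_keys) {
  if (nrow(fit$V) != nrow(column_keys)) {
    stop("loading_table: ", nrow(fit$V), " loadings but ",
         nrow(column_keys), " column keys")
  }
  out <- do.call(rbind, lapply(seq_len(fit$R), function(r) {
    data.frame(symptom = column_keys$symptom, year = column_keys$year,
               month = column_keys$month, component = r,
               weight = fit$V[, r])
  }))
  rownames(out) <- NULL
  out
}
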