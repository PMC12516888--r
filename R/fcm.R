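# Fuzzy C-means soft clustering of TF-IDF feature vectors.
#
# Standard alternating fixed-point updates:
#   u_ij = 1 / sum_l (d_ij / d_lj)^(2/(m-1)),
#   c_i  = sum_j u_ij^m x_j / sum_j u_ij^m,
# run until the objective J_m = sum_ij u_ij^m ||x_j - c_i||^2 changes by
# less than `tol`, best of `n_restarts` random starts by final objective.
# Points exactly coincident with a centroid receive membership 1 there.

#' Fuzzy C-means configuration
#'
#' Defaults follow the clustering setup used throughout the package:
#' `k = 6` clusters and fuzziness exponent `m = 1.2`, chosen to balance
#' cluster overlap and separation for mortality-cause feature grouping.
#'
#' @param k number of clusters (>= 1).
#' @param m fuzziness exponent (> 1); values near 1 approach hard k-means.
#' @param tol convergence tolerance on the objective change.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of random restarts.
#' @param seed integer RNG seed.
#' @return a list of class `fcm_config`.
#' @export
fcm_config <- function(k = 6L, m = 1.2, tol = 1e-7, max_iter = 500L,
                       n_restarts = 10L, seed = 1L) {
  stopifnot(k >= 1L, m > 1, tol > 0, max_iter >= 1L, n_restarts >= 1L)
  structure(list(k = as.integer(k), m = m, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "fcm_config")
}

.sqdist <- function(centers, X) {
  # k x n matrix of squared Euclidean distances
  cn <- rowSums(centers^2)
  xn <- rowSums(X^2)
  d2 <- outer(cn, xn, `+`) - 2 * tcrossprod(centers, X)
  pmax(d2, 0)
}

.fcm_memberships <- function(d2, m) {
  k <- nrow(d2)
  n <- ncol(d2)
  U <- matrix(0, k, n)
  expo <- 1 / (m - 1)  # applied to squared distances = (d_ij/d_lj)^(2/(m-1))
  zero <- d2 < 1e-24
  for (j in seq_len(n)) {
    if (any(zero[, j])) {
      hits <- which(zero[, j])
      U[hits, j] <- 1 / length(hits)
    } else {
      inv <- (1 / d2[, j])^expo
      U[, j] <- inv / sum(inv)
    }
  }
  U
}

.fcm_objective <- function(U, d2, m) sum((U^m) * d2)

.fcm_single <- function(X, k, m, tol, max_iter, init = NULL) {
  n <- nrow(X)
  centers <- if (is.null(init)) X[sample.int(n, k), , drop = FALSE] else init
  trace <- numeric(0)
  j_prev <- Inf
  U <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- .sqdist(centers, X)
    U <- .fcm_memberships(d2, m)
    Um <- U^m
    wsum <- rowSums(Um)
    newc <- (Um %*% X) / wsum
    degen <- wsum < 1e-30
    if (any(degen)) newc[degen, ] <- centers[degen, , drop = FALSE]
    centers <- newc
    j_cur <- .fcm_objective(U, .sqdist(centers, X), m)
    trace <- c(trace, j_cur)
    if (is.finite(j_prev) && abs(j_prev - j_cur) < tol) break
    j_prev <- j_cur
  }
  list(U = U, centroids = centers, objective_trace = trace,
       objective = trace[length(trace)], iterations = length(trace))
}

#' Fuzzy C-means clustering
#'
#' @param X numeric matrix (rows = points, e.g. the `weights` of a
#'   [build_tfidf()] result) or a `tfidf_matrix`.
#' @param config an [fcm_config()].
#' @param init optional k x d matrix of initial centroids; when given, a
#'   single run is performed from exactly these centers (no restarts).
#' @return object of class `fcm_fit`: `U` (k x n membership matrix, columns
#'   sum to 1), `centroids`, `objective_trace` (non-increasing),
#'   `objective`, `iterations`, `config`, and `features` (column names of
#'   `U`).
#' @export
fuzzy_cmeans <- function(X, config = fcm_config(), init = NULL) {
  if (inherits(X, "tfidf_matrix")) X <- X$weights
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in input", call. = FALSE)
  n <- nrow(X)
  if (n < config$k) stop("fewer points than clusters", call. = FALSE)

  set.seed(config$seed)
  if (!is.null(init)) {
    init <- as.matrix(init)
    stopifnot(nrow(init) == config$k, ncol(init) == ncol(X))
    best <- .fcm_single(X, config$k, config$m, config$tol, config$max_iter,
                        init = init)
  } else {
    best <- NULL
    for (r in seq_len(config$n_restarts)) {
      fit <- .fcm_single(X, config$k, config$m, config$tol, config$max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  }
  dimnames(best$U) <- list(paste0("cluster_", seq_len(config$k)),
                           rownames(X))
  structure(
    c(best, list(config = config, features = rownames(X))),
    class = "fcm_fit"
  )
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("Fuzzy C-means fit: k = %d, m = %.3g, %d points, J = %.6g (%d iterations)\n",
              nrow(x$U), x$config$m, ncol(x$U), x$objective, x$iterations))
  invisible(x)
}
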