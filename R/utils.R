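`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` cross-validation folds such that
#' every outcome class is spread as evenly as possible across folds. Used
#' throughout model tuning and stacking so that each fold's event rate stays
#' within `1/k` of the cohort rate.
#'
#' @param y outcome vector (any type with a small number of distinct values).
#' @param k number of folds (>= 2).
#' @param seed optional integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, same length as `y`.
#' @export
stratified_folds <- function(y, k = 5L, seed = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 2L, length(y) >= k)
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Deterministic per-stage sub-seed from a master seed and a stream name,
# kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stream) {
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch)) %% 1000003
  as.integer((as.numeric(seed) %% 2147483 * 1000 + h) %% 2147483647)
}

assert_binary_labels <- function(y) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  invisible(as.numeric(y))
}
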