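# Thresholded multi-membership cluster assignment and labelling.

#' Assign features to clusters by membership cutoff
#'
#' A feature joins every cluster whose membership reaches the cutoff
#' (soft multi-membership); memberships within `tie_eps` below the cutoff
#' are also retained, so exact ties at the boundary are kept. A feature
#' reaching no cluster falls back to its argmax cluster alone, which
#' guarantees every feature belongs to at least one cluster.
#'
#' @param fit an `fcm_fit` (or a bare k x n membership matrix `U`).
#' @param cutoff minimum membership in (0, 1]; default 0.2.
#' @param tie_eps tolerance for exact ties at the cutoff boundary.
#' @return object of class `cluster_assignment`: `members` (named list,
#'   feature -> integer cluster indices), `fallback` (logical per feature),
#'   `labels` (cluster index -> name), `cutoff`, `U`.
#' @export
assign_clusters <- function(fit, cutoff = 0.2, tie_eps = 1e-12) {
  stopifnot(cutoff > 0, cutoff <= 1)
  U <- if (inherits(fit, "fcm_fit")) fit$U else as.matrix(fit)
  k <- nrow(U)
  feats <- colnames(U) %||% paste0("feature_", seq_len(ncol(U)))
  labels <- rownames(U) %||% paste0("cluster_", seq_len(k))

  members <- vector("list", ncol(U))
  fallback <- logical(ncol(U))
  for (j in seq_len(ncol(U))) {
    keep <- which(U[, j] >= cutoff - tie_eps)
    if (length(keep) == 0L) {
      keep <- which.max(U[, j])
      fallback[j] <- TRUE
    }
    members[[j]] <- as.integer(keep)
  }
  names(members) <- feats
  names(fallback) <- feats
  structure(list(members = members, fallback = fallback,
                 labels = labels, cutoff = cutoff, U = U),
            class = "cluster_assignment")
}

#' Attach clinician labels to clusters
#'
#' @param assignment a `cluster_assignment`.
#' @param label_map named vector/list mapping cluster index (as integer or
#'   `"1"`-style name) to a human label, e.g.
#'   `c("1" = "Liver Failure", "2" = "Infection")`. Unlabelled clusters keep
#'   their index names. Duplicate labels are an error.
#' @return the assignment with `labels` updated.
#' @export
label_clusters <- function(assignment, label_map) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (length(label_map) == 0L) return(assignment)
  idx <- as.integer(names(label_map))
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(assignment$labels))) {
    stop("label_map keys must be valid cluster indices", call. = FALSE)
  }
  labs <- assignment$labels
  labs[idx] <- unlist(label_map, use.names = FALSE)
  if (anyDuplicated(labs)) stop("duplicate cluster labels", call. = FALSE)
  assignment$labels <- labs
  rownames(assignment$U) <- labs
  assignment
}

#' Features belonging to each cluster
#'
#' @param assignment a `cluster_assignment`.
#' @return named list: cluster label -> character vector of features.
#' @export
cluster_feature_sets <- function(assignment) {
  k <- length(assignment$labels)
  out <- lapply(seq_len(k), function(i) {
    names(Filter(function(m) i %in% m, assignment$members))
  })
  names(out) <- assignment$labels
  out
}

#' Long-format membership table for heatmap plotting
#'
#' @param fit an `fcm_fit`.
#' @param assignment matching `cluster_assignment`.
#' @return data.frame with columns `feature`, `cluster`, `membership`,
#'   `retained`; one row per (cluster, feature) pair.
#' @export
membership_heatmap_export <- function(fit, assignment) {
  U <- fit$U
  k <- nrow(U)
  feats <- colnames(U)
  df <- data.frame(
    feature = rep(feats, each = k),
    cluster = rep(assignment$labels, times = length(feats)),
    membership = as.vector(U),
    stringsAsFactors = FALSE
  )
  df$retained <- mapply(function(f, ci) ci %in% assignment$members[[f]],
                        df$feature, rep(seq_len(k), times = length(feats)))
  df
}

#' Cluster a description corpus end to end
#'
#' Convenience wrapper: preprocess the corpus, build the TF-IDF matrix, run
#' fuzzy C-means, and derive the thresholded assignment. Documents whose
#' bodies reduce to zero tokens are excluded from clustering (with a
#' warning) and assigned post hoc to the clusters of their nearest nonempty
#' neighbour in TF-IDF space (which, for an all-zero row, is the first
#' nonempty document; in practice empty documents indicate corpus problems
#' surfaced by [validate_corpus()]).
#'
#' @param corpus list of documents (`feature`, `body`).
#' @param config an [fcm_config()].
#' @param cutoff membership cutoff for [assign_clusters()].
#' @param stopwords,stem passed to [preprocess_corpus()].
#' @return list with `tfidf`, `fit` (`fcm_fit`), `assignment`.
#' @export
fit_semantic_clusters <- function(corpus, config = fcm_config(),
                                  cutoff = 0.2,
                                  stopwords = default_stopwords(),
                                  stem = TRUE) {
  toks <- preprocess_corpus(corpus, stopwords = stopwords, stem = stem)
  tfidf <- build_tfidf(toks)
  X <- tfidf$weights
  empty <- rownames(X) %in% tfidf$empty_docs
  if (any(empty)) {
    warning(sprintf("%d empty documents excluded from clustering: %s",
                    sum(empty), paste(tfidf$empty_docs, collapse = ", ")))
  }
  fit <- fuzzy_cmeans(X[!empty, , drop = FALSE], config)
  assignment <- assign_clusters(fit, cutoff = cutoff)
  if (any(empty)) {
    nonempty <- rownames(X)[!empty]
    for (f in rownames(X)[empty]) {
      d2 <- .sqdist(X[f, , drop = FALSE], X[nonempty, , drop = FALSE])
      nn <- nonempty[which.min(d2)]
      assignment$members[[f]] <- assignment$members[[nn]]
      assignment$fallback[f] <- TRUE
    }
  }
  list(tfidf = tfidf, fit = fit, assignment = assignment)
}

#' Write a cluster assignment to JSON
#'
#' @param assignment a `cluster_assignment`.
#' @param path output path.
#' @export
write_assignment <- function(assignment, path) {
  obj <- lapply(assignment$members, function(m) assignment$labels[m])
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
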