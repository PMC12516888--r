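# Classification metrics, threshold selection and model comparison.

#' Area under the ROC curve
#'
#' Rank (concordance) formulation: the probability that a random positive
#' outranks a random negative, with ties counted 1/2. Identical to
#' U / (n1 * n0) from the Mann-Whitney statistic on scores split by label.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- assert_binary_labels(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus sentinels, suitable for plotting.
#' @export
roc_points <- function(scores, labels) {
  labels <- assert_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               fpr = sum(pred & labels == 0) / sum(labels == 0),
               tpr = sum(pred & labels == 1) / sum(labels == 1))
  }))
}

#' Accuracy-maximizing decision threshold
#'
#' Candidate thresholds are the midpoints of consecutive distinct sorted
#' scores plus sentinels below and above all scores; the decision rule is
#' "predict positive when score >= threshold". Among maximizing candidates
#' the smallest is returned (favouring sensitivity).
#'
#' @inheritParams roc_auc
#' @return list with `threshold` and `accuracy`.
#' @export
select_threshold <- function(scores, labels) {
  labels <- assert_binary_labels(labels)
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2, Inf)
  acc <- vapply(cand, function(t) mean((scores >= t) == labels), numeric(1))
  best <- which(acc == max(acc))[1L]  # candidates ascending: smallest wins
  list(threshold = cand[best], accuracy = acc[best])
}

#' Classification metrics at a threshold
#'
#' Predicted positive when `score >= threshold`. Precision (and recall)
#' with a zero denominator are reported as `NA` with an `undefined` flag,
#' never coerced to 0.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold.
#' @param cohort optional tag (e.g. `"derivation"`, `"validation"`).
#' @return list of class `metrics_report`: `accuracy`, `recall`,
#'   `precision`, `f1`, `auc`, `threshold`, `counts` (tp/fp/tn/fn),
#'   `undefined` (character vector of undefined metrics), `cohort`.
#' @export
classification_metrics <- function(scores, labels, threshold,
                                   cohort = NA_character_) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  undefined <- character(0)
  precision <- if (tp + fp == 0) { undefined <- c(undefined, "precision"); NA_real_ } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { undefined <- c(undefined, "recall"); NA_real_ } else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall)) undefined <- c(undefined, "f1")
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  auc <- if (length(unique(labels)) == 2L) roc_auc(scores, labels) else NA_real_
  structure(list(accuracy = (tp + tn) / length(labels), recall = recall,
                 precision = precision, f1 = f1, auc = auc,
                 threshold = threshold,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 undefined = undefined, cohort = cohort),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics%s @ threshold %.4g\n",
              if (!is.na(x$cohort)) paste0(" (", x$cohort, ")") else "",
              x$threshold))
  cat(sprintf("  accuracy %.3f  recall %.3f  precision %.3f  F1 %.3f  AUC %.3f\n",
              x$accuracy, x$recall, x$precision, x$f1, x$auc))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from ranks for `sample_a` versus `sample_b`; the two-sided
#' p-value is exact (null enumeration) when `n_a + n_b <= 20` and no ties
#' are present, and a tie-corrected normal approximation otherwise
#' (delegated to [stats::wilcox.test()]).
#'
#' @param sample_a,sample_b nonempty numeric samples.
#' @return list with `U` (for `sample_a`), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("samples must be nonempty", call. = FALSE)
  }
  na <- length(sample_a); nb <- length(sample_b)
  r <- rank(c(sample_a, sample_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
  exact <- (na + nb) <= 20L && !ties
  p <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE)$p.value
  )
  list(U = U, p = min(p, 1), method = if (exact) "exact" else "normal_approx")
}

#' Compare two models' per-fold metrics
#'
#' Runs a two-sided Mann-Whitney U test per metric on matched per-fold
#' values; the verdict is "no significant difference" only when every
#' metric's p-value is at least `alpha`. With few folds the test has little
#' power, which is recorded in the returned note.
#'
#' @param metrics_a,metrics_b data.frames (folds x metrics) with identical
#'   column names and row counts.
#' @param alpha significance level (default 0.05).
#' @return list with `per_metric` (data.frame metric/U/p/significant),
#'   `verdict` (`"no significant difference"` or
#'   `"significant difference"`), `alpha`, `note`.
#' @export
compare_models <- function(metrics_a, metrics_b, alpha = 0.05) {
  if (!identical(dim(metrics_a), dim(metrics_b)) ||
      !identical(names(metrics_a), names(metrics_b))) {
    stop("metric tables must be matched", call. = FALSE)
  }
  res <- do.call(rbind, lapply(names(metrics_a), function(mname) {
    t <- mann_whitney_u(metrics_a[[mname]], metrics_b[[mname]])
    data.frame(metric = mname, U = t$U, p = t$p,
               significant = t$p < alpha, stringsAsFactors = FALSE)
  }))
  list(per_metric = res,
       verdict = if (any(res$significant)) "significant difference"
                 else "no significant difference",
       alpha = alpha,
       note = sprintf("per-fold samples of size %d per side; low power at small n",
                      nrow(metrics_a)))
}
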