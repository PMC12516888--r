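# Hierarchical gain-based importance and cluster-level Shapley explanations.

#' Normalized gain importance of a fitted booster
#'
#' Per-feature split gains summed across all trees and normalized to sum 1.
#' Features never used in a split receive exactly 0.
#'
#' @param model an `xgb.Booster` (or a `global_model` / `strong_learner`
#'   wrapper).
#' @param feature_names full feature name vector; defaults to the names
#'   stored in the model.
#' @return named numeric vector over `feature_names`, summing to 1.
#' @export
gain_importance <- function(model, feature_names = NULL) {
  if (inherits(model, "global_model")) {
    feature_names <- feature_names %||% model$features
    model <- model$model
  } else if (inherits(model, "strong_learner")) {
    feature_names <- feature_names %||% model$labels
    model <- model$model
  }
  trees <- xgboost::xgb.model.dt.tree(model = model)
  if (nrow(trees) == 0L || all(trees$Feature == "Leaf")) {
    stop("model has no split trees", call. = FALSE)
  }
  feature_names <- feature_names %||% setdiff(unique(trees$Feature), "Leaf")
  imp <- xgboost::xgb.importance(model = model)
  out <- setNames(numeric(length(feature_names)), feature_names)
  hit <- intersect(imp$Feature, feature_names)
  out[hit] <- imp$Gain[match(hit, imp$Feature)]
  out / sum(out)
}

#' Hierarchical importance report (cluster weight x within-cluster share)
#'
#' Combines the strong learner's per-cluster gain shares `w_i` with each
#' weak learner's within-cluster feature gain shares `f_ij` into final
#' importances `w_i * f_ij`, renormalized to sum 1 over all
#' (cluster, feature) pairs. A feature owned by several clusters has one
#' entry per owning cluster plus a summed per-feature total.
#'
#' @param w named numeric vector of per-cluster weights (strong-learner
#'   gains over exactly the K cluster inputs), or a `hybrid_model` from
#'   which both levels are extracted.
#' @param f_by_cluster named list (cluster -> named numeric of
#'   within-cluster feature importances); ignored when `w` is a
#'   `hybrid_model`.
#' @return object of class `importance_report`: `table` (data.frame
#'   cluster/feature/w/f/final), `cluster_weights`, `per_feature`
#'   (summed across owning clusters).
#' @export
hierarchical_importance <- function(w, f_by_cluster = NULL) {
  if (inherits(w, "hybrid_model")) {
    model <- w
    w <- gain_importance(model$strong)
    f_by_cluster <- lapply(model$weak$learners, function(l) {
      gain_importance(l$model, feature_names = l$features)
    })
    names(f_by_cluster) <- model$weak$labels
  }
  if (!setequal(names(w), names(f_by_cluster))) {
    stop("cluster labels of w and f_by_cluster disagree", call. = FALSE)
  }
  f_by_cluster <- f_by_cluster[names(w)]
  w <- w / sum(w)
  tab <- do.call(rbind, lapply(names(w), function(cl) {
    f <- f_by_cluster[[cl]]
    s <- sum(f)
    f <- if (s > 0) f / s else f
    data.frame(cluster = cl, feature = names(f), w = w[[cl]], f = as.numeric(f),
               final = w[[cl]] * as.numeric(f), stringsAsFactors = FALSE)
  }))
  tot <- sum(tab$final)
  if (tot > 0) tab$final <- tab$final / tot
  per_feature <- tapply(tab$final, tab$feature, sum)
  structure(list(table = tab[order(-tab$final), ],
                 cluster_weights = w,
                 per_feature = sort(per_feature, decreasing = TRUE)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, n = 10L, ...) {
  cat("Hierarchical importance (cluster weight x within-cluster share)\n")
  cat("Cluster weights:\n")
  print(round(x$cluster_weights, 3))
  cat(sprintf("Top %d (cluster, feature) importances:\n", n))
  print(head(x$table, n), row.names = FALSE)
  invisible(x)
}

# Coalition value: expected model output with off-coalition inputs drawn
# from the background sample (interventional expectation).
.coalition_values <- function(predict_fun, x, background) {
  k <- length(x)
  nb <- nrow(background)
  n_coal <- 2L^k
  # rows for all coalitions stacked: coalition index varies slowest
  big <- background[rep(seq_len(nb), times = n_coal), , drop = FALSE]
  for (s in 0:(n_coal - 1L)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(k - 1L))) != 0L)
    if (length(members)) {
      rows <- s * nb + seq_len(nb)
      big[rows, members] <- rep(x[members], each = nb)
    }
  }
  p <- predict_fun(big)
  vapply(0:(n_coal - 1L), function(s) mean(p[s * nb + seq_len(nb)]),
         numeric(1))
}

.as_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "strong_learner")) {
    spec <- model$spec
    booster <- model$model
    return(function(M) .predict_booster(booster, M, spec))
  }
  if (inherits(model, "global_model")) {
    return(function(M) predict_risk(model, M))
  }
  stop("model must be a function, strong_learner or global_model",
       call. = FALSE)
}

#' Exact Shapley explanation by coalition enumeration
#'
#' Exact Shapley values of the model output at `x`, with the value of a
#' coalition defined as the interventional expectation: off-coalition
#' inputs are replaced by background rows and the model output averaged.
#' Efficiency (baseline + sum of contributions = f(x)) holds by
#' construction.
#'
#' @param model a predict function `matrix -> probabilities`, a
#'   `strong_learner`, or a `global_model`.
#' @param x named numeric vector of inputs for the explained case (for the
#'   hybrid model: the K weak output probabilities of one stay).
#' @param background matrix of background rows (same columns as `x`).
#' @return object of class `shapley_explanation`: `baseline` (E[f(x)] over
#'   the background), `output` (f(x)), `contributions` (named), `method`.
#' @export
exact_shapley <- function(model, x, background) {
  k <- length(x)
  if (k > 15L) {
    stop("more than 15 players: use sampled_shapley()", call. = FALSE)
  }
  f <- .as_predict_fun(model)
  background <- .as_matrix(background)
  v <- .coalition_values(f, x, background)

  fact <- factorial(0:k)
  phi <- setNames(numeric(k), names(x))
  for (i in seq_len(k)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    for (s in 0:(2L^k - 1L)) {
      if (bitwAnd(s, bit_i) != 0L) next
      size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(k - 1L))) != 0L)
      wgt <- fact[size + 1L] * fact[k - size] / fact[k + 1L]
      phi[i] <- phi[i] + wgt * (v[s + bit_i + 1L] - v[s + 1L])
    }
  }
  structure(list(baseline = v[1L], output = v[2L^k], contributions = phi,
                 method = "exact", se = NULL),
            class = "shapley_explanation")
}

#' Permutation-sampled Shapley explanation
#'
#' Monte-Carlo estimate averaging marginal contributions over sampled
#' player orderings; each ordering is evaluated against the full background
#' sample, so additive models are recovered exactly regardless of the
#' number of permutations. Efficiency is enforced by distributing the small
#' residual proportionally to the absolute contributions; per-player
#' Monte-Carlo standard errors are reported.
#'
#' @inheritParams exact_shapley
#' @param n_permutations number of sampled orderings (>= 1).
#' @param seed integer seed.
#' @return a `shapley_explanation` with `method = "sampled"` and `se`.
#' @export
sampled_shapley <- function(model, x, background, n_permutations = 1000L,
                            seed = 1L) {
  stopifnot(n_permutations >= 1L)
  f <- .as_predict_fun(model)
  background <- .as_matrix(background)
  k <- length(x)
  nb <- nrow(background)
  set.seed(seed)

  baseline <- mean(f(background))
  contrib <- matrix(0, n_permutations, k, dimnames = list(NULL, names(x)))
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(k)
    # rows for steps 1..k: cumulative substitution along the ordering
    big <- background[rep(seq_len(nb), times = k), , drop = FALSE]
    members <- integer(0)
    for (step in seq_len(k)) {
      members <- c(members, ord[step])
      rows <- (step - 1L) * nb + seq_len(nb)
      big[rows, members] <- rep(x[members], each = nb)
    }
    vals <- f(big)
    step_means <- vapply(seq_len(k), function(s) {
      mean(vals[(s - 1L) * nb + seq_len(nb)])
    }, numeric(1))
    prev <- baseline
    for (step in seq_len(k)) {
      contrib[p, ord[step]] <- step_means[step] - prev
      prev <- step_means[step]
    }
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2L, sd) / sqrt(n_permutations)
  output <- mean(f(matrix(x, 1L, dimnames = list(NULL, names(x)))))
  resid <- (output - baseline) - sum(phi)
  if (abs(resid) > 0 && sum(abs(phi)) > 0) {
    phi <- phi + resid * abs(phi) / sum(abs(phi))
  }
  structure(list(baseline = baseline, output = output, contributions = phi,
                 method = "sampled", se = se),
            class = "shapley_explanation")
}

#' @export
print.shapley_explanation <- function(x, ...) {
  cat(sprintf("Shapley explanation (%s): E[f(x)] = %.4f, f(x) = %.4f\n",
              x$method, x$baseline, x$output))
  print(round(x$contributions, 4))
  invisible(x)
}

#' Waterfall table of a Shapley explanation
#'
#' Contributions sorted by decreasing absolute value; beyond `top_n` they
#' are aggregated into a single "other" row. Baseline and model-output rows
#' are included so the table sums consistently for waterfall plotting.
#'
#' @param explanation a `shapley_explanation`.
#' @param top_n number of individual rows to keep (default all).
#' @return data.frame with `item`, `value`, `cumulative`.
#' @export
waterfall_export <- function(explanation, top_n = Inf) {
  phi <- explanation$contributions
  ord <- order(-abs(phi))
  phi <- phi[ord]
  keep <- seq_len(min(top_n, length(phi)))
  rows <- data.frame(item = names(phi)[keep], value = as.numeric(phi[keep]),
                     stringsAsFactors = FALSE)
  rest <- phi[-keep]
  if (length(rest) > 0L) {
    rows <- rbind(rows, data.frame(
      item = sprintf("other (%d features)", length(rest)),
      value = sum(rest)
    ))
  }
  out <- rbind(
    data.frame(item = "baseline E[f(x)]", value = explanation$baseline),
    rows,
    data.frame(item = "f(x)", value = explanation$output)
  )
  n <- nrow(out)
  out$cumulative <- c(cumsum(out$value[-n]), explanation$output)
  rownames(out) <- NULL
  out
}
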