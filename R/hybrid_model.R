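# Stacked weak/strong boosted-tree ensemble.
#
# One weak XGBoost classifier per mortality-cause cluster, trained on that
# cluster's features only; a strong XGBoost classifier consumes the K weak
# output probabilities. By default the strong learner is trained on
# out-of-fold weak predictions from a shared stratified 5-fold partition,
# which avoids the stacking leak that in-sample weak outputs would cause.

#' Boosted-tree training specification
#'
#' @param grid data.frame of hyperparameter combinations to grid-search;
#'   columns are xgboost parameter names (e.g. `max_depth`, `eta`). The
#'   default grid is depth \{2, 3, 4\} by learning rate \{0.05, 0.1, 0.3\}.
#' @param nrounds maximum boosting rounds (early stopping prunes them).
#' @param early_stopping_rounds rounds without AUC improvement on the
#'   internal validation split before stopping (default 10).
#' @param validation_fraction stratified fraction of the training data held
#'   out for early stopping.
#' @param nthread threads for xgboost (1 keeps runs bit-reproducible).
#' @return list of class `boosted_tree_spec` with `objective`
#'   `"binary:logistic"` and `eval_metric` `"auc"`.
#' @export
boosted_tree_spec <- function(grid = default_grid(), nrounds = 400L,
                              early_stopping_rounds = 10L,
                              validation_fraction = 0.2, nthread = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            early_stopping_rounds > 0L)
  structure(list(objective = "binary:logistic", eval_metric = "auc",
                 grid = grid, nrounds = as.integer(nrounds),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 validation_fraction = validation_fraction,
                 nthread = as.integer(nthread)),
            class = "boosted_tree_spec")
}

#' @rdname boosted_tree_spec
#' @export
default_grid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1, 0.3))
}

.as_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

# Fit one booster with an internal stratified holdout for early stopping.
.fit_booster <- function(X, y, params, spec, seed, monotone = FALSE) {
  # exact greedy splits: midpoints between observed values, reproducible
  # across runs; histogram binning can misplace cuts on small cohorts
  if (is.null(params$tree_method)) params$tree_method <- "exact"
  if (monotone) {
    params$monotone_constraints <-
      paste0("(", paste(rep(1L, ncol(X)), collapse = ","), ")")
  }
  set.seed(seed)
  fold <- stratified_folds(y, k = max(2L, round(1 / spec$validation_fraction)))
  va <- fold == 1L
  dtrain <- xgboost::xgb.DMatrix(X[!va, , drop = FALSE], label = y[!va],
                                 nthread = spec$nthread)
  dvalid <- xgboost::xgb.DMatrix(X[va, , drop = FALSE], label = y[va],
                                 nthread = spec$nthread)
  xgboost::xgb.train(
    params = c(list(objective = spec$objective, eval_metric = spec$eval_metric,
                    nthread = spec$nthread, seed = seed), params),
    data = dtrain, nrounds = spec$nrounds,
    evals = list(valid = dvalid),
    early_stopping_rounds = spec$early_stopping_rounds, verbose = 0
  )
}

.predict_booster <- function(model, X, spec) {
  predict(model, xgboost::xgb.DMatrix(.as_matrix(X), nthread = spec$nthread))
}

#' Grid-search hyperparameters by stratified cross-validated AUC
#'
#' Every grid row is evaluated by mean out-of-fold AUC under a stratified
#' k-fold partition; within each training fold, boosting uses early
#' stopping on an internal stratified holdout. Deterministic given `seed`.
#'
#' @param spec a [boosted_tree_spec()].
#' @param X feature matrix (or data.frame); missing values allowed.
#' @param y 0/1 outcome with both classes present.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed.
#' @return list with `best_params` (named list) and `cv` (data.frame of the
#'   grid with `mean_auc`).
#' @export
tune <- function(spec, X, y, folds = 5L, seed = 1L) {
  y <- assert_binary_labels(y)
  stopifnot(folds >= 2L)
  X <- .as_matrix(X)
  fold <- stratified_folds(y, k = folds, seed = derive_seed(seed, "folds"))
  aucs <- numeric(nrow(spec$grid))
  for (g in seq_len(nrow(spec$grid))) {
    params <- as.list(spec$grid[g, , drop = FALSE])
    fold_auc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- .fit_booster(X[tr, , drop = FALSE], y[tr], params, spec,
                            seed = derive_seed(seed, paste0("cv", g, "_", f)))
      p <- .predict_booster(model, X[!tr, , drop = FALSE], spec)
      fold_auc[f] <- roc_auc(p, y[!tr])
    }
    aucs[g] <- mean(fold_auc)
  }
  best <- which.max(aucs)
  list(best_params = as.list(spec$grid[best, , drop = FALSE]),
       cv = cbind(spec$grid, mean_auc = aucs))
}

#' Train the per-cluster weak classifiers
#'
#' One boosted-tree learner per cluster, fit on exactly that cluster's
#' feature columns (features belonging to several clusters are used by each
#' owning learner). All clusters share one stratified fold partition, and
#' out-of-fold weak predictions are recorded for leak-free stacking.
#'
#' @param X feature matrix or data.frame (columns named as in the
#'   assignment).
#' @param y 0/1 outcome.
#' @param assignment a `cluster_assignment`; only features present as
#'   columns of `X` participate, and a cluster whose features are all
#'   absent is an error naming the cluster.
#' @param spec a [boosted_tree_spec()].
#' @param folds shared stratified fold count for stacking (default 5).
#' @param seed integer seed.
#' @param tune_grid when `TRUE` (default) the shared grid is searched per
#'   cluster; when `FALSE` the first grid row is used directly.
#' @return object of class `weak_learner_set`: `learners` (per cluster:
#'   `label`, `features`, `model`, `params`), `oof` (N x K out-of-fold
#'   probability matrix), `fold` (fold ids), `labels`, `seed`.
#' @export
train_weak_set <- function(X, y, assignment, spec = boosted_tree_spec(),
                           folds = 5L, seed = 1L, tune_grid = TRUE) {
  y <- assert_binary_labels(y)
  X <- .as_matrix(X)
  sets <- cluster_feature_sets(assignment)
  labels <- names(sets)
  fold <- stratified_folds(y, k = folds, seed = derive_seed(seed, "stack"))

  learners <- vector("list", length(sets))
  oof <- matrix(NA_real_, nrow(X), length(sets),
                dimnames = list(NULL, labels))
  for (i in seq_along(sets)) {
    cols <- intersect(sets[[i]], colnames(X))
    if (length(cols) == 0L) {
      stop(sprintf("cluster '%s' has no matching feature columns", labels[i]),
           call. = FALSE)
    }
    Xi <- X[, cols, drop = FALSE]
    params <- if (tune_grid && nrow(spec$grid) > 1L) {
      tune(spec, Xi, y, folds = folds,
           seed = derive_seed(seed, paste0("tune_", labels[i])))$best_params
    } else {
      as.list(spec$grid[1L, , drop = FALSE])
    }
    for (f in seq_len(folds)) {
      tr <- fold != f
      mf <- .fit_booster(Xi[tr, , drop = FALSE], y[tr], params, spec,
                         seed = derive_seed(seed, paste0("oof_", labels[i], f)))
      oof[!tr, i] <- .predict_booster(mf, Xi[!tr, , drop = FALSE], spec)
    }
    model <- .fit_booster(Xi, y, params, spec,
                          seed = derive_seed(seed, paste0("final_", labels[i])))
    learners[[i]] <- list(label = labels[i], features = cols, model = model,
                          params = params)
  }
  structure(list(learners = learners, oof = oof, fold = fold,
                 labels = labels, seed = seed, spec = spec),
            class = "weak_learner_set")
}

#' Weak-classifier output probabilities
#'
#' @param weak a `weak_learner_set`.
#' @param X feature matrix/data.frame containing every cluster's columns.
#' @return N x K matrix of death probabilities, columns in the cluster
#'   label order recorded in the model.
#' @export
weak_outputs <- function(weak, X) {
  X <- .as_matrix(X)
  out <- matrix(NA_real_, nrow(X), length(weak$learners),
                dimnames = list(NULL, weak$labels))
  for (i in seq_along(weak$learners)) {
    l <- weak$learners[[i]]
    missing <- setdiff(l$features, colnames(X))
    if (length(missing)) {
      stop(sprintf("missing feature columns: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    out[, i] <- .predict_booster(l$model, X[, l$features, drop = FALSE], weak$spec)
  }
  out
}

#' Train the strong (meta) classifier over weak outputs
#'
#' By default the strong learner is constrained to be monotone increasing
#' in every cluster-probability input: a higher cause-specific risk cannot
#' lower the overall predicted risk. This is clinically necessary and
#' regularizes the stacking stage.
#'
#' @param weak_out N x K matrix of weak output probabilities (in-sample or
#'   out-of-fold, see [train_hybrid()]).
#' @param y 0/1 outcome.
#' @param spec a [boosted_tree_spec()].
#' @param seed integer seed.
#' @param tune_grid as in [train_weak_set()].
#' @param monotone constrain the meta-model to be increasing in each
#'   input (default `TRUE`).
#' @return list of class `strong_learner`: `model`, `params`, `labels`.
#' @export
train_strong <- function(weak_out, y, spec = boosted_tree_spec(),
                         seed = 1L, tune_grid = TRUE, monotone = TRUE) {
  y <- assert_binary_labels(y)
  weak_out <- .as_matrix(weak_out)
  if (nrow(weak_out) != length(y)) stop("dimension mismatch", call. = FALSE)
  params <- if (tune_grid && nrow(spec$grid) > 1L) {
    tune(spec, weak_out, y, seed = derive_seed(seed, "tune_strong"))$best_params
  } else {
    as.list(spec$grid[1L, , drop = FALSE])
  }
  model <- .fit_booster(weak_out, y, params, spec,
                        seed = derive_seed(seed, "final_strong"),
                        monotone = monotone)
  structure(list(model = model, params = params,
                 labels = colnames(weak_out), spec = spec),
            class = "strong_learner")
}

#' Train the full hybrid (weak + strong) model
#'
#' @inheritParams train_weak_set
#' @param stacking `"insample"` (default) trains the strong learner on the
#'   final weak models' in-sample output probabilities, matching the input
#'   distribution the meta-model sees at prediction time; note that
#'   derivation-cohort metrics of this mode are optimistic, so model
#'   quality is judged on held-out data. `"oof"` trains it on out-of-fold
#'   weak predictions instead, which keeps derivation metrics honest at
#'   the cost of a train/deployment input mismatch.
#' @param monotone passed to [train_strong()].
#' @return object of class `hybrid_model`: `weak`, `strong`, `assignment`,
#'   `stacking`, `seed`.
#' @export
train_hybrid <- function(X, y, assignment, spec = boosted_tree_spec(),
                         folds = 5L, seed = 1L, tune_grid = TRUE,
                         stacking = c("insample", "oof"), monotone = TRUE) {
  stacking <- match.arg(stacking)
  weak <- train_weak_set(X, y, assignment, spec, folds = folds, seed = seed,
                         tune_grid = tune_grid)
  meta_in <- if (stacking == "oof") weak$oof else weak_outputs(weak, X)
  strong <- train_strong(meta_in, y, spec, seed = seed, tune_grid = tune_grid,
                         monotone = monotone)
  structure(list(weak = weak, strong = strong, assignment = assignment,
                 stacking = stacking, seed = seed),
            class = "hybrid_model")
}

#' Train the unstructured global boosted-tree model
#'
#' Benchmark model on the complete feature list, tuned with the identical
#' protocol as the hybrid workflow.
#'
#' @inheritParams train_weak_set
#' @return object of class `global_model`: `model`, `params`, `features`.
#' @export
train_global <- function(X, y, spec = boosted_tree_spec(), folds = 5L,
                         seed = 1L, tune_grid = TRUE) {
  y <- assert_binary_labels(y)
  X <- .as_matrix(X)
  params <- if (tune_grid && nrow(spec$grid) > 1L) {
    tune(spec, X, y, folds = folds, seed = derive_seed(seed, "tune_global"))$best_params
  } else {
    as.list(spec$grid[1L, , drop = FALSE])
  }
  model <- .fit_booster(X, y, params, spec,
                        seed = derive_seed(seed, "final_global"))
  structure(list(model = model, params = params, features = colnames(X),
                 spec = spec),
            class = "global_model")
}

#' Predicted risk of death
#'
#' @param model a `hybrid_model` or `global_model`.
#' @param X feature matrix/data.frame; columns are matched by name, so
#'   column order is irrelevant. Missing required columns are an error
#'   listing them.
#' @return numeric vector of death probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, X) UseMethod("predict_risk")

#' @export
predict_risk.hybrid_model <- function(model, X) {
  wo <- weak_outputs(model$weak, X)
  .predict_booster(model$strong$model, wo, model$strong$spec)
}

#' @export
predict_risk.global_model <- function(model, X) {
  X <- .as_matrix(X)
  missing <- setdiff(model$features, colnames(X))
  if (length(missing)) {
    stop(sprintf("missing feature columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  .predict_booster(model$model, X[, model$features, drop = FALSE], model$spec)
}

#' Save / load a fitted hybrid model bundle
#'
#' The bundle is a directory with a JSON manifest (cluster labels, feature
#' subsets, hyperparameters, seeds, stacking mode) and each booster in
#' xgboost's native JSON format.
#'
#' @param model a `hybrid_model`.
#' @param dir bundle directory.
#' @return `dir` (save) or the restored `hybrid_model` (load).
#' @export
save_hybrid_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    labels = model$weak$labels,
    features = lapply(model$weak$learners, function(l) l$features),
    params = lapply(model$weak$learners, function(l) l$params),
    strong_params = model$strong$params,
    stacking = model$stacking,
    seed = model$seed,
    xgboost_version = as.character(utils::packageVersion("xgboost"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (i in seq_along(model$weak$learners)) {
    xgboost::xgb.save(model$weak$learners[[i]]$model,
                      file.path(dir, sprintf("weak_%02d.json", i)))
  }
  xgboost::xgb.save(model$strong$model, file.path(dir, "strong.json"))
  invisible(dir)
}
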