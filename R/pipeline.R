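# End-to-end pipeline orchestration: corpus -> clusters -> hybrid + global
# models -> evaluation -> explanations, with every artifact written to a
# run directory and all randomness derived from one master seed via named
# substreams.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; any subset can
#' be overridden via a YAML file or an override list. When neither a
#' corpus path nor a feature-table path is given, the synthetic generators
#' stand in (their defaults are the package's reference study conditions).
#'
#' @param overrides named list merged over the defaults (nested lists are
#'   merged recursively).
#' @return configuration list of class `run_config`.
#' @export
default_run_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    out_dir = "icuhybrid_run",
    corpus = list(path = NULL, simulate = TRUE),
    patients = list(path = NULL, simulate = TRUE, n = NULL),
    fcm = list(k = 6L, m = 1.2, tol = 1e-7, max_iter = 500L, n_restarts = 10L),
    cutoff = 0.2,
    labels = list(),
    model = list(folds = 5L, tune = TRUE, grid = NULL),
    evaluation = list(validation_fraction = 0.25)
  )
  cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  default_run_config(yaml::read_yaml(path))
}

.validate_run_config <- function(cfg) {
  if (!is.null(cfg$corpus$path) && !file.exists(cfg$corpus$path)) {
    stop("corpus path does not exist: ", cfg$corpus$path, call. = FALSE)
  }
  if (!is.null(cfg$patients$path) && !file.exists(cfg$patients$path)) {
    stop("feature table path does not exist: ", cfg$patients$path,
         call. = FALSE)
  }
  stopifnot(cfg$fcm$m > 1, cfg$fcm$k >= 1, cfg$cutoff > 0, cfg$cutoff <= 1)
  invisible(cfg)
}

.model_spec_from_config <- function(cfg) {
  if (is.null(cfg$model$grid)) {
    boosted_tree_spec()
  } else {
    boosted_tree_spec(grid = as.data.frame(cfg$model$grid))
  }
}

#' Run the full modelling pipeline
#'
#' Stages: ingest (or simulate) the description corpus; preprocess,
#' vectorize and cluster it; ingest (or simulate) the patient feature
#' table; split into derivation and validation parts; train the hybrid and
#' the global model on the derivation part; select accuracy-maximizing
#' thresholds on the derivation part and evaluate both models on both
#' parts; extract hierarchical importance and a cluster-level Shapley
#' explanation for the highest-risk validation stay. Every artifact plus a
#' manifest (seeds, config hash, package versions) is written under
#' `cfg$out_dir`; re-running with the same configuration reproduces
#' identical outputs.
#'
#' @param cfg a `run_config` (see [default_run_config()]).
#' @return the manifest list, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  .validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed

  # stage: corpus
  if (!is.null(cfg$corpus$path)) {
    corpus <- read_corpus(cfg$corpus$path)
    truth <- NULL
  } else {
    sim <- simulate_corpus(corpus_sim_config(seed = derive_seed(seed, "corpus")))
    corpus <- sim$corpus
    truth <- sim$truth
    write_corpus(corpus, file.path(cfg$out_dir, "corpus.json"))
  }

  # stage: clustering
  sem <- fit_semantic_clusters(
    corpus,
    config = fcm_config(k = cfg$fcm$k, m = cfg$fcm$m, tol = cfg$fcm$tol,
                        max_iter = cfg$fcm$max_iter,
                        n_restarts = cfg$fcm$n_restarts,
                        seed = derive_seed(seed, "fcm")),
    cutoff = cfg$cutoff
  )
  assignment <- sem$assignment
  if (length(cfg$labels)) assignment <- label_clusters(assignment, cfg$labels)
  write.csv(sem$fit$U, file.path(cfg$out_dir, "membership_U.csv"))
  write_assignment(assignment, file.path(cfg$out_dir, "assignment.json"))
  write.csv(membership_heatmap_export(sem$fit, assignment),
            file.path(cfg$out_dir, "membership_heatmap.csv"), row.names = FALSE)

  # stage: patients
  if (!is.null(cfg$patients$path)) {
    tab <- read.csv(cfg$patients$path, check.names = FALSE)
    stopifnot("outcome" %in% names(tab))
    y <- tab$outcome
    X <- tab[, setdiff(names(tab), c("outcome", "stay_id")), drop = FALSE]
  } else {
    if (is.null(truth)) stop("synthetic patients require a synthetic corpus",
                             call. = FALSE)
    pcfg <- patient_sim_config(seed = derive_seed(seed, "patients"))
    if (!is.null(cfg$patients$n)) pcfg$n_patients <- as.integer(cfg$patients$n)
    pats <- simulate_patients(pcfg, truth)
    X <- pats$features
    y <- pats$labels
  }

  # stage: derivation/validation split + training
  split_fold <- stratified_folds(
    y, k = max(2L, round(1 / cfg$evaluation$validation_fraction)),
    seed = derive_seed(seed, "split"))
  va <- split_fold == 1L
  spec <- .model_spec_from_config(cfg)
  hybrid <- train_hybrid(X[!va, , drop = FALSE], y[!va], assignment, spec,
                         folds = cfg$model$folds,
                         seed = derive_seed(seed, "hybrid"),
                         tune_grid = isTRUE(cfg$model$tune))
  global <- train_global(X[!va, , drop = FALSE], y[!va], spec,
                         folds = cfg$model$folds,
                         seed = derive_seed(seed, "global"),
                         tune_grid = isTRUE(cfg$model$tune))
  save_hybrid_model(hybrid, file.path(cfg$out_dir, "hybrid_model"))

  # stage: evaluation
  metrics <- list()
  thresholds <- list()
  for (m in c("hybrid", "global")) {
    model <- if (m == "hybrid") hybrid else global
    p_der <- predict_risk(model, X[!va, , drop = FALSE])
    p_val <- predict_risk(model, X[va, , drop = FALSE])
    thr <- select_threshold(p_der, y[!va])$threshold
    thresholds[[m]] <- thr
    metrics[[paste0(m, "_derivation")]] <-
      unclass(classification_metrics(p_der, y[!va], thr, "derivation"))
    metrics[[paste0(m, "_validation")]] <-
      unclass(classification_metrics(p_val, y[va], thr, "validation"))
  }
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # stage: interpretation
  imp <- hierarchical_importance(hybrid)
  write.csv(imp$table, file.path(cfg$out_dir, "importance.csv"),
            row.names = FALSE)
  wo_val <- weak_outputs(hybrid$weak, X[va, , drop = FALSE])
  set.seed(derive_seed(seed, "background"))
  bg <- wo_val[sample.int(nrow(wo_val), min(100L, nrow(wo_val))), , drop = FALSE]
  top_stay <- which.max(predict_risk(hybrid, X[va, , drop = FALSE]))
  expl <- exact_shapley(hybrid$strong, wo_val[top_stay, ], bg)
  write.csv(waterfall_export(expl, top_n = 20L),
            file.path(cfg$out_dir, "waterfall.csv"), row.names = FALSE)

  # manifest
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    thresholds = thresholds,
    n_clusters = length(assignment$labels),
    n_stays = length(y),
    derivation_n = sum(!va),
    validation_n = sum(va),
    versions = list(
      icuhybrid = as.character(utils::packageVersion("icuhybrid")),
      xgboost = as.character(utils::packageVersion("xgboost")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
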