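sep_data <- function(n = 120, seed = 1) {
  set.seed(seed)
  x1 <- c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3))
  X <- cbind(x1 = x1, x2 = rnorm(n))
  list(X = X, y = rep(c(0, 1), each = n / 2))
}

test_that("stratified folds balance the event rate across folds", {
  set.seed(3)
  y <- rbinom(500, 1, 0.15)
  fold <- stratified_folds(y, k = 5, seed = 1)
  rates <- tapply(y, fold, mean)
  expect_true(all(abs(rates - mean(y)) < 1 / 5))
  expect_equal(sort(unique(fold)), 1:5)
})

test_that("grid search returns the singleton grid and finds separable data easy", {
  d <- sep_data()
  spec <- tiny_spec()
  out <- tune(spec, d$X, d$y, folds = 5, seed = 1)
  expect_equal(out$best_params$max_depth, 2L)
  expect_equal(out$best_params$eta, 0.1)
  expect_equal(out$cv$mean_auc, 1, tolerance = 1e-9)
  expect_error(tune(spec, d$X, rep(1, nrow(d$X))), "both")
})

test_that("grid search is deterministic given the seed", {
  d <- sep_data(seed = 5)
  spec <- boosted_tree_spec(grid = expand.grid(max_depth = 2:3,
                                               eta = c(0.1, 0.3)),
                            nrounds = 50L)
  a <- tune(spec, d$X, d$y, seed = 9)
  b <- tune(spec, d$X, d$y, seed = 9)
  expect_identical(a, b)
})

test_that("one weak learner per cluster, shared features used by each owner", {
  co <- make_planted_cohort(seed = 31, n = 600)
  weak <- train_weak_set(co$X, co$y, co$sem$assignment, tiny_spec(),
                         seed = 1, tune_grid = FALSE)
  expect_length(weak$learners, 6L)
  dual <- co$sim$truth$feature[!is.na(co$sim$truth$cause_secondary)]
  owners <- vapply(weak$learners, function(l) dual[1] %in% l$features,
                   logical(1))
  expect_gte(sum(owners), 2L)
  # out-of-fold matrix is complete and in [0, 1]
  expect_false(anyNA(weak$oof))
  expect_true(all(weak$oof >= 0 & weak$oof <= 1))
})

test_that("a cluster with no matching feature columns is a named error", {
  co <- make_planted_cohort(seed = 31, n = 300)
  X2 <- co$X[, setdiff(colnames(co$X),
                       cluster_feature_sets(co$sem$assignment)[[2]])]
  expect_error(
    train_weak_set(X2, co$y, co$sem$assignment, tiny_spec(), seed = 1,
                   tune_grid = FALSE),
    co$sem$assignment$labels[2], fixed = TRUE)
})

test_that("weak outputs are probabilities in recorded cluster order", {
  co <- make_planted_cohort(seed = 32, n = 400)
  weak <- train_weak_set(co$X, co$y, co$sem$assignment, tiny_spec(),
                         seed = 1, tune_grid = FALSE)
  wo <- weak_outputs(weak, co$X)
  expect_identical(colnames(wo), weak$labels)
  expect_true(all(wo >= 0 & wo <= 1))
  # identical rows give identical outputs
  Xc <- co$X[rep(1, 5), ]
  expect_equal(apply(weak_outputs(weak, Xc), 2, function(v) diff(range(v))),
               setNames(rep(0, 6), weak$labels))
  expect_error(weak_outputs(weak, co$X[, 1:3]), "missing feature columns")
})

test_that("duplicating a cluster column gives the strong learner no AUC gain", {
  set.seed(8)
  n <- 1000
  p1 <- plogis(rnorm(n))
  p2 <- plogis(rnorm(n))
  y <- rbinom(n, 1, plogis(qlogis(p1) + qlogis(p2)))
  tr <- seq_len(n) <= 700
  base <- cbind(c1 = p1, c2 = p2)
  dupl <- cbind(base, c1copy = p1)
  s1 <- train_strong(base[tr, ], y[tr], tiny_spec(), seed = 2,
                     tune_grid = FALSE)
  s2 <- train_strong(dupl[tr, ], y[tr], tiny_spec(), seed = 2,
                     tune_grid = FALSE)
  a1 <- roc_auc(predict(s1$model, xgboost::xgb.DMatrix(base[!tr, ], nthread = 1)), y[!tr])
  a2 <- roc_auc(predict(s2$model, xgboost::xgb.DMatrix(dupl[!tr, ], nthread = 1)), y[!tr])
  expect_lt(abs(a1 - a2), 0.01)
})

test_that("the strong learner outperforms the single best weak learner", {
  aucs <- sapply(c(41, 42), function(s) {
    co <- make_planted_cohort(seed = s, n = 1200)
    va <- stratified_folds(co$y, 4, seed = s) == 1
    hyb <- train_hybrid(co$X[!va, ], co$y[!va], co$sem$assignment,
                        simulation_study_spec(), seed = s, tune_grid = FALSE)
    wo <- weak_outputs(hyb$weak, co$X[va, ])
    best_weak <- max(apply(wo, 2, roc_auc, labels = co$y[va]))
    c(strong = roc_auc(predict_risk(hyb, co$X[va, ]), co$y[va]),
      weak = best_weak)
  })
  expect_true(all(aucs["strong", ] > aucs["weak", ]))
})

test_that("in-sample stacking inflates derivation AUC relative to out-of-fold", {
  gaps <- sapply(c(51, 52), function(s) {
    co <- make_planted_cohort(seed = s, n = 1200)
    ins <- train_hybrid(co$X, co$y, co$sem$assignment, tiny_spec(),
                        seed = s, tune_grid = FALSE, stacking = "insample")
    oof <- train_hybrid(co$X, co$y, co$sem$assignment, tiny_spec(),
                        seed = s, tune_grid = FALSE, stacking = "oof")
    roc_auc(predict_risk(ins, co$X), co$y) -
      roc_auc(predict_risk(oof, co$X), co$y)
  })
  expect_true(all(gaps > 0))
})

test_that("end-to-end training is reproducible and prediction is schema-robust", {
  co <- make_planted_cohort(seed = 33, n = 500)
  h1 <- train_hybrid(co$X, co$y, co$sem$assignment, tiny_spec(), seed = 7,
                     tune_grid = FALSE)
  h2 <- train_hybrid(co$X, co$y, co$sem$assignment, tiny_spec(), seed = 7,
                     tune_grid = FALSE)
  p1 <- predict_risk(h1, co$X)
  expect_identical(p1, predict_risk(h2, co$X))
  expect_true(all(p1 >= 0 & p1 <= 1))
  # column order must not matter
  perm <- sample(ncol(co$X))
  expect_equal(predict_risk(h1, co$X[, perm]), p1, tolerance = 1e-12)
  # batch and single-row prediction agree
  expect_equal(predict_risk(h1, co$X[3, , drop = FALSE]), p1[3],
               tolerance = 1e-7)
})

test_that("global model follows the same protocol and reproduces exactly", {
  d <- sep_data(seed = 4)
  spec <- tiny_spec()
  g1 <- train_global(d$X, d$y, spec, seed = 3, tune_grid = FALSE)
  g2 <- train_global(d$X, d$y, spec, seed = 3, tune_grid = FALSE)
  expect_identical(predict_risk(g1, d$X), predict_risk(g2, d$X))
  expect_equal(roc_auc(predict_risk(g1, d$X), d$y), 1, tolerance = 1e-9)
  expect_error(predict_risk(g1, d$X[, "x2", drop = FALSE]), "missing")
})

test_that("zeroing one cause's signal drags its weak AUC toward chance", {
  deltas <- sapply(c(61, 62, 63), function(s) {
    # no dual-cause features: they would leak other causes' severities
    # into the silenced cluster
    sim <- simulate_corpus(corpus_sim_config(shared_features = 0, seed = s))
    sem <- fit_semantic_clusters(sim$corpus, fcm_config(seed = s,
                                                        n_restarts = 3))
    cfg <- patient_sim_config(n_patients = 1000, seed = s)
    cfg$beta[2] <- 0  # silence cause 2
    pats <- simulate_patients(cfg, sim$truth)
    weak <- train_weak_set(pats$features, pats$labels, sem$assignment,
                           tiny_spec(), seed = s, tune_grid = FALSE)
    # identify the cluster dominated by cause-2 features
    sets <- cluster_feature_sets(sem$assignment)
    c2feats <- sim$truth$feature[sim$truth$cause_primary == 2 &
                                   is.na(sim$truth$cause_secondary)]
    cl <- which.max(vapply(sets, function(fs) sum(fs %in% c2feats), 0))
    roc_auc(weak$oof[, cl], pats$labels)
  })
  expect_lt(mean(deltas), 0.55)
})

test_that("model bundles serialize to a manifest plus native boosters", {
  co <- make_planted_cohort(seed = 34, n = 300)
  h <- train_hybrid(co$X, co$y, co$sem$assignment, tiny_spec(), seed = 1,
                    tune_grid = FALSE)
  dir <- withr::local_tempdir()
  save_hybrid_model(h, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "^weak_.*json$"), 6L)
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_identical(man$stacking, "insample")
})
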