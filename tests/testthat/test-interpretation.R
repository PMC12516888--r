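fit_toy_booster <- function(X, y, nrounds = 2, max_depth = 2) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "auc",
                  nthread = 1, max_depth = max_depth, eta = 0.5, seed = 1),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0)
}

test_that("gain importance: single informative feature takes everything", {
  set.seed(1)
  X <- cbind(x1 = c(rnorm(50, -2), rnorm(50, 2)), x2 = rnorm(100))
  y <- rep(c(0, 1), each = 50)
  m <- fit_toy_booster(X, y, nrounds = 3, max_depth = 1)
  g <- gain_importance(m, feature_names = c("x1", "x2"))
  expect_equal(unname(g["x1"]), 1)
  expect_equal(unname(g["x2"]), 0)
  expect_equal(sum(g), 1)
})

test_that("gain importance equals the manual sum over the tree dump", {
  set.seed(2)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(100, 1, plogis(X[, 1] + 0.5 * X[, 2]))
  m <- fit_toy_booster(X, y, nrounds = 2)
  dump <- xgboost::xgb.model.dt.tree(model = m)
  splits <- dump[dump$Feature != "Leaf", ]
  manual <- tapply(splits$Gain, splits$Feature, sum)
  manual <- manual / sum(manual)
  g <- gain_importance(m, feature_names = c("a", "b", "c"))
  expect_equal(as.numeric(g[names(manual)]), as.numeric(manual),
               tolerance = 1e-7)
})

test_that("hierarchical importance reproduces the worked example exactly", {
  rep1 <- hierarchical_importance(
    w = c(A = 0.6, B = 0.4),
    f_by_cluster = list(A = c(x = 0.5, y = 0.5), B = c(z = 1.0)))
  expect_equal(rep1$table$final[match(c("x", "y", "z"), rep1$table$feature)],
               c(0.30, 0.30, 0.40), tolerance = 1e-12)
  # single cluster: final equals the within-cluster shares
  rep2 <- hierarchical_importance(w = c(A = 1),
                                  f_by_cluster = list(A = c(x = 0.7, y = 0.3)))
  expect_equal(rep2$table$final, c(0.7, 0.3), tolerance = 1e-12)
  expect_error(
    hierarchical_importance(w = c(A = 1), f_by_cluster = list(B = c(x = 1))),
    "disagree")
})

test_that("importance normalizations hold on a fitted hybrid model", {
  co <- make_planted_cohort(seed = 71, n = 500)
  h <- train_hybrid(co$X, co$y, co$sem$assignment, tiny_spec(), seed = 1,
                    tune_grid = FALSE)
  rep <- hierarchical_importance(h)
  expect_equal(sum(rep$cluster_weights), 1, tolerance = 1e-9)
  for (cl in unique(rep$table$cluster)) {
    expect_equal(sum(rep$table$f[rep$table$cluster == cl]), 1,
                 tolerance = 1e-9)
  }
  expect_equal(sum(rep$table$final), 1, tolerance = 1e-9)
  # multi-cluster features appear once per owning cluster
  multi <- names(Filter(function(m) length(m) >= 2,
                        co$sem$assignment$members))
  expect_gt(length(multi), 0)
  expect_gte(sum(rep$table$feature == multi[1]), 2)
  expect_equal(sum(rep$per_feature), 1, tolerance = 1e-9)
})

test_that("exact Shapley satisfies additivity, symmetry and null player", {
  set.seed(3)
  bg <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- c(a = 0.9, b = 0.9, c = 0.2)

  # additive model: contribution i = g_i(x_i) - E[g_i]
  f_add <- function(M) 2 * M[, "a"] + 3 * M[, "b"] + 0 * M[, "c"]
  e <- exact_shapley(f_add, x, bg)
  expect_equal(unname(e$contributions["a"]), 2 * (x["a"] - mean(bg[, "a"])),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(e$contributions["b"]), 3 * (x["b"] - mean(bg[, "b"])),
               tolerance = 1e-9, ignore_attr = TRUE)
  # null player gets exactly zero
  expect_equal(unname(e$contributions["c"]), 0, tolerance = 1e-12)
  # efficiency by construction
  expect_lt(abs(e$baseline + sum(e$contributions) - e$output), 1e-9)

  # symmetry: identical columns and a symmetric model
  bg_sym <- bg
  bg_sym[, "b"] <- bg_sym[, "a"]
  f_sym <- function(M) M[, "a"] * M[, "b"]
  es <- exact_shapley(f_sym, c(a = 0.7, b = 0.7, c = 0.1), bg_sym)
  expect_equal(unname(es$contributions["a"]), unname(es$contributions["b"]),
               tolerance = 1e-9)
})

test_that("exact Shapley agrees with the factorial permutation oracle", {
  set.seed(4)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(X[, 1] - X[, 2] + 0.3 * X[, 1] * X[, 3]))
  m <- fit_toy_booster(X, y, nrounds = 5)
  f <- function(M) predict(m, xgboost::xgb.DMatrix(M, nthread = 1))
  bg <- X[1:40, ]
  x <- X[7, ]
  e <- exact_shapley(f, x, bg)
  orc <- shapley_perm_oracle(f, x, bg)
  expect_equal(e$contributions, orc, tolerance = 1e-7)
  expect_error(exact_shapley(f, setNames(rnorm(16), paste0("p", 1:16)), bg),
               "sampled_shapley")
})

test_that("sampled Shapley is exact for additive models and reproducible", {
  set.seed(5)
  bg <- matrix(runif(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  x <- setNames(runif(4), letters[1:4])
  f_add <- function(M) M %*% c(1, -2, 0.5, 0)
  s1 <- sampled_shapley(f_add, x, bg, n_permutations = 3, seed = 9)
  e <- exact_shapley(f_add, x, bg)
  expect_equal(s1$contributions, e$contributions, tolerance = 1e-9)
  s2 <- sampled_shapley(f_add, x, bg, n_permutations = 3, seed = 9)
  expect_identical(s1$contributions, s2$contributions)
})

test_that("waterfall export orders, aggregates and sums consistently", {
  expl <- structure(list(
    baseline = 0.2, output = 0.65,
    contributions = c(h = 0.3, i = -0.1, r = 0.15, c = 0.05, m = 0.03,
                      l = 0.02),
    method = "exact", se = NULL), class = "shapley_explanation")
  full <- waterfall_export(expl)
  expect_identical(full$item[1], "baseline E[f(x)]")
  expect_identical(full$item[nrow(full)], "f(x)")
  expect_false(any(grepl("other", full$item)))
  expect_equal(full$cumulative[nrow(full) - 1], expl$output, tolerance = 1e-12)

  top <- waterfall_export(expl, top_n = 3)
  expect_identical(top$item[2:4], c("h", "r", "i"))  # by |value|
  expect_match(top$item[5], "other \\(3 features\\)")
  expect_equal(sum(top$value[-nrow(top)]), expl$output, tolerance = 1e-12)
})
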