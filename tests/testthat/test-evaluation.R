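test_that("AUC is the concordance probability with ties at one half", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # exhaustive pair count: pairs (.35 vs .1 +), (.35 vs .4 -),
  # (.8 vs .1 +), (.8 vs .4 +) -> 3/4
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both")
})

test_that("AUC equals U/(n1 n0) and matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2)  # ties likely
    a <- roc_auc(s, y)
    u <- mann_whitney_u(s[y == 1], s[y == 0])$U
    expect_equal(a, u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
  }
  set.seed(11)
  y <- rbinom(200, 1, 0.3)
  s <- rnorm(200)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("threshold selection maximizes accuracy over midpoint candidates", {
  out <- select_threshold(c(0.2, 0.8), c(0, 1))
  expect_equal(out$threshold, 0.5)
  expect_equal(out$accuracy, 1)

  # correctly ordered labels always admit a perfect threshold
  s <- sort(runif(20))
  y <- rep(c(0, 1), each = 10)
  expect_equal(select_threshold(s, y)$accuracy, 1)

  # exhaustive scan oracle on random data
  set.seed(12)
  for (i in 1:20) {
    s <- round(runif(50), 2)
    y <- rbinom(50, 1, plogis(4 * s - 2))
    if (length(unique(y)) < 2) next
    got <- select_threshold(s, y)
    cand <- c(-Inf, sort(unique(s)), Inf)
    accs <- sapply(cand, function(t) mean((s >= t) == y))
    expect_gte(got$accuracy + 1e-12, max(accs))
  }
})

test_that("classification metrics follow the confusion counts exactly", {
  perfect <- classification_metrics(c(0.1, 0.9, 0.2, 0.8), c(0, 1, 0, 1), 0.5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)

  # TP=2 FP=1 FN=2 TN=5 -> precision 2/3, recall 1/2, F1 4/7
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.3, rep(0.1, 5))
  labels <- c(1, 1, 0, 1, 1, rep(0, 5))
  m <- classification_metrics(scores, labels, threshold = 0.5)
  expect_equal(unname(m$counts), c(2, 1, 5, 2))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1 / 2)
  expect_equal(m$f1, 4 / 7)

  # all predicted negative: recall 0, precision undefined-with-flag
  deg <- classification_metrics(c(0.1, 0.2, 0.3), c(0, 1, 1), threshold = 0.9)
  expect_equal(deg$recall, 0)
  expect_true(is.na(deg$precision))
  expect_true("precision" %in% deg$undefined)
})

test_that("metrics are invariant under monotone score transforms", {
  set.seed(14)
  s <- runif(60)
  y <- rbinom(60, 1, s)
  if (length(unique(y)) == 2) {
    f <- function(x) qlogis(x / 2 + 0.25)
    expect_equal(roc_auc(f(s), y), roc_auc(s, y), tolerance = 1e-12)
    expect_equal(select_threshold(f(s), y)$accuracy,
                 select_threshold(s, y)$accuracy, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney: exact p for complete separation, symmetry, ties", {
  sep <- mann_whitney_u(6:10, 1:5)
  expect_equal(sep$U, 25)
  expect_equal(sep$p, 2 / 252, tolerance = 1e-12)
  expect_identical(sep$method, "exact")

  swap <- mann_whitney_u(1:5, 6:10)
  expect_equal(swap$U, 5 * 5 - sep$U)
  expect_equal(swap$p, sep$p, tolerance = 1e-12)

  same <- mann_whitney_u(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.1))
  expect_gt(same$p, 0.8)

  big <- mann_whitney_u(rnorm(30), rnorm(30))
  expect_identical(big$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("model comparison verdicts are two-sided and order-invariant", {
  a <- data.frame(auc = c(0.8, 0.81, 0.79, 0.8, 0.82),
                  accuracy = c(0.9, 0.89, 0.91, 0.9, 0.9))
  expect_identical(compare_models(a, a)$verdict, "no significant difference")

  b <- data.frame(auc = a$auc + 0.2, accuracy = a$accuracy - 0.2)
  v1 <- compare_models(a, b)
  v2 <- compare_models(b, a)
  expect_identical(v1$verdict, "significant difference")
  expect_equal(v1$per_metric$p, v2$per_metric$p, tolerance = 1e-12)
  expect_error(compare_models(a, a[1:3, ]), "matched")
})
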