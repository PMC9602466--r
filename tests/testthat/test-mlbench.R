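test_that("stratified folds balance classes to within one member", {
  y <- c(rep(1, 5), rep(0, 5))
  f <- stratified_folds(y, k = 5, seed = 3)
  for (i in 1:5) {
    expect_identical(sum(y[f == i] == 1), 1L)
    expect_identical(sum(y[f == i] == 0), 1L)
  }
  y2 <- c(rep(1, 6), rep(0, 4))
  f2 <- stratified_folds(y2, k = 5, seed = 3)
  pos_per_fold <- vapply(1:5, function(i) sum(y2[f2 == i] == 1), 0L)
  neg_per_fold <- vapply(1:5, function(i) sum(y2[f2 == i] == 0), 0L)
  expect_true(all(pos_per_fold %in% 1:2))
  expect_true(all(neg_per_fold %in% 0:1))
  expect_identical(f2, stratified_folds(y2, k = 5, seed = 3))  # deterministic
  expect_false(identical(f2, stratified_folds(y2, k = 5, seed = 4)))
  expect_error(stratified_folds(c(1, 1, 1, 0), k = 5), "at least")
})

test_that("folds partition every sample across many seeded label vectors", {
  set.seed(99)
  for (rep_i in 1:100) {
    n <- sample(20:120, 1)
    npos <- sample(6:(n - 6), 1)
    y <- sample(c(rep(1, npos), rep(0, n - npos)))
    k <- 5
    if (min(npos, n - npos) < k) next
    f <- stratified_folds(y, k = k, seed = rep_i)
    expect_identical(sort(unique(f)), 1:k)
    expect_identical(length(f), n)
    for (i in seq_len(k)) {
      expect_lte(abs(sum(y[f == i] == 1) - npos / k), 1)
      expect_lte(abs(sum(y[f == i] == 0) - (n - npos) / k), 1)
    }
  }
})

test_that("confusion counts follow their definitions", {
  perfect <- confusion(rep(c(0, 1), 5), rep(c(0, 1), 5))
  expect_identical(perfect$fp + perfect$fn, 0L)
  allpos <- confusion(c(rep(1, 3), rep(0, 7)), rep(1, 10))
  expect_identical(allpos[c("tp", "fp", "tn", "fn")],
                   list(tp = 3L, fp = 7L, tn = 0L, fn = 0L))
  y <- c(1, 0, 1, 1, 0)
  inv <- confusion(y, 1 - y)
  fwd <- confusion(y, y)
  expect_identical(inv$fn, fwd$tp)
  expect_identical(inv$fp, fwd$tn)
  expect_error(confusion(c(1, 0), 1), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("the metric formulas reproduce the worked example", {
  m <- metrics(list(tp = 50, tn = 30, fp = 10, fn = 10))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8333, tolerance = 1e-4)
  expect_equal(m$recall, 0.8333, tolerance = 1e-4)
  expect_equal(m$f1, 0.8333, tolerance = 1e-4)
  expect_equal(m$mcc, 0.5833, tolerance = 1e-4)
  expect_false(m$degenerate)
  perfect <- metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall", "f1", "mcc")]) == 1))
  onecls <- metrics(confusion(c(1, 1, 0, 0), c(1, 1, 1, 1)))
  expect_identical(onecls$mcc, 0)
  expect_true(onecls$degenerate)
})

test_that("metrics agree exactly with brute-force recomputation on random tables", {
  set.seed(7)
  for (i in 1:200) {
    cc <- as.list(stats::setNames(sample(0:60, 4, replace = TRUE),
                                  c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cc)) == 0) cc$tp <- 1L
    got <- metrics(cc)
    want <- oracle_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
    expect_equal(got$accuracy, unname(want["accuracy"]))
    expect_equal(got$precision, unname(want["precision"]))
    expect_equal(got$recall, unname(want["recall"]))
    expect_equal(got$f1, unname(want["f1"]))
    expect_equal(got$mcc, unname(want["mcc"]))
    expect_gte(got$mcc, -1); expect_lte(got$mcc, 1)
  }
})

test_that("AUROC follows the rank formulation with half-credit ties", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.75)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")
  # invariant under strictly monotone transforms
  set.seed(11)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(60)
  base <- auroc(y, s)
  expect_equal(auroc(y, exp(s)), base)
  expect_equal(auroc(y, 3 * s - 100), base)
  expect_equal(auroc(y, rank(s)), base)
})

test_that("AUROC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rbinom(80, 1, 0.4); y[1:2] <- c(0, 1)
  s <- rnorm(80) + y
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(auroc(y, s), ref)
})

test_that("the benchmark is deterministic and leak-free", {
  lib <- make_labeled_library(n = 60, noise = 0, seed = 2)
  std <- standardize_molecules(lib$library)
  fps <- ecfp4_table(std)
  labels <- std[, c("id", "label")]
  b1 <- run_benchmark(list(ecfp4 = fps), labels, models = c("dummy", "nb"),
                      k = 5, seed = 9)
  b2 <- run_benchmark(list(ecfp4 = fps), labels, models = c("dummy", "nb"),
                      k = 5, seed = 9)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  expect_identical(nrow(b1), 2L * 5L * 2L)  # models x folds x splits
  expect_setequal(unique(b1$fold), 1:5)
  g <- glance(b1)
  expect_identical(nrow(g), 4L)
  td <- tidy(b1)
  expect_setequal(unique(td$metric), c("accuracy", "precision", "recall", "f1", "mcc", "auroc"))
})

test_that("a forest recovers planted signal that the dummy cannot", {
  lib <- make_labeled_library(n = 60, noise = 0, seed = 2)
  std <- standardize_molecules(lib$library)
  fps <- ecfp4_table(std)
  labels <- std[, c("id", "label")]
  bm <- run_benchmark(list(ecfp4 = fps), labels, models = c("dummy", "rf"),
                      k = 5, seed = 1)
  g <- glance(bm)
  rf_acc <- g$accuracy[g$model == "rf" & g$split == "test"]
  dummy_acc <- g$accuracy[g$model == "dummy" & g$split == "test"]
  expect_gt(rf_acc, 0.9)
  expect_lt(abs(dummy_acc - 0.5), 0.25)
})

test_that("the uniform-random baseline converges to one-half accuracy", {
  # small-n behaviour over 10 seeds
  accs <- vapply(1:10, function(s) {
    y <- rep(c(0L, 1L), 50)
    pred <- withr::with_seed(s, sample(c(0L, 1L), 100, replace = TRUE))
    metrics(confusion(y, pred))$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
  # large-n convergence
  y <- rep(c(0L, 1L), 5000)
  pred <- withr::with_seed(123, sample(c(0L, 1L), 10000, replace = TRUE))
  expect_lt(abs(metrics(confusion(y, pred))$accuracy - 0.5), 0.02)
})
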