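#' Stratified k-fold assignment
#'
#' Shuffles each class independently (seeded) and deals members round-robin
#' across folds, so per-fold class counts never differ by more than one
#' from proportional allocation. A class smaller than `k` is legal — it is
#' simply absent from some folds. Deterministic for a fixed seed.
#'
#' @param labels binary label vector (0/1, factor, or logical).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return integer vector of fold indices (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  y <- as.integer(as.factor(labels))
  if (length(y) < k) {
    abort(sprintf("need at least k = %d samples.", k))
  }
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Confusion counts of a binary prediction
#'
#' @param y_true,y_pred vectors of 0/1 labels, equal length.
#' @return named list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("label vectors differ in length.")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    abort("labels must be binary 0/1.")
  }
  list(
    tp = sum(y_true == 1L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fp = sum(y_true == 0L & y_pred == 1L),
    fn = sum(y_true == 1L & y_pred == 0L)
  )
}

#' Classification metric suite from confusion counts
#'
#' Accuracy, precision, recall, F1 and the Matthews correlation coefficient,
#' evaluated from their defining formulas:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' A metric whose denominator is zero (e.g. MCC of an all-one-class
#' prediction) is reported as 0 and flagged in the `degenerate` field.
#'
#' @param cc [confusion()] output (or a list with `tp`,`tn`,`fp`,`fn`).
#' @return tibble row: `accuracy`, `precision`, `recall`, `f1`, `mcc`,
#'   `degenerate`.
#' @export
metrics <- function(cc) {
  # double precision up front: the MCC denominator product overflows
  # integer arithmetic already at a few thousand samples
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  total <- tp + tn + fp + fn
  if (total < 1L) abort("empty confusion table.")
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  accuracy <- (tp + tn) / total
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den2 == 0) { degenerate <- TRUE; 0 } else {
    (tp * tn - fp * fn) / sqrt(mcc_den2)
  }
  tibble(
    accuracy = accuracy, precision = precision, recall = recall,
    f1 = f1, mcc = mcc, degenerate = degenerate
  )
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outscores a random negative, ties counted one half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param y_true binary 0/1 labels; both classes must be present.
#' @param scores numeric decision scores (higher = more positive).
#' @return number in \[0, 1\].
#' @export
auroc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) abort("lengths differ.")
  npos <- sum(y_true == 1L)
  nneg <- sum(y_true == 0L)
  if (npos == 0L || nneg == 0L) abort("AUROC needs both classes present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# --- models -----------------------------------------------------------------

fit_predict <- function(model, x_train, y_train, x_test, seed) {
  y_f <- factor(y_train, levels = c(0L, 1L))
  pred2 <- function(pred_tr, pred_te, score_tr, score_te) {
    list(
      train = list(pred = pred_tr, score = score_tr),
      test = list(pred = pred_te, score = score_te)
    )
  }
  switch(model,
    dummy = withr::with_seed(seed, {
      # uniform-random class assignment, the no-information baseline
      p_tr <- sample(c(0L, 1L), nrow(x_train), replace = TRUE)
      p_te <- sample(c(0L, 1L), nrow(x_test), replace = TRUE)
      pred2(p_tr, p_te, stats::runif(nrow(x_train)), stats::runif(nrow(x_test)))
    }),
    svm = withr::with_seed(seed, {
      # binary bit features: scaling is meaningless and warns on constant bits
      fit <- e1071::svm(x_train, y_f, kernel = "radial", probability = TRUE,
                        scale = FALSE)
      sc <- function(x) {
        pr <- attr(predict(fit, x, probability = TRUE), "probabilities")[, "1"]
        pr
      }
      s_tr <- sc(x_train); s_te <- sc(x_test)
      pred2(as.integer(s_tr > 0.5), as.integer(s_te > 0.5), s_tr, s_te)
    }),
    rf = withr::with_seed(seed, {
      fit <- randomForest::randomForest(x_train, y_f, ntree = 500)
      s_tr <- predict(fit, x_train, type = "prob")[, "1"]
      s_te <- predict(fit, x_test, type = "prob")[, "1"]
      pred2(as.integer(s_tr > 0.5), as.integer(s_te > 0.5), s_tr, s_te)
    }),
    nb = {
      # Bernoulli-style naive Bayes: binary features as two-level factors
      df_tr <- as.data.frame(lapply(
        as.data.frame(x_train), factor, levels = c(0L, 1L)
      ))
      df_te <- as.data.frame(lapply(
        as.data.frame(x_test), factor, levels = c(0L, 1L)
      ))
      fit <- e1071::naiveBayes(df_tr, y_f, laplace = 1)
      s_tr <- predict(fit, df_tr, type = "raw")[, "1"]
      s_te <- predict(fit, df_te, type = "raw")[, "1"]
      pred2(as.integer(s_tr > 0.5), as.integer(s_te > 0.5), s_tr, s_te)
    },
    abort(sprintf("unknown model '%s'.", model))
  )
}

split_metrics <- function(y, out) {
  m <- metrics(confusion(y, out$pred))
  m$auroc <- if (length(unique(y)) == 2L) auroc(y, out$score) else NA_real_
  m
}

#' Cross-validated fingerprint/model benchmark
#'
#' Runs every (feature set, model) combination through stratified k-fold
#' cross-validation and reports train and test metrics per fold. Models:
#' `dummy` (uniform-random baseline), `svm` (RBF kernel), `rf` (500-tree
#' random forest), `nb` (Bernoulli-style naive Bayes). Fold assignment and
#' every stochastic model are seeded, so results are reproducible; each
#' fold's train and test sets are asserted disjoint.
#'
#' @param features named list of fingerprint tables (`id`, `fp`) or numeric
#'   feature matrices with rownames; all must cover the same ids.
#' @param labels tibble with `id` and `label` (0/1).
#' @param models character subset of `c("dummy","svm","rf","nb")`.
#' @param k folds (default 5).
#' @param seed RNG seed.
#' @param drop_empty_bits drop all-zero fingerprint columns before fitting.
#' @return object of class `bbb_benchmark`: tibble `feature_set`, `model`,
#'   `fold`, `split`, plus metric columns.
#' @export
run_benchmark <- function(features, labels, models = c("dummy", "svm", "rf", "nb"),
                          k = 5L, seed = 1L, drop_empty_bits = TRUE) {
  stopifnot(is.list(features), length(features) >= 1L, !is.null(names(features)))
  stopifnot(all(c("id", "label") %in% names(labels)))
  ids <- as.character(labels$id)
  y <- as.integer(labels$label)
  if (anyNA(y)) abort("labels must be known (0/1) for benchmarking.")
  if (length(unique(y)) < 2L) abort("need both classes present.")
  mats <- lapply(names(features), function(nm) {
    f <- features[[nm]]
    if (is.matrix(f)) {
      m <- f[match(ids, rownames(f)), , drop = FALSE]
    } else {
      stopifnot(all(c("id", "fp") %in% names(f)))
      hit <- match(ids, as.character(f$id))
      if (anyNA(hit)) abort(sprintf("feature set '%s' is missing molecules.", nm))
      m <- fp_matrix(f$fp[hit], drop_empty = drop_empty_bits)
      rownames(m) <- ids
    }
    if (anyNA(m)) abort(sprintf("feature set '%s' contains NA values.", nm))
    storage.mode(m) <- "double"
    m
  })
  names(mats) <- names(features)
  fold <- stratified_folds(y, k = k, seed = seed)
  rows <- list()
  for (nm in names(mats)) {
    x <- mats[[nm]]
    for (model in models) {
      for (f_i in seq_len(k)) {
        te <- which(fold == f_i)
        tr <- which(fold != f_i)
        stopifnot(length(intersect(tr, te)) == 0L, length(union(tr, te)) == length(y))
        out <- fit_predict(model, x[tr, , drop = FALSE], y[tr],
                           x[te, , drop = FALSE], seed = seed + f_i)
        rows[[length(rows) + 1L]] <- bind_rows(
          cbind(tibble(feature_set = nm, model = model, fold = f_i, split = "train"),
                split_metrics(y[tr], out$train)),
          cbind(tibble(feature_set = nm, model = model, fold = f_i, split = "test"),
                split_metrics(y[te], out$test))
        )
      }
    }
  }
  res <- bind_rows(rows)
  structure(res, class = c("bbb_benchmark", class(res)), seed = seed, k = k)
}

#' @export
print.bbb_benchmark <- function(x, ...) {
  cat(sprintf("<benchmark: %d folds, seed %d>\n", attr(x, "k"), attr(x, "seed")))
  print(glance.bbb_benchmark(x))
  invisible(x)
}

#' Tidy per-fold benchmark results
#'
#' @param x a `bbb_benchmark`.
#' @param ... unused.
#' @return long tibble `feature_set`, `model`, `fold`, `split`, `metric`,
#'   `value`.
#' @export
tidy.bbb_benchmark <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(
      c("accuracy", "precision", "recall", "f1", "mcc", "auroc"),
      names_to = "metric", values_to = "value"
    ) %>%
    select("feature_set", "model", "fold", "split", "metric", "value")
}

#' Fold-averaged benchmark summary (train/test means per cell)
#'
#' @param x a `bbb_benchmark`.
#' @param ... unused.
#' @return tibble with one row per (feature set, model, split) and mean
#'   metrics across folds.
#' @export
glance.bbb_benchmark <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$feature_set, .data$model, .data$split) %>%
    summarise(across(
      c("accuracy", "precision", "recall", "f1", "mcc", "auroc"),
      ~ mean(.x, na.rm = TRUE)
    ), .groups = "drop")
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot fold-averaged test metrics of a benchmark
#'
#' @param object a `bbb_benchmark`.
#' @param metric_cols metrics to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bbb_benchmark <- function(object, metric_cols = c("accuracy", "f1", "mcc", "auroc"), ...) {
  d <- tidy.bbb_benchmark(object) %>%
    filter(.data$split == "test", .data$metric %in% metric_cols)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$model, y = .data$value, fill = .data$feature_set
  )) +
    ggplot2::stat_summary(fun = mean, geom = "col", position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(y = "mean test value", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write benchmark results in long CSV form
#'
#' @param x a `bbb_benchmark`.
#' @param path output CSV.
#' @export
write_benchmark_csv <- function(x, path) {
  write.csv(tidy.bbb_benchmark(x), path, row.names = FALSE)
  invisible(path)
}
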