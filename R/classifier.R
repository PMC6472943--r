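#' Configuration for RFE around a random forest
#'
#' @param subset_sizes Integer grid of candidate feature-subset sizes
#'   (default 2:30). Grid values above the available feature count are
#'   skipped with a warning.
#' @param n_trees Trees per forest (default 500).
#' @param cv_folds Cross-validation folds (default 10), stratified by class.
#' @param cv_repeats Repeats of the whole CV (default 5); each repeat
#'   re-randomizes fold assignment.
#' @param train_fraction Fraction of each class assigned to the training set
#'   by [stratified_split()] (default 0.7).
#' @param importance `"impurity"` (default: mean decrease in Gini impurity)
#'   or `"permutation"` (mean decrease in accuracy) for feature ranking.
#'   Ranking ties are broken by gene id, lexicographically, for determinism.
#' @param seed Integer seed making the whole selection reproducible;
#'   `NULL` uses the current RNG state.
#' @return A list of class `rfe_config`. `mtry` is always recomputed as
#'   `floor(sqrt(p))` of the feature count currently in play.
#' @export
rfe_config <- function(subset_sizes = 2:30, n_trees = 500L, cv_folds = 10L,
                       cv_repeats = 5L, train_fraction = 0.7,
                       importance = c("impurity", "permutation"),
                       seed = NULL) {
  importance <- match.arg(importance)
  stopifnot(all(subset_sizes >= 2), cv_folds >= 2, cv_repeats >= 1,
            train_fraction > 0, train_fraction < 1, n_trees >= 1)
  structure(list(
    subset_sizes = sort(unique(as.integer(subset_sizes))),
    n_trees = as.integer(n_trees), cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats), train_fraction = train_fraction,
    importance = importance, seed = seed
  ), class = "rfe_config")
}

#' Stratified train/test split
#'
#' Per class, assigns `ceiling(train_fraction * n_class)` samples (sampled
#' without replacement) to the training set and the remainder to the test
#' set, so class proportions are approximately preserved. With 45 + 32
#' samples at fraction 0.7 this yields the 55/22 = (32+23)/(13+9) partition.
#'
#' @param annotation Data frame with columns `sample_id` and `condition`
#'   (two-level).
#' @param train_fraction Training fraction (default 0.7).
#' @param seed Optional integer seed.
#' @return A list with character vectors `train` and `test`.
#' @export
stratified_split <- function(annotation, train_fraction = 0.7, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  cls <- split(annotation$sample_id, annotation$condition)
  if (length(cls) != 2) {
    stop("stratified_split expects exactly two classes.", call. = FALSE)
  }
  if (any(lengths(cls) < 2)) {
    stop("Each class needs at least 2 samples.", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  train <- unlist(lapply(cls, function(ids) {
    sample(ids, ceiling(train_fraction * length(ids)))
  }), use.names = FALSE)
  list(train = train,
       test = setdiff(annotation$sample_id, train))
}

# Stratified fold ids: within each class, shuffle and deal into k folds.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

rf_mtry <- function(p) max(1L, floor(sqrt(p)))

# Importance ranking with lexicographic tie-break on feature names.
rank_features <- function(x, y, n_trees, importance) {
  rf <- randomForest::randomForest(
    x, y, ntree = n_trees, mtry = rf_mtry(ncol(x)),
    importance = importance == "permutation"
  )
  imp <- if (importance == "permutation") {
    randomForest::importance(rf, type = 1)[, 1]
  } else {
    randomForest::importance(rf, type = 2)[, 1]
  }
  names(imp)[order(-imp, names(imp))]
}

fold_metrics <- function(pred, truth, positive) {
  pos <- truth == positive
  c(accuracy = mean(pred == truth),
    sensitivity = if (any(pos)) mean(pred[pos] == positive) else NA_real_,
    specificity = if (any(!pos)) mean(pred[!pos] != positive) else NA_real_)
}

#' Recursive feature elimination with a random-forest learner
#'
#' Within each of `cv_repeats x cv_folds` resamples: a forest is fitted on
#' all features of the in-fold data and features are ranked by importance;
#' for every subset size on the grid the model is refitted on the top-ranked
#' features and held-out accuracy, sensitivity and specificity are recorded.
#' Metrics are averaged over resamples; the optimal size is the grid value
#' maximizing mean CV accuracy (ties toward the smaller subset). The final
#' model is refitted on the full training set restricted to the top
#' `optimal_size` features of the full-training-set ranking. `mtry` is
#' recomputed as `floor(sqrt(p))` at every (re)fit.
#'
#' @param expr Training [expr_matrix] (features are genes) or a plain
#'   samples x features matrix.
#' @param labels Two-level factor/character vector of class labels aligned
#'   to samples.
#' @param config An [rfe_config()].
#' @param positive Label of the positive (cancer) class; default the second
#'   factor level.
#' @return An object of class `rfe_result`: list with `profile` (tibble:
#'   `size`, `accuracy`, `sensitivity`, `specificity`, `n_resamples`),
#'   `optimal_size`, `optimal_genes`, `ranking` (full-training-set ranking),
#'   `model` (the final `randomForest`), `positive`, and `config`.
#' @export
rfe_rf_select <- function(expr, labels, config = rfe_config(),
                          positive = NULL) {
  stopifnot(inherits(config, "rfe_config"))
  x <- classifier_matrix(expr)
  labels <- as_two_level(labels, length(labels))
  stopifnot(nrow(x) == length(labels))
  if (min(table(labels)) < config$cv_folds) {
    stop("Each class needs at least cv_folds samples in the training set.",
         call. = FALSE)
  }
  positive <- positive %||% levels(labels)[2]
  sizes <- config$subset_sizes[config$subset_sizes <= ncol(x)]
  if (length(sizes) < length(config$subset_sizes)) {
    warning("Skipping subset size(s) above the feature count: ",
            paste(setdiff(config$subset_sizes, sizes), collapse = ", "),
            call. = FALSE)
  }
  if (length(sizes) == 0) stop("No usable subset size.", call. = FALSE)
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  acc <- array(NA_real_,
               dim = c(length(sizes), 3, config$cv_repeats * config$cv_folds),
               dimnames = list(sizes,
                               c("accuracy", "sensitivity", "specificity"),
                               NULL))
  resample <- 0L
  for (r in seq_len(config$cv_repeats)) {
    fold <- stratified_folds(labels, config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      resample <- resample + 1L
      tr <- fold != f
      ranking <- rank_features(x[tr, , drop = FALSE], labels[tr],
                               config$n_trees, config$importance)
      for (si in seq_along(sizes)) {
        feats <- ranking[seq_len(sizes[si])]
        rf <- randomForest::randomForest(
          x[tr, feats, drop = FALSE], labels[tr],
          ntree = config$n_trees, mtry = rf_mtry(sizes[si]))
        pred <- stats::predict(rf, x[!tr, feats, drop = FALSE])
        acc[si, , resample] <- fold_metrics(pred, labels[!tr], positive)
      }
    }
  }
  profile <- tibble::tibble(
    size = sizes,
    accuracy = apply(acc[, "accuracy", , drop = FALSE], 1, mean,
                     na.rm = TRUE),
    sensitivity = apply(acc[, "sensitivity", , drop = FALSE], 1, mean,
                        na.rm = TRUE),
    specificity = apply(acc[, "specificity", , drop = FALSE], 1, mean,
                        na.rm = TRUE),
    n_resamples = config$cv_repeats * config$cv_folds
  )
  optimal_size <- sizes[which.max(profile$accuracy)]
  full_ranking <- rank_features(x, labels, config$n_trees, config$importance)
  optimal_genes <- full_ranking[seq_len(optimal_size)]
  model <- randomForest::randomForest(
    x[, optimal_genes, drop = FALSE], labels,
    ntree = config$n_trees, mtry = rf_mtry(optimal_size))
  structure(list(profile = profile, optimal_size = optimal_size,
                 optimal_genes = optimal_genes, ranking = full_ranking,
                 model = model, positive = positive, config = config),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> optimal size %d, mean CV accuracy %.3f\n",
              x$optimal_size,
              x$profile$accuracy[x$profile$size == x$optimal_size]))
  cat("genes:", paste(utils::head(x$optimal_genes, 10), collapse = ", "),
      if (x$optimal_size > 10) "..." else "", "\n")
  invisible(x)
}

#' @rdname rfe_rf_select
#' @param x An `rfe_result`.
#' @param ... Unused.
#' @export
tidy.rfe_result <- function(x, ...) x$profile

#' @rdname rfe_rf_select
#' @export
glance.rfe_result <- function(x, ...) {
  opt <- x$profile[x$profile$size == x$optimal_size, ]
  tibble::tibble(optimal_size = x$optimal_size,
                 cv_accuracy = opt$accuracy,
                 cv_sensitivity = opt$sensitivity,
                 cv_specificity = opt$specificity)
}

classifier_matrix <- function(expr) {
  if (inherits(expr, "expr_matrix")) t(as_bare_matrix(expr)) else as.matrix(expr)
}

as_two_level <- function(labels, n) {
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) {
    stop("Two-class labels required.", call. = FALSE)
  }
  labels
}

#' Evaluate a fitted model on a held-out test set
#'
#' Predicts every test sample once with the final model of an
#' [rfe_rf_select()] result and tabulates the confusion matrix against the
#' true labels. All selected features must be present in the test matrix.
#'
#' @param fit An `rfe_result` (or a bare `randomForest` plus `genes`).
#' @param test_expr Test [expr_matrix] (or samples x features matrix).
#' @param labels True test labels.
#' @param genes Feature set when `fit` is a bare model.
#' @param positive Positive-class label; defaults to the one stored in the
#'   `rfe_result`.
#' @return An object of class `confusion_matrix`: list with integer `tp`,
#'   `fn`, `fp`, `tn` and the `positive` label.
#' @export
evaluate_on_test <- function(fit, test_expr, labels, genes = NULL,
                             positive = NULL) {
  if (inherits(fit, "rfe_result")) {
    genes <- fit$optimal_genes
    positive <- positive %||% fit$positive
    model <- fit$model
  } else {
    model <- fit
    if (is.null(genes)) stop("`genes` required for a bare model.",
                             call. = FALSE)
  }
  x <- classifier_matrix(test_expr)
  missing <- setdiff(genes, colnames(x))
  if (length(missing) > 0) {
    stop("Feature(s) missing from the test matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- factor(labels, levels = levels(model$y))
  positive <- positive %||% levels(labels)[2]
  pred <- stats::predict(model, x[, genes, drop = FALSE])
  structure(list(
    tp = sum(pred == positive & labels == positive),
    fn = sum(pred != positive & labels == positive),
    fp = sum(pred == positive & labels != positive),
    tn = sum(pred != positive & labels != positive),
    positive = positive
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> positive =", x$positive, "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' `accuracy = (tp + tn) / total`, `sensitivity = tp / (tp + fn)`,
#' `specificity = tn / (tn + fp)`. A metric with a zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm A `confusion_matrix` (from [evaluate_on_test()]) or a list with
#'   `tp`, `fn`, `fp`, `tn`.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `n`.
#' @export
confusion_metrics <- function(cm) {
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    accuracy = safe_div(cm$tp + cm$tn, total),
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    specificity = safe_div(cm$tn, cm$tn + cm$fp),
    n = total
  )
}

#' ROC curve and Mann-Whitney AUC
#'
#' The AUC is the probability that a random positive sample outranks a
#' random negative one, ties counted one half (the Mann-Whitney / rank-sum
#' formulation, computed from the rank sum of the positive scores). The
#' curve gives TPR and FPR at every distinct score threshold.
#'
#' @param scores Numeric positive-class scores (e.g. class probabilities).
#' @param labels Two-level labels aligned to `scores`.
#' @param positive Positive-class label; default the second level.
#' @return An object of class `roc_result`: list with `curve` (tibble:
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as_two_level(labels, length(scores))
  positive <- positive %||% levels(labels)[2]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("Both classes must be present to compute a ROC curve.",
         call. = FALSE)
  }
  r <- rank(scores)                       # midranks: ties count 1/2
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), 0),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), 0)
  )
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d thresholds)\n", x$auc,
              nrow(x$curve)))
  invisible(x)
}

# Mean CV accuracy of a forest on a fixed feature set.
cv_accuracy <- function(x, y, folds, repeats, n_trees) {
  accs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
      rf <- randomForest::randomForest(
        x[tr, , drop = FALSE], y[tr],
        ntree = n_trees, mtry = rf_mtry(ncol(x)))
      pred <- stats::predict(rf, x[!tr, , drop = FALSE])
      accs <- c(accs, mean(pred == y[!tr]))
    }
  }
  mean(accs)
}

#' Add-one empirical permutation p-value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + rounds)`: the add-one estimator,
#' which can never return 0 (its floor at 1,000 rounds is 0.001).
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistics.
#' @return The empirical p-value.
#' @export
perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Permutation-null significance of a fixed-gene-set classifier
#'
#' Each round permutes the class labels and records the mean repeated-CV
#' accuracy of a random forest on the fixed gene set; the observed accuracy
#' is the same CV statistic under the true labels. The empirical p-value
#' uses the add-one estimator ([perm_pvalue()]).
#'
#' @param expr Training [expr_matrix] (or samples x features matrix).
#' @param labels Two-level class labels.
#' @param genes Fixed feature set (e.g. `optimal_genes` of an `rfe_result`).
#' @param config An [rfe_config()] (uses `cv_folds`, `cv_repeats`,
#'   `n_trees`, `seed`).
#' @param rounds Number of permutation rounds (>= 1).
#' @return An object of class `perm_null`: list with `null_accuracy`
#'   (length-`rounds` numeric), `observed`, `p_value`, `rounds`.
#' @export
permutation_significance <- function(expr, labels, genes,
                                     config = rfe_config(), rounds = 1000L) {
  stopifnot(rounds >= 1)
  x <- classifier_matrix(expr)
  labels <- as_two_level(labels, nrow(x))
  missing <- setdiff(genes, colnames(x))
  if (length(missing) > 0) {
    stop("Feature(s) missing from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[, genes, drop = FALSE]
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  observed <- cv_accuracy(x, labels, config$cv_folds, config$cv_repeats,
                          config$n_trees)
  null_accuracy <- vapply(seq_len(rounds), function(i) {
    cv_accuracy(x, sample(labels), config$cv_folds, config$cv_repeats,
                config$n_trees)
  }, 0)
  structure(list(null_accuracy = null_accuracy, observed = observed,
                 p_value = perm_pvalue(observed, null_accuracy),
                 rounds = as.integer(rounds)),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null> observed %.3f vs null %.3f +/- %.3f (%d rounds), p = %.4g\n",
    x$observed, mean(x$null_accuracy), stats::sd(x$null_accuracy),
    x$rounds, x$p_value))
  invisible(x)
}

#' @rdname permutation_significance
#' @param x A `perm_null`.
#' @param ... Unused.
#' @export
tidy.perm_null <- function(x, ...) {
  tibble::tibble(round = seq_along(x$null_accuracy),
                 accuracy = x$null_accuracy)
}

#' @rdname permutation_significance
#' @export
glance.perm_null <- function(x, ...) {
  tibble::tibble(observed = x$observed,
                 null_mean = mean(x$null_accuracy),
                 null_sd = stats::sd(x$null_accuracy),
                 rounds = x$rounds, p_value = x$p_value)
}
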