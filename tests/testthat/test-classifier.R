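test_that("stratified split uses per-class ceiling rounding", {
  ann <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:77),
    condition = rep(c("healthy", "cancer"), times = c(45, 32)))
  sp <- stratified_split(ann, 0.7, seed = 1)
  cls <- setNames(ann$condition, ann$sample_id)
  expect_length(sp$train, 55)
  expect_length(sp$test, 22)
  expect_equal(sum(cls[sp$train] == "healthy"), 32)   # ceil(0.7*45)
  expect_equal(sum(cls[sp$train] == "cancer"), 23)    # ceil(0.7*32)
  expect_equal(sum(cls[sp$test] == "healthy"), 13)
  expect_equal(sum(cls[sp$test] == "cancer"), 9)

  ann2 <- tibble::tibble(sample_id = paste0("s", 1:20),
                         condition = rep(c("a", "b"), each = 10))
  sp2 <- stratified_split(ann2, 0.5, seed = 2)
  expect_length(sp2$train, 10)
  # a class of 7 at 0.7 contributes ceiling(4.9) = 5 to train
  ann3 <- tibble::tibble(sample_id = paste0("s", 1:14),
                         condition = rep(c("a", "b"), each = 7))
  sp3 <- stratified_split(ann3, 0.7, seed = 3)
  expect_equal(sum(setNames(ann3$condition, ann3$sample_id)[sp3$train] == "a"), 5)
  expect_error(stratified_split(
    tibble::tibble(sample_id = "x", condition = "a")), "two classes")
})

test_that("confusion metrics follow their definitions", {
  cm <- structure(list(tp = 9, fn = 0, fp = 4, tn = 9, positive = "cancer"),
                  class = "confusion_matrix")
  met <- confusion_metrics(cm)
  expect_equal(met$accuracy, 18 / 22)      # 0.818 -> printed 82%
  expect_equal(met$sensitivity, 1)         # 100%
  expect_equal(met$specificity, 9 / 13)    # 0.692 -> printed 69%
  perfect <- list(tp = 5, fn = 0, fp = 0, tn = 5)
  expect_equal(unlist(confusion_metrics(perfect)[1, 1:3]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  wrong <- list(tp = 0, fn = 5, fp = 5, tn = 0)
  expect_equal(confusion_metrics(wrong)$accuracy, 0)
  degenerate <- list(tp = 0, fn = 0, fp = 2, tn = 3)
  expect_true(is.na(confusion_metrics(degenerate)$sensitivity))
})

test_that("ROC/AUC matches the Mann-Whitney definition and pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
                       c("pos", "neg", "pos", "neg"),
                       positive = "pos")$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c("n", "n", "p", "p"),
                       positive = "p")$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("n", "p"), 3),
                       positive = "p")$auc, 0.5)
  expect_error(roc_auc(1:3, c("p", "p", "p")), "Two-class|Both classes")
  withr::local_seed(7)
  for (i in 1:5) {
    sc <- sample(seq(0, 1, 0.1), 30, replace = TRUE)   # plenty of ties
    lab <- sample(c("n", "p"), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(sc, lab, positive = "p")$auc,
                 oracle_auc(sc, lab, "p"))
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(8)
  sc <- runif(40)
  lab <- rep(c("n", "p"), each = 20)
  auc_ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("n", "p"),
                                            direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(sc, lab, positive = "p")$auc, auc_ref)
})

test_that("the add-one permutation p-value counts exceedances correctly", {
  expect_equal(perm_pvalue(0.6, c(0.5, 0.6, 0.7)), 0.75)    # (1+2)/4
  expect_equal(perm_pvalue(0.9, runif(999, 0.4, 0.6)), 0.001)
  expect_equal(perm_pvalue(0.3, runif(999, 0.4, 0.6)), 1)
})

small_rfe_cfg <- function(seed) {
  rfe_config(subset_sizes = 2:8, n_trees = 150, cv_folds = 5,
             cv_repeats = 1, seed = seed)
}

test_that("RFE is reproducible under seed and honors the subset grid", {
  sim <- simulate_feature_matrix(c(20, 20), 40, 4, 2, seed = 11)
  a <- rfe_rf_select(sim$expr, sim$labels, small_rfe_cfg(12))
  b <- rfe_rf_select(sim$expr, sim$labels, small_rfe_cfg(12))
  expect_identical(a$optimal_genes, b$optimal_genes)
  expect_identical(a$profile, b$profile)
  expect_true(a$optimal_size %in% 2:8)
  expect_length(a$optimal_genes, a$optimal_size)
  expect_true(all(a$profile$size %in% 2:8))
  # grid values above the feature count are skipped with a warning
  simsmall <- simulate_feature_matrix(c(20, 20), 6, 2, 2, seed = 13)
  expect_warning(
    r2 <- rfe_rf_select(simsmall$expr, simsmall$labels, small_rfe_cfg(14)),
    "Skipping")
  expect_true(all(r2$profile$size <= 6))
})

test_that("feature selection never sees the test data", {
  sim <- simulate_feature_matrix(c(30, 30), 40, 4, 2, seed = 15)
  ann <- tibble::tibble(sample_id = sample_ids(sim$expr),
                        condition = as.character(sim$labels))
  sp <- stratified_split(ann, 0.7, seed = 16)
  train_only <- sim$expr[, sp$train]
  a <- rfe_rf_select(train_only, sim$labels[match(sp$train, ann$sample_id)],
                     small_rfe_cfg(17))
  # rebuild the training matrix from the full data (test columns present in
  # the source object): selection must be identical
  b <- rfe_rf_select(sim$expr[, sp$train],
                     sim$labels[match(sp$train, ann$sample_id)],
                     small_rfe_cfg(17))
  expect_identical(a$optimal_genes, b$optimal_genes)
})

test_that("pure-noise data yields chance-level CV accuracy", {
  sim <- simulate_feature_matrix(c(20, 20), 30, 0, 0, seed = 18)
  r <- rfe_rf_select(sim$expr, sim$labels, small_rfe_cfg(19))
  best <- max(r$profile$accuracy)
  # central interval around the 0.5 no-information rate
  expect_gt(best, 0.3)
  expect_lt(best, 0.72)
})

test_that("test-set evaluation predicts each sample once and checks
           features", {
  sim <- simulate_feature_matrix(c(25, 25), 20, 3, 3, seed = 20)
  ann <- tibble::tibble(sample_id = sample_ids(sim$expr),
                        condition = as.character(sim$labels))
  sp <- stratified_split(ann, 0.7, seed = 21)
  lab <- setNames(sim$labels, ann$sample_id)
  r <- rfe_rf_select(sim$expr[, sp$train], lab[sp$train], small_rfe_cfg(22))
  cm <- evaluate_on_test(r, sim$expr[, sp$test], lab[sp$test])
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, length(sp$test))
  # strongly separated: no errors expected at shift 3
  expect_equal(cm$fn + cm$fp, 0)
  missing_feature <- sim$expr[setdiff(gene_ids(sim$expr),
                                      r$optimal_genes[1]), sp$test]
  expect_error(evaluate_on_test(r, missing_feature, lab[sp$test]),
               r$optimal_genes[1])
})

test_that("permutation significance is seed-reproducible and counts as the
           direct estimator", {
  sim <- simulate_feature_matrix(c(12, 12), 6, 2, 2, seed = 23)
  cfg <- rfe_config(cv_folds = 4, cv_repeats = 1, n_trees = 100, seed = 24)
  a <- permutation_significance(sim$expr, sim$labels, gene_ids(sim$expr),
                                cfg, rounds = 15)
  b <- permutation_significance(sim$expr, sim$labels, gene_ids(sim$expr),
                                cfg, rounds = 15)
  expect_identical(a$null_accuracy, b$null_accuracy)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$p_value, perm_pvalue(a$observed, a$null_accuracy))
  expect_length(a$null_accuracy, 15)
  expect_gt(a$p_value, 0)
  expect_lte(a$p_value, 1)
})
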