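#' End-to-end TAM-signature pipeline on synthetic data
#'
#' Orchestrates the signature arm of the workflow: generate a
#' TAM-vs-resident-macrophage count cohort with planted up-regulated genes,
#' reference gene sets, a tumor cohort whose survival is linked to the
#' planted module, and a cell-line panel; preprocess (CPM filter, TMM
#' normalization, log-CPM); run moderated-t differential expression; derive
#' the five-filter signature; score the tumor cohort; and run the
#' optimal-cutpoint survival analysis on the score. With the same config the
#' run is byte-identical: one seed is forked deterministically per stage.
#'
#' The default config matches the contrast the pipeline emulates: 4 vs 4
#' macrophage samples with 40 planted genes at log2 fold change 4, a
#' 600-patient tumor cohort, and a hazard ratio of 2 per score SD.
#'
#' @param config A [sim_config()]; `NULL` uses the defaults above.
#' @param signature_cfg A [signature_config()]; its `anchor_gene` is filled
#'   in from the generated reference sets when unset.
#' @param min_group Minimum arm size for the cutpoint scan (default 1).
#' @param out_dir Optional directory: every intermediate is persisted as TSV
#'   plus a JSON run-metadata sidecar.
#' @return A list bundle: `config`, `de`, `signature` (a `tam_signature`),
#'   `scores`, `scan` (a `cutoff_scan`), `km` (a `km_curve` of the
#'   dichotomized groups), `cox` (score and group fits), and `paths` (when
#'   written).
#' @export
run_signature_pipeline <- function(config = NULL,
                                   signature_cfg = signature_config(),
                                   min_group = 1, out_dir = NULL) {
  if (is.null(config)) {
    config <- sim_config(group_sizes = c(4L, 4L),
                         condition_labels = c("RM", "TAM"),
                         n_signal_genes = 40L, effect_log2fc = 4)
  }
  sim <- simulate_two_class_counts(config)
  sets <- make_reference_sets(config, exclude = sim$signal_genes)
  anchor <- attr(sets, "anchor_gene")
  if (is.null(signature_cfg$anchor_gene)) signature_cfg$anchor_gene <- anchor
  tumor <- simulate_tumor_cohort(config, signature_genes = sim$signal_genes,
                                 anchor_gene = signature_cfg$anchor_gene)
  # tumor-cell-expressed genes: a deterministic block outside the module
  universe <- sim_gene_ids(config$n_genes)
  expressed <- utils::tail(setdiff(universe,
                                   c(sim$signal_genes,
                                     signature_cfg$anchor_gene)), 200)
  celllines <- simulate_cell_line_panel(config, expressed_genes = expressed)

  filtered <- filter_low_expression(sim$counts, min_cpm = 1,
                                    min_samples = min(config$group_sizes))
  factors <- normalization_factors(filtered, method = "TMM")
  logexpr <- log_cpm(filtered, factors)
  de <- fit_moderated_t(logexpr, sim$annotation$condition)
  sig <- derive_tam_signature(de, sets, tumor$expr, celllines, signature_cfg)

  scores <- signature_score(tumor$expr, sig$genes)
  scan <- optimal_cutoff_scan(scores$score, tumor$survival,
                              min_group = min_group)
  group <- ifelse(scores$score > scan$optimal_cutoff, "high", "low")
  km <- km_curve(tumor$survival, group = group)
  cox <- list(
    score = cox_fit(tumor$survival,
                    data.frame(score_z = as.vector(scale(scores$score)))),
    group = cox_fit(tumor$survival,
                    data.frame(high = as.numeric(group == "high")))
  )
  bundle <- list(config = config, de = de, signature = sig, scores = scores,
                 scan = scan, km = km, cox = cox)
  if (!is.null(out_dir)) {
    bundle$paths <- write_signature_bundle(bundle, sim, logexpr, out_dir)
  }
  bundle
}

write_tsv_quiet <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_signature_bundle <- function(bundle, sim, logexpr, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  paths <- c(
    write_expression_matrix(logexpr, p("log_expression.tsv")),
    write_tsv_quiet(sim$annotation, p("annotation.tsv")),
    write_tsv_quiet(dplyr::arrange(bundle$de, .data$fdr), p("de_results.tsv")),
    write_tsv_quiet(bundle$signature$trace, p("signature_trace.tsv")),
    write_tsv_quiet(tibble::tibble(gene_id = bundle$signature$genes),
                    p("signature_genes.tsv")),
    write_tsv_quiet(bundle$scores, p("signature_scores.tsv")),
    write_tsv_quiet(bundle$scan$candidates, p("cutoff_candidates.tsv")),
    write_tsv_quiet(as.data.frame(bundle$km), p("km_curve.tsv")),
    write_tsv_quiet(bundle$cox$score, p("cox_score.tsv"))
  )
  meta <- p("run_metadata.json")
  write_run_metadata(meta, seed = bundle$config$seed,
                     params = bundle$config[setdiff(names(bundle$config),
                                                    "seed")])
  c(paths, meta)
}

#' End-to-end monocyte-classifier pipeline on synthetic data
#'
#' Orchestrates the liquid-biopsy arm: generate a two-class monocyte count
#' cohort, preprocess (CPM filter, upper-quartile normalization, log-CPM,
#' batch adjustment when batches are present), split 70/30 stratified by
#' class, run recursive feature elimination with a random-forest learner on
#' the training set only, evaluate the frozen model exactly once on the test
#' set, and assess significance against a permutation null. Test metrics are
#' computed only after feature selection is frozen, so the test set never
#' leaks into selection.
#'
#' The default config matches the cohort the classifier emulates: 45 healthy
#' vs 32 cancer samples with 10 informative genes at log2 fold change 2.
#'
#' @param config A [sim_config()]; `NULL` uses the defaults above (with a
#'   300-gene universe to keep the search tractable).
#' @param rfe_cfg An [rfe_config()]; its seed is forked from the sim seed
#'   when unset.
#' @param rounds Permutation rounds (default 200).
#' @param out_dir Optional output directory for artifacts + metadata.
#' @return A list bundle: `config`, `split`, `rfe` (an `rfe_result`),
#'   `confusion`, `metrics`, `roc` (a `roc_result`), `permutation` (a
#'   `perm_null`), and `paths` (when written).
#' @export
run_classifier_pipeline <- function(config = NULL, rfe_cfg = NULL,
                                    rounds = 200L, out_dir = NULL) {
  if (is.null(config)) {
    config <- sim_config(n_genes = 300L, group_sizes = c(45L, 32L),
                         condition_labels = c("healthy", "cancer"),
                         n_signal_genes = 10L, effect_log2fc = 2)
  }
  if (is.null(rfe_cfg)) rfe_cfg <- rfe_config(seed = config$seed + 10L)
  sim <- simulate_two_class_counts(config)
  filtered <- filter_low_expression(sim$counts, min_cpm = 1,
                                    min_samples = min(config$group_sizes))
  factors <- normalization_factors(filtered, method = "upperquartile")
  logexpr <- log_cpm(filtered, factors)
  if (length(unique(sim$annotation$batch)) > 1) {
    logexpr <- batch_adjust(logexpr, sim$annotation$batch)
  }
  split <- stratified_split(sim$annotation,
                            train_fraction = rfe_cfg$train_fraction,
                            seed = config$seed + 11L)
  lab <- stats::setNames(sim$annotation$condition, sim$annotation$sample_id)
  train_expr <- logexpr[, split$train, drop = FALSE]
  test_expr <- logexpr[, split$test, drop = FALSE]
  train_lab <- factor(lab[split$train], levels = config$condition_labels)
  test_lab <- factor(lab[split$test], levels = config$condition_labels)

  rfe <- rfe_rf_select(train_expr, train_lab, rfe_cfg,
                       positive = config$condition_labels[2])
  confusion <- evaluate_on_test(rfe, test_expr, test_lab)
  metrics <- confusion_metrics(confusion)
  votes <- stats::predict(rfe$model,
                          classifier_matrix(test_expr)[, rfe$optimal_genes,
                                                       drop = FALSE],
                          type = "prob")[, rfe$positive]
  roc <- roc_auc(votes, test_lab, positive = rfe$positive)
  perm_cfg <- rfe_cfg
  perm_cfg$seed <- (rfe_cfg$seed %||% config$seed) + 12L
  permutation <- permutation_significance(train_expr, train_lab,
                                          rfe$optimal_genes, perm_cfg,
                                          rounds = rounds)
  bundle <- list(config = config, split = split, rfe = rfe,
                 confusion = confusion, metrics = metrics, roc = roc,
                 permutation = permutation)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    cm <- confusion
    paths <- c(
      write_tsv_quiet(rfe$profile, p("rfe_profile.tsv")),
      write_tsv_quiet(tibble::tibble(gene_id = rfe$optimal_genes),
                      p("selected_genes.tsv")),
      write_tsv_quiet(roc$curve, p("roc_curve.tsv")),
      write_tsv_quiet(tidy(permutation), p("permutation_null.tsv"))
    )
    mj <- p("metrics.json")
    jsonlite::write_json(list(
      confusion = list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
                       positive = cm$positive),
      test = as.list(metrics), auc = roc$auc,
      permutation = as.list(glance(permutation))
    ), mj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    meta <- p("run_metadata.json")
    write_run_metadata(meta, seed = config$seed,
                       params = list(rounds = rounds,
                                     rfe = rfe_cfg[setdiff(names(rfe_cfg),
                                                           "seed")]))
    bundle$paths <- c(paths, mj, meta)
  }
  bundle
}
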