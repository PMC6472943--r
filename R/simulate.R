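#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' list. The defaults describe the study conditions the pipeline is designed
#' around: a two-class bulk RNA-seq cohort with negative-binomial counts and a
#' planted log2 fold change, and a tumor cohort whose survival hazard is
#' proportional to a planted co-expression-module score.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes Number of genes in the simulated universe.
#' @param group_sizes Integer vector of length 2: samples per condition for
#'   the two-class count generator.
#' @param condition_labels Labels for the two conditions (second label is the
#'   class carrying the planted effect).
#' @param n_signal_genes Number of genes carrying the planted effect.
#' @param effect_log2fc Planted log2 fold change in class 2 (negative values
#'   plant down-regulation).
#' @param nb_dispersion Negative-binomial dispersion, shared across genes
#'   (variance = mu + dispersion * mu^2).
#' @param lib_size_range Range (min, max) of per-sample library sizes; sizes
#'   drawn uniformly.
#' @param batch_shift Per-batch location offset on the log2 scale; 0 disables
#'   batch structure, otherwise samples are split over two batches and the
#'   second is shifted by `batch_shift`.
#' @param n_patients Tumor-cohort size.
#' @param module_loading Latent-factor loading for planted-module genes; with
#'   unit residual noise the expected pairwise Pearson correlation inside the
#'   module is `module_loading^2 / (1 + module_loading^2)` (default ~0.6).
#' @param cox_beta Log hazard ratio linking the standardized signature score
#'   to the survival hazard.
#' @param baseline_hazard Baseline event rate, events per month.
#' @param censor_rate Expected fraction censored under the null (`cox_beta =
#'   0`); the uniform censoring window is solved from it.
#' @param n_cell_lines Number of cell lines in the simulated expression panel.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       group_sizes = c(40L, 40L),
                       condition_labels = c("healthy", "cancer"),
                       n_signal_genes = 100L,
                       effect_log2fc = 2,
                       nb_dispersion = 0.1,
                       lib_size_range = c(8e6, 12e6),
                       batch_shift = 0,
                       n_patients = 600L,
                       module_loading = sqrt(1.5),
                       cox_beta = log(2),
                       baseline_hazard = 0.005,
                       censor_rate = 0.6,
                       n_cell_lines = 57L) {
  if (any(group_sizes != round(group_sizes))) {
    stop("group_sizes must be integers.", call. = FALSE)
  }
  group_sizes <- as.integer(group_sizes)
  stopifnot(length(group_sizes) == 2, all(group_sizes >= 2),
            length(condition_labels) == 2,
            n_genes >= 1, n_signal_genes >= 0, n_signal_genes <= n_genes,
            nb_dispersion >= 0, length(lib_size_range) == 2,
            all(lib_size_range > 0), n_patients >= 2,
            baseline_hazard > 0, censor_rate >= 0, censor_rate < 1,
            n_cell_lines >= 1)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    group_sizes = group_sizes, condition_labels = condition_labels,
    n_signal_genes = as.integer(n_signal_genes),
    effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
    lib_size_range = lib_size_range, batch_shift = batch_shift,
    n_patients = as.integer(n_patients), module_loading = module_loading,
    cox_beta = cox_beta, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, n_cell_lines = as.integer(n_cell_lines)
  ), class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a two-class RNA-seq count cohort
#'
#' Draws gene-by-sample counts from a negative-binomial model with gene-wise
#' baseline abundances and a shared dispersion. Exactly `n_signal_genes`
#' genes (the first ones, recorded in the output) carry a mean shift of
#' `effect_log2fc` log2 units in the second condition. When `batch_shift` is
#' non-zero, samples are split alternately over two batches and the second
#' batch is shifted on the log scale. Fully reproducible under the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (an [expr_matrix] with counts units),
#'   `annotation` (tibble: `sample_id`, `condition`, `batch`), and
#'   `signal_genes` (character vector of planted gene ids).
#' @export
simulate_two_class_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n1 <- config$group_sizes[1]; n2 <- config$group_sizes[2]
  n <- n1 + n2
  genes <- sim_gene_ids(config$n_genes)
  samples <- sprintf("S%03d", seq_len(n))
  condition <- rep(config$condition_labels, times = c(n1, n2))
  batch <- if (config$batch_shift != 0) {
    rep(c("b1", "b2"), length.out = n)
  } else {
    rep("b1", n)
  }
  # relative abundances span ~8 log2 units, a typical bulk dynamic range
  log2_abund <- stats::runif(config$n_genes, 0, 8)
  q <- 2^log2_abund
  lib <- stats::runif(n, config$lib_size_range[1], config$lib_size_range[2])
  signal <- genes[seq_len(config$n_signal_genes)]
  fc <- rep(1, config$n_genes)
  fc[seq_len(config$n_signal_genes)] <- 2^config$effect_log2fc
  mu <- outer(q, lib / sum(q))           # genes x samples baseline means
  mu[, condition == config$condition_labels[2]] <-
    mu[, condition == config$condition_labels[2]] * fc
  mu <- sweep(mu, 2, 2^(config$batch_shift * (batch == "b2")), `*`)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu),
                   size = if (config$nb_dispersion > 0)
                     1 / config$nb_dispersion else Inf),
    nrow = config$n_genes, dimnames = list(genes, samples)
  )
  list(
    counts = expr_matrix(counts, "counts"),
    annotation = tibble::tibble(sample_id = samples, condition = condition,
                                batch = batch),
    signal_genes = signal
  )
}

# Solve the uniform-censoring window W so that, under the null hazard h0,
# P(censored) = (1 - exp(-h0 W)) / (h0 W) equals the requested rate.
censor_window <- function(baseline_hazard, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(x) (1 - exp(-x)) / x - censor_rate
  x <- stats::uniroot(f, c(1e-9, 1e4))$root
  x / baseline_hazard
}

#' Simulate a tumor expression cohort with survival linked to a gene module
#'
#' Generates a log2-scale expression matrix in which `signature_genes` (plus
#' an optional `anchor_gene`) form a correlated module driven by one shared
#' latent factor per patient. Survival follows a proportional-hazards model:
#' the per-patient hazard is `baseline_hazard * exp(cox_beta * z)` where `z`
#' is the standardized median signature score of the module genes. Event
#' times are exponential; censoring is independent uniform over a follow-up
#' window solved from `censor_rate`. Clinical covariates are drawn with
#' declared marginals (ER+ 75%, PR+ 60%, Her2+ 15%, grade I/II/III 20/45/35%,
#' age ~ Normal(61, 12) years, tumor size log-normal around 22 mm),
#' independent of survival.
#'
#' @param config A [sim_config()].
#' @param signature_genes Character vector of module gene ids (must be a
#'   subset of the simulated universe; must be non-empty).
#' @param anchor_gene Optional gene id to load on the same latent factor
#'   (a CD163-like pan-macrophage anchor).
#' @return A list with `expr` ([expr_matrix], log2norm), `annotation`
#'   (tibble), `survival` (tibble: `sample_id`, `time`, `event`), `score`
#'   (tibble: `sample_id`, `score`, `z`), and `latent` (tibble: `sample_id`,
#'   `factor`).
#' @export
simulate_tumor_cohort <- function(config, signature_genes,
                                  anchor_gene = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(signature_genes) == 0) {
    stop("signature_genes must be non-empty.", call. = FALSE)
  }
  genes <- sim_gene_ids(config$n_genes)
  missing <- setdiff(c(signature_genes, anchor_gene), genes)
  if (length(missing) > 0) {
    stop("signature/anchor gene(s) outside the simulated universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  withr::local_seed(config$seed + 1L)
  n <- config$n_patients
  patients <- sprintf("P%04d", seq_len(n))
  mu <- stats::runif(config$n_genes, 4, 10)
  f <- stats::rnorm(n)                    # shared latent factor
  expr <- matrix(stats::rnorm(config$n_genes * n, mean = mu, sd = 1),
                 nrow = config$n_genes, dimnames = list(genes, patients))
  module <- unique(c(signature_genes, anchor_gene))
  expr[module, ] <- expr[module, ] +
    config$module_loading * matrix(rep(f, each = length(module)),
                                   nrow = length(module))
  em <- expr_matrix(expr, "log2norm")

  score <- signature_score(em, signature_genes)$score
  z <- as.vector(scale(score))
  rate <- config$baseline_hazard * exp(config$cox_beta * z)
  t_event <- stats::rexp(n, rate)
  W <- censor_window(config$baseline_hazard, config$censor_rate)
  t_cens <- if (is.finite(W)) stats::runif(n, 0, W) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  annotation <- tibble::tibble(
    sample_id = patients,
    condition = "tumor",
    batch = "b1",
    er = sample(c("+", "-"), n, TRUE, prob = c(0.75, 0.25)),
    pr = sample(c("+", "-"), n, TRUE, prob = c(0.60, 0.40)),
    her2 = sample(c("+", "-"), n, TRUE, prob = c(0.15, 0.85)),
    grade = sample(c("I", "II", "III"), n, TRUE, prob = c(0.20, 0.45, 0.35)),
    tumor_size_mm = stats::rlnorm(n, log(22), 0.5),
    age_years = pmax(25, stats::rnorm(n, 61, 12)),
    subtype = "unknown"
  )
  list(
    expr = em,
    annotation = annotation,
    survival = tibble::tibble(sample_id = patients, time = time,
                              event = event),
    score = tibble::tibble(sample_id = patients, score = score, z = z),
    latent = tibble::tibble(sample_id = patients, factor = f)
  )
}

#' Simulate a tumor cell-line expression panel
#'
#' Log2-scale expression across cell lines in which `expressed_genes` have a
#' per-gene median above 6 (drawn around 9) and all other genes a median
#' below 6 (drawn around 2) — the structure needed to exercise a
#' tumor-cell-expression exclusion gate.
#'
#' @param config A [sim_config()].
#' @param expressed_genes Gene ids to make highly expressed in the panel
#'   (may be empty).
#' @return An [expr_matrix] (log2norm), genes x cell lines.
#' @export
simulate_cell_line_panel <- function(config, expressed_genes = character()) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed + 2L)
  genes <- sim_gene_ids(config$n_genes)
  lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  mu <- ifelse(genes %in% expressed_genes, 9, 2)
  m <- matrix(stats::rnorm(config$n_genes * config$n_cell_lines,
                           mean = mu, sd = 1),
              nrow = config$n_genes, dimnames = list(genes, lines))
  expr_matrix(m, "log2norm")
}

#' Generate reference gene-set collections
#'
#' Builds the gene-set inputs the pipeline consumes: an immune compendium of
#' `n_sets` cell-type sets (one of which, `MACROPHAGES`, is the
#' macrophage-lineage set that a signature cascade whitelists), a CSF1-like
#' response set, and a PAM50-like intrinsic-subtype set. Genes listed in
#' `exclude` are kept out of every set, so a planted signature module is not
#' removed by the compendium gate; a designated anchor gene (a CD163
#' stand-in) is chosen outside both `exclude` and the compendium sets.
#'
#' @param config A [sim_config()].
#' @param n_sets Number of immune cell-type sets (default 17).
#' @param set_size Members per immune set (default 30).
#' @param csf1_size Members of the CSF1-response-like set (default 112).
#' @param pam50_size Members of the PAM50-like set (default 50).
#' @param exclude Gene ids excluded from all sets.
#' @return A gene-set tibble (`set_id`, `description`, `genes`) with
#'   attribute `anchor_gene`.
#' @export
make_reference_sets <- function(config, n_sets = 17L, set_size = 30L,
                                csf1_size = 112L, pam50_size = 50L,
                                exclude = character()) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed + 3L)
  genes <- sim_gene_ids(config$n_genes)
  pool <- setdiff(genes, exclude)
  need <- n_sets * set_size + csf1_size + pam50_size + 1L
  if (max(set_size, csf1_size, pam50_size) > length(pool)) {
    stop("Requested set size exceeds the available gene universe.",
         call. = FALSE)
  }
  if (need > length(pool)) {
    stop("Gene universe too small for disjoint reference sets (need ",
         need, ", have ", length(pool), ").", call. = FALSE)
  }
  drawn <- sample(pool, need)
  idx <- 0L
  take <- function(k) {
    out <- drawn[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  anchor <- take(1L)
  immune_ids <- c("MACROPHAGES",
                  sprintf("IMMUNE_%02d", seq_len(n_sets - 1L)))
  sets <- tibble::tibble(
    set_id = c(immune_ids, "CSF1_RESPONSE", "PAM50_LIKE"),
    description = c("macrophage lineage",
                    rep("immune cell type", n_sets - 1L),
                    "CSF1 response signature (112-gene-like)",
                    "intrinsic subtype set (PAM50-like)"),
    genes = c(replicate(n_sets, take(set_size), simplify = FALSE),
              list(take(csf1_size)), list(take(pam50_size)))
  )
  attr(sets, "anchor_gene") <- anchor
  sets
}

#' Simulate a Gaussian feature matrix with a planted class shift
#'
#' Draws standard-normal features (unit pooled SD) for two classes and adds
#' a mean shift of `shift` pooled SDs to the first `n_informative` features
#' in the second class. This is the design-point generator for classifier
#' benchmarking: the signal strength is stated directly in effect-size
#' units rather than through the count model.
#'
#' @param n_per_class Integer vector of length 2: samples per class.
#' @param n_features Number of features.
#' @param n_informative Number of features carrying the shift (first ones).
#' @param shift Class-2 mean shift in pooled-SD units.
#' @param labels Class labels (length 2); default `c("healthy", "cancer")`.
#' @param seed Optional integer seed.
#' @return A list with `expr` (an [expr_matrix], log2norm units, features as
#'   genes), `labels` (factor), and `informative` (feature ids).
#' @export
simulate_feature_matrix <- function(n_per_class, n_features,
                                    n_informative, shift,
                                    labels = c("healthy", "cancer"),
                                    seed = NULL) {
  stopifnot(length(n_per_class) == 2, n_informative <= n_features)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- sum(n_per_class)
  feats <- sprintf("F%03d", seq_len(n_features))
  cls <- factor(rep(labels, times = n_per_class), levels = labels)
  m <- matrix(stats::rnorm(n_features * n), nrow = n_features,
              dimnames = list(feats, sprintf("S%03d", seq_len(n))))
  if (n_informative > 0) {
    m[seq_len(n_informative), cls == labels[2]] <-
      m[seq_len(n_informative), cls == labels[2]] + shift
  }
  list(expr = expr_matrix(m, "log2norm"), labels = cls,
       informative = feats[seq_len(n_informative)])
}
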