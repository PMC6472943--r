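#' Filter lowly expressed genes by CPM
#'
#' Retains exactly the genes with counts-per-million above `min_cpm` in at
#' least `min_samples` samples, where CPM is the raw count scaled by the
#' sample's library size times 1e6. `min_samples` is conventionally set to
#' the size of the smallest condition group. The sample set is unchanged.
#'
#' @param counts An [expr_matrix] with counts units.
#' @param min_cpm CPM threshold (strict `>`); default 1.
#' @param min_samples Minimum number of samples clearing the threshold.
#' @return A filtered [expr_matrix] (counts).
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 1) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_units(counts) != "counts") {
    stop("filter_low_expression expects counts units, got ",
         expr_units(counts), ".", call. = FALSE)
  }
  stopifnot(min_cpm > 0, min_samples >= 1)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("Sample(s) with zero library size: ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  cpm <- sweep(as_bare_matrix(counts), 2, lib, `/`) * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Between-sample normalization factors (TMM / upper-quartile)
#'
#' Computes per-sample scaling factors with the trimmed-mean-of-M-values
#' method (30% trim on log-ratios M, 5% on average abundances A, inverse
#' binomial-variance weights, reference sample chosen by upper-quartile
#' proximity to the mean) or by the upper quartile of nonzero counts over
#' library size. Factors are rescaled to geometric mean 1. Computation is
#' delegated to `edgeR::calcNormFactors()`, the canonical implementation of
#' both methods.
#'
#' @param counts A filtered [expr_matrix] with counts units.
#' @param method `"TMM"` (default) or `"upperquartile"`.
#' @return A tibble with columns `sample_id`, `factor`, `method`.
#' @export
normalization_factors <- function(counts, method = c("TMM", "upperquartile")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_units(counts) != "counts") {
    stop("normalization_factors expects counts units.", call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("Sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  if (method == "upperquartile") {
    uq_def <- apply(as_bare_matrix(counts), 2,
                    function(x) stats::quantile(x[x > 0], 0.75, names = FALSE))
    if (any(!is.finite(uq_def))) {
      stop("Sample(s) with undefined upper quartile (no nonzero counts): ",
           paste(colnames(counts)[!is.finite(uq_def)], collapse = ", "),
           call. = FALSE)
    }
  }
  f <- edgeR::calcNormFactors(as_bare_matrix(counts), method = method)
  tibble::tibble(sample_id = colnames(counts), factor = unname(f),
                 method = method)
}

#' Log2 counts-per-million
#'
#' Transforms counts to `log2((count + prior) / effective_library * 1e6)`,
#' where the effective library size is the raw library size times the
#' sample's normalization factor. With no factors supplied, all factors
#' default to 1 (library-size-only normalization).
#'
#' @param counts An [expr_matrix] with counts units.
#' @param factors Optional tibble from [normalization_factors()] (columns
#'   `sample_id`, `factor`), aligned by sample id.
#' @param prior Pseudo-count added to every count before the log; must be
#'   positive. Default 0.5.
#' @return An [expr_matrix] with log2norm units.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_units(counts) != "counts") {
    stop("log_cpm expects counts units.", call. = FALSE)
  }
  if (prior <= 0) stop("prior must be > 0.", call. = FALSE)
  lib <- colSums(counts)
  f <- rep(1, ncol(counts))
  if (!is.null(factors)) {
    i <- match(colnames(counts), factors$sample_id)
    if (any(is.na(i))) {
      stop("factors missing sample(s): ",
           paste(colnames(counts)[is.na(i)], collapse = ", "), call. = FALSE)
    }
    f <- factors$factor[i]
  }
  eff <- lib * f
  m <- log2(sweep(as_bare_matrix(counts) + prior, 2, eff, `/`) * 1e6)
  expr_matrix(m, "log2norm")
}

#' Median-center each gene across samples
#'
#' Subtracts each gene's across-sample median, so every gene row of the
#' output has median 0. Idempotent.
#'
#' @param expr An [expr_matrix] with log2norm (or centered) units.
#' @return An [expr_matrix] with centered units.
#' @export
median_center <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr_units(expr) == "counts") {
    stop("median_center expects log-scale values, not counts.", call. = FALSE)
  }
  med <- apply(as_bare_matrix(expr), 1, stats::median)
  expr_matrix(sweep(as_bare_matrix(expr), 1, med, `-`), "centered")
}

#' Empirical-Bayes batch adjustment
#'
#' Removes per-gene, per-batch location and scale effects, shrinking the
#' batch-effect estimates toward across-gene parametric empirical-Bayes
#' priors and restoring the grand mean; no covariates are modeled.
#' Computation is delegated to `sva::ComBat()` (parametric, `mod = NULL`).
#' With a single batch the input is returned unchanged.
#'
#' @param expr An [expr_matrix] with log2norm units.
#' @param batches Character/factor vector of batch labels, one per sample
#'   (aligned to columns), or the name is matched against a data frame via
#'   `annotation` + `batch_col`.
#' @return An [expr_matrix] with log2norm units.
#' @export
batch_adjust <- function(expr, batches) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr_units(expr) != "log2norm") {
    stop("batch_adjust expects log2norm units.", call. = FALSE)
  }
  batches <- as.character(batches)
  if (length(batches) != ncol(expr)) {
    stop("One batch label per sample is required.", call. = FALSE)
  }
  tab <- table(batches)
  if (any(tab < 2)) {
    stop("Batch(es) with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  if (length(tab) == 1) return(expr)
  # ComBat drops genes with zero within-batch variance from shrinkage; guard
  # fully constant rows, which it cannot standardize.
  m <- as_bare_matrix(expr)
  const <- apply(m, 1, function(x) stats::var(x) == 0)
  adj <- m
  if (any(!const)) {
    adj[!const, ] <- suppressMessages(
      sva::ComBat(dat = m[!const, , drop = FALSE], batch = batches,
                  mod = NULL, par.prior = TRUE)
    )
  }
  expr_matrix(adj, "log2norm")
}
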