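#' Configuration for the five-filter TAM signature cascade
#'
#' Thresholds follow the strict/non-strict inequalities of the derivation
#' they encode: differential-expression gate `log2fc > de_min_log2fc` and
#' `fdr < de_max_fdr`; co-expression gate `|r| >= coexpr_min_abs_r`; anchor
#' gate `r > anchor_min_r` and `p <= anchor_max_p`; tumor-cell exclusion gate
#' removes genes with cell-line median `> cellline_max_median_log2`.
#'
#' @param de_min_log2fc DE fold-change gate (default 3).
#' @param de_max_fdr DE FDR gate (default 0.05).
#' @param coexpr_min_abs_r Minimum absolute pairwise Pearson correlation for
#'   the co-expression gate (default 0.5).
#' @param coexpr_mode `"select"` (default: keep genes correlated at
#'   `>= coexpr_min_abs_r` with at least one other surviving candidate) or
#'   `"reduce"` (redundancy removal via `caret::findCorrelation()`).
#' @param anchor_gene Id of the pan-macrophage anchor gene (CD163 stand-in);
#'   must be present in the tumor cohort matrix.
#' @param anchor_min_r Minimum Pearson correlation with the anchor
#'   (default 0.5, strict).
#' @param anchor_max_p Maximum two-sided correlation p-value for the anchor
#'   gate (default 0.05).
#' @param cellline_max_median_log2 Cell-line median expression above which a
#'   gene is considered tumor-cell-expressed and removed (default 6).
#' @return A list of class `signature_config`.
#' @export
signature_config <- function(de_min_log2fc = 3, de_max_fdr = 0.05,
                             coexpr_min_abs_r = 0.5,
                             coexpr_mode = c("select", "reduce"),
                             anchor_gene = NULL, anchor_min_r = 0.5,
                             anchor_max_p = 0.05,
                             cellline_max_median_log2 = 6) {
  coexpr_mode <- match.arg(coexpr_mode)
  stopifnot(de_max_fdr > 0, de_max_fdr <= 1, coexpr_min_abs_r >= 0,
            coexpr_min_abs_r <= 1, anchor_max_p > 0, anchor_max_p <= 1)
  structure(list(
    de_min_log2fc = de_min_log2fc, de_max_fdr = de_max_fdr,
    coexpr_min_abs_r = coexpr_min_abs_r, coexpr_mode = coexpr_mode,
    anchor_gene = anchor_gene, anchor_min_r = anchor_min_r,
    anchor_max_p = anchor_max_p,
    cellline_max_median_log2 = cellline_max_median_log2
  ), class = "signature_config")
}

# Two-sided p for a Pearson correlation via the t transform with n - 2 df.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Derive a TAM gene signature through the five-filter cascade
#'
#' Starting from a two-group differential-expression result (TAM vs resident
#' macrophage), applies in order: (1) the DE gate (`log2fc >` threshold,
#' `fdr <` threshold); (2) the immune-compendium gate, removing genes that
#' belong to any compendium set not whitelisted as macrophage/monocyte
#' lineage; (3) the co-expression gate on the tumor cohort (keep genes with
#' absolute Pearson correlation at or above the threshold with at least one
#' other surviving candidate, or redundancy removal under
#' `coexpr_mode = "reduce"`); (4) the anchor gate, keeping genes positively
#' correlated with the designated pan-macrophage anchor gene at the stated
#' correlation and p-value thresholds; (5) the tumor-cell exclusion gate,
#' removing genes whose median expression across cell lines exceeds the
#' threshold. The cascade is fully deterministic.
#'
#' @param de DE tibble from [fit_moderated_t()] (columns `gene_id`,
#'   `log2fc`, `fdr`).
#' @param compendium Gene-set tibble (see [read_gene_sets()]) of immune
#'   cell-type sets.
#' @param tumor_expr Tumor-cohort [expr_matrix] (log2norm) used for the
#'   co-expression and anchor gates; needs at least 3 samples.
#' @param celllines Cell-line panel [expr_matrix] (log2norm) used for the
#'   tumor-cell exclusion gate.
#' @param config A [signature_config()]; its `anchor_gene` must be set and
#'   present in `tumor_expr`.
#' @param macrophage_sets Character vector of compendium `set_id`s
#'   whitelisted as macrophage/monocyte lineage (their members are not
#'   removed at stage 2). Default `"MACROPHAGES"`.
#' @return A list of class `tam_signature` with `genes` (character vector)
#'   and `trace` (tibble: `stage`, `n_kept`), stages in cascade order.
#' @export
derive_tam_signature <- function(de, compendium, tumor_expr, celllines,
                                 config, macrophage_sets = "MACROPHAGES") {
  stopifnot(inherits(config, "signature_config"),
            inherits(tumor_expr, "expr_matrix"),
            inherits(celllines, "expr_matrix"))
  if (is.null(config$anchor_gene)) {
    stop("config$anchor_gene must be set.", call. = FALSE)
  }
  if (!config$anchor_gene %in% rownames(tumor_expr)) {
    stop("Anchor gene ", config$anchor_gene,
         " absent from the tumor cohort matrix.", call. = FALSE)
  }
  if (ncol(tumor_expr) < 3) {
    stop("Tumor cohort needs >= 3 samples for correlation p-values.",
         call. = FALSE)
  }

  # stage 1: differential-expression gate
  cand <- de$gene_id[de$log2fc > config$de_min_log2fc &
                       de$fdr < config$de_max_fdr]
  trace <- tibble::tibble(stage = "de_gate", n_kept = length(cand))

  # stage 2: compendium gate — drop members of non-whitelisted immune sets
  other <- compendium[!compendium$set_id %in% macrophage_sets, ]
  other_genes <- unique(unlist(other$genes))
  cand <- setdiff(cand, other_genes)
  trace <- dplyr::bind_rows(trace, tibble::tibble(
    stage = "compendium_gate", n_kept = length(cand)))

  # stage 3: co-expression gate on the tumor cohort
  cand <- intersect(cand, rownames(tumor_expr))
  if (length(cand) >= 2) {
    sub <- t(as_bare_matrix(tumor_expr[cand, , drop = FALSE]))
    r <- suppressWarnings(stats::cor(sub))
    r[!is.finite(r)] <- 0
    diag(r) <- 0
    if (config$coexpr_mode == "select") {
      cand <- cand[apply(abs(r) >= config$coexpr_min_abs_r, 1, any)]
    } else {
      if (!requireNamespace("caret", quietly = TRUE)) {
        stop("coexpr_mode = \"reduce\" needs the caret package.",
             call. = FALSE)
      }
      diag(r) <- 1
      drop_idx <- caret::findCorrelation(r, cutoff = config$coexpr_min_abs_r)
      if (length(drop_idx) > 0) cand <- cand[-drop_idx]
    }
  } else if (config$coexpr_mode == "select") {
    cand <- character()                  # no partner available
  }
  trace <- dplyr::bind_rows(trace, tibble::tibble(
    stage = "coexpression_gate", n_kept = length(cand)))

  # stage 4: anchor-correlation gate
  if (length(cand) > 0) {
    anchor <- as.vector(as_bare_matrix(
      tumor_expr[config$anchor_gene, , drop = FALSE]))
    r_a <- suppressWarnings(stats::cor(
      t(as_bare_matrix(tumor_expr[cand, , drop = FALSE])), anchor))[, 1]
    r_a[!is.finite(r_a)] <- 0
    p_a <- cor_pvalue(r_a, ncol(tumor_expr))
    cand <- cand[r_a > config$anchor_min_r & p_a <= config$anchor_max_p]
  }
  trace <- dplyr::bind_rows(trace, tibble::tibble(
    stage = "anchor_gate", n_kept = length(cand)))

  # stage 5: tumor-cell exclusion gate (genes absent from the panel are kept:
  # there is no evidence they are tumor-cell expressed)
  in_panel <- intersect(cand, rownames(celllines))
  if (length(in_panel) > 0) {
    med <- apply(as_bare_matrix(celllines[in_panel, , drop = FALSE]), 1,
                 stats::median)
    expressed <- in_panel[med > config$cellline_max_median_log2]
    cand <- setdiff(cand, expressed)
  }
  trace <- dplyr::bind_rows(trace, tibble::tibble(
    stage = "cellline_gate", n_kept = length(cand)))

  structure(list(genes = cand, trace = trace), class = "tam_signature")
}

#' @export
print.tam_signature <- function(x, ...) {
  cat("<tam_signature>", length(x$genes), "genes\n")
  print(x$trace)
  invisible(x)
}

#' @export
tidy.tam_signature <- function(x, ...) x$trace

#' Median signature score per sample
#'
#' Restricts the matrix to the signature genes present, median-centers each
#' gene across samples, and takes the per-sample median across the signature
#' genes. Missing genes are reported with a warning; no overlap is an error.
#'
#' @param expr An [expr_matrix] with log2norm (or centered) units.
#' @param genes Character vector of signature gene ids.
#' @return A tibble with columns `sample_id`, `score`.
#' @export
signature_score <- function(expr, genes) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(genes) == 0) stop("Empty signature gene list.", call. = FALSE)
  present <- intersect(unique(genes), rownames(expr))
  absent <- setdiff(unique(genes), present)
  if (length(present) == 0) {
    stop("No signature gene present in the matrix; absent: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(absent) > 0) {
    warning("Signature gene(s) absent from the matrix: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  centered <- median_center(expr[present, , drop = FALSE])
  tibble::tibble(
    sample_id = colnames(expr),
    score = unname(apply(as_bare_matrix(centered), 2, stats::median))
  )
}
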