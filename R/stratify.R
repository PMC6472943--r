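#' Stratify a cohort into CSF1 High / Mid / Low groups
#'
#' K-means (k = 3, multiple restarts, best within-cluster sum of squares)
#' on the sample-by-signature-gene submatrix; the three clusters are then
#' relabeled High / Mid / Low by descending mean expression of the
#' signature genes, so the labels depend only on the group means, never on
#' cluster indexing or the RNG.
#'
#' @param expr An [expr_matrix] (log2norm) with at least 3 samples.
#' @param csf1_genes CSF1-response signature gene ids; at least one must be
#'   present in the matrix.
#' @param seed Optional integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 25).
#' @return An object of class `stratification`: list with `labels` (tibble:
#'   `sample_id`, `group`), `counts` (named per-group sizes), `centroids`
#'   (group x gene matrix).
#' @export
csf1_stratify <- function(expr, csf1_genes, seed = NULL, nstart = 25) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr) < 3) stop("Need >= 3 samples for k = 3.", call. = FALSE)
  present <- intersect(csf1_genes, rownames(expr))
  if (length(present) == 0) {
    stop("No CSF1 signature gene present in the matrix.", call. = FALSE)
  }
  x <- t(as_bare_matrix(expr[present, , drop = FALSE]))
  if (!is.null(seed)) withr::local_seed(seed)
  if (nrow(x) == 3) {
    # degenerate k = n: every sample is its own cluster
    km <- list(cluster = stats::setNames(1:3, rownames(x)), centers = x)
  } else {
    km <- stats::kmeans(x, centers = 3, nstart = nstart)
  }
  mean_by_cluster <- tapply(rowMeans(x), km$cluster, mean)
  ord <- order(mean_by_cluster, decreasing = TRUE)   # High > Mid > Low
  relabel <- stats::setNames(c("High", "Mid", "Low"), names(mean_by_cluster)[ord])
  group <- unname(relabel[as.character(km$cluster)])
  centroids <- km$centers[as.integer(names(relabel)), , drop = FALSE]
  rownames(centroids) <- unname(relabel)
  structure(list(
    labels = tibble::tibble(sample_id = colnames(expr), group = group),
    counts = table(factor(group, levels = c("High", "Mid", "Low"))),
    centroids = centroids
  ), class = "stratification")
}

#' Assign samples to subtype clusters by PAM50-style hierarchical clustering
#'
#' Agglomerative clustering of samples on the PAM50-gene submatrix with
#' distance 1 - Pearson correlation and average linkage, cut at `k`
#' clusters. Because correlation is invariant to per-sample positive affine
#' transforms, so is the assignment. Cluster-to-subtype naming is
#' caller-provided via `subtype_map`; without it, anonymous cluster ids
#' (`C1`..`Ck`) are returned — the function never invents biological labels.
#'
#' @param expr An [expr_matrix] (log2norm) with at least `k` samples.
#' @param pam50_genes Subtype gene ids (at least 2 present).
#' @param k Number of clusters to cut (default 5).
#' @param subtype_map Optional named character vector mapping cluster ids
#'   (`"C1"`, ...) to subtype names.
#' @return An object of class `stratification`: `labels` (tibble:
#'   `sample_id`, `group`), `counts`, `centroids` (cluster x gene means),
#'   and `hclust` (the tree).
#' @export
pam50_assign <- function(expr, pam50_genes, k = 5, subtype_map = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), k >= 1)
  if (ncol(expr) < k) {
    stop("Fewer samples than clusters requested (k = ", k, ").",
         call. = FALSE)
  }
  present <- intersect(pam50_genes, rownames(expr))
  if (length(present) < 2) {
    stop("Need >= 2 subtype genes present for correlation distance.",
         call. = FALSE)
  }
  sub <- as_bare_matrix(expr[present, , drop = FALSE])
  d <- stats::as.dist(1 - suppressWarnings(stats::cor(sub)))
  if (any(!is.finite(d))) {
    stop("Correlation distance undefined for constant sample profile(s).",
         call. = FALSE)
  }
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  group <- paste0("C", cl)
  if (!is.null(subtype_map)) {
    mapped <- subtype_map[group]
    if (any(is.na(mapped))) {
      stop("subtype_map missing cluster(s): ",
           paste(unique(group[is.na(mapped)]), collapse = ", "),
           call. = FALSE)
    }
    group <- unname(mapped)
  }
  x <- t(sub)
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(x)), group),
                                     function(i) colMeans(x[i, , drop = FALSE])))
  structure(list(
    labels = tibble::tibble(sample_id = colnames(expr), group = group),
    counts = table(group),
    centroids = centroids,
    hclust = hc
  ), class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("<stratification>\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.stratification <- function(x, ...) x$labels
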