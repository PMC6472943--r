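#' Gene-by-sample expression matrix
#'
#' `expr_matrix()` wraps a numeric matrix (genes as rows, samples as columns)
#' together with a units tag that records what the values are: raw `"counts"`,
#' `"log2norm"` (log2-scale normalized expression, e.g. log-CPM or log
#' intensities), or `"centered"` (log2-scale values after per-gene median
#' centering). Downstream operations check the tag so that, for example, CPM
#' filtering is only ever applied to raw counts.
#'
#' @param values Numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene ids) and colnames (sample ids).
#' @param units One of `"counts"`, `"log2norm"`, `"centered"`.
#'
#' @return An object of class `expr_matrix`: the matrix with a `units`
#'   attribute.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' em <- expr_matrix(m, "counts")
#' expr_units(em)
#' @export
expr_matrix <- function(values, units = c("counts", "log2norm", "centered")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples).", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have rownames (gene ids) and colnames (sample ids).",
         call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    stop("Duplicate gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop("Duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (units == "counts") {
    if (any(values < 0, na.rm = TRUE)) {
      stop("counts units require all values >= 0.", call. = FALSE)
    }
    if (any(abs(values - round(values)) > 1e-8, na.rm = TRUE)) {
      stop("counts units require integral values.", call. = FALSE)
    }
  }
  structure(values, units = units, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_units <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  attr(x, "units")
}

#' @rdname expr_matrix
#' @export
gene_ids <- function(x) rownames(x)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x)

# Strip class/units so base matrix ops do not carry a stale tag around.
as_bare_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "units") <- NULL
  y
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, units: %s\n",
              nrow(x), ncol(x), expr_units(x)))
  utils::str(as_bare_matrix(x), give.attr = FALSE)
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  y <- as_bare_matrix(x)[i, j, ..., drop = drop]
  if (is.matrix(y)) expr_matrix(y, expr_units(x)) else y
}

#' Convert an expression matrix to / from a tidy tibble
#'
#' `as_tibble()` on an `expr_matrix` returns a long tibble with one row per
#' gene-sample pair; `expr_from_tibble()` reverses the operation.
#'
#' @param x An `expr_matrix`.
#' @param ... Unused, for generic consistency.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(as_bare_matrix(x))
  )
}

#' @rdname as_tibble.expr_matrix
#' @param tbl A long tibble with columns `gene_id`, `sample_id`, `value`.
#' @param units Units tag for the result.
#' @export
expr_from_tibble <- function(tbl, units = "log2norm") {
  wide <- tidyr::pivot_wider(tbl, id_cols = "gene_id",
                             names_from = "sample_id", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  expr_matrix(m, units)
}

#' Read / write an expression matrix as TSV
#'
#' The on-disk format is tab-separated text: first column gene ids (header
#' `gene_id`), remaining columns one per sample with sample ids as the header
#' row. Gene and sample order are preserved exactly as in the file.
#'
#' @param path Path to a TSV file.
#' @param units Units tag to attach to the values (`"counts"`, `"log2norm"`,
#'   `"centered"`); the file itself carries no units.
#' @return `read_expression_matrix()` returns an [expr_matrix];
#'   `write_expression_matrix()` returns `path`, invisibly.
#' @export
read_expression_matrix <- function(path, units = c("counts", "log2norm",
                                                   "centered")) {
  units <- match.arg(units)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) {
    stop("Expression TSV needs a gene-id column plus at least one sample.",
         call. = FALSE)
  }
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("Duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad) > 0) {
      stop(sprintf("Non-numeric value '%s' at row %d (gene %s), column %s of %s",
                   vals[[j]][bad[1]], bad[1], ids[bad[1]], colnames(vals)[j],
                   path), call. = FALSE)
    }
    m[, j] <- v
  }
  expr_matrix(m, units)
}

#' @rdname read_expression_matrix
#' @param x An `expr_matrix` to write.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x), as_bare_matrix(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
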