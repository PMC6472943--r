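#' Read and write gene-set collections (GMT)
#'
#' The GMT dialect is one set per line: set id, description, then one member
#' gene per tab-separated field. Empty lines are skipped; a line with fewer
#' than three fields (no members) is an error.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `description`, and a list-column
#'   `genes` (character vectors of member ids).
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("SETA\tdesc\tG1\tG2", tf)
#' read_gene_sets(tf)
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    bad <- idx[which(n_fields < 3)[1]]
    stop(sprintf("GMT line %d of %s has fewer than 3 fields (no members).",
                 bad, path), call. = FALSE)
  }
  out <- tibble::tibble(
    set_id = vapply(fields, `[[`, "", 1),
    description = vapply(fields, `[[`, "", 2),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
  dup <- unique(out$set_id[duplicated(out$set_id)])
  if (length(dup) > 0) {
    stop("Duplicate set id(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname read_gene_sets
#' @param sets A gene-set tibble (columns `set_id`, `description`, `genes`).
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Declared condition labels and clinical factor levels
#'
#' Unknown/missing clinical values are kept as the explicit level
#' `"unknown"` rather than `NA`, and excluded listwise only where a model
#' requires it (Cox fits).
#' @keywords internal
ternary_levels <- c("+", "-", "unknown")

#' Read a clinical + survival table
#'
#' Reads a delimited per-patient table and maps it onto the package's sample
#' annotation and survival records using an explicit column mapping, so the
#' caller never relies on guessed column names. Survival status strings are
#' mapped to the event indicator with the disease-specific rule: statuses in
#' `event_status` code 1 (disease-specific death / recurrence), statuses in
#' `censor_status` code 0 (alive, or death from other causes); any other
#' status is a hard error.
#'
#' @param path Path to a TSV/CSV file (delimiter inferred from the extension,
#'   or set `sep`).
#' @param mapping A named list (or a path to a YAML/JSON file holding one)
#'   with entries: `sample_id`, `time`, `status` (required column names), and
#'   optionally `condition`, `batch`, `er`, `pr`, `her2`, `grade`,
#'   `tumor_size_mm`, `age_years`, `subtype`; plus `event_status` and
#'   `censor_status`, character vectors of status strings mapping to event = 1
#'   and event = 0 (defaults `"Died of disease"` / `c("Living", "Died of
#'   other causes")`).
#' @param sep Field separator; default inferred (`","` for `.csv` else tab).
#'
#' @return A list with `annotation` (tibble: `sample_id`, `condition`,
#'   `batch`, `er`, `pr`, `her2`, `grade`, `tumor_size_mm`, `age_years`,
#'   `subtype`) and `survival` (tibble: `sample_id`, `time`, `event`).
#' @export
read_clinical_survival <- function(path, mapping, sep = NULL) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- read_config(mapping)
  }
  for (req in c("sample_id", "time", "status")) {
    if (is.null(mapping[[req]])) {
      stop("mapping must name a `", req, "` column.", call. = FALSE)
    }
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  col <- function(key, default = NA) {
    nm <- mapping[[key]]
    if (is.null(nm)) return(rep(default, nrow(df)))
    if (!nm %in% names(df)) {
      stop("Mapped column `", nm, "` (", key, ") not found in ", path,
           call. = FALSE)
    }
    df[[nm]]
  }
  time <- as.numeric(col("time"))
  if (any(is.na(time))) stop("Non-numeric survival time.", call. = FALSE)
  if (any(time < 0)) {
    stop("Negative survival time for sample(s): ",
         paste(col("sample_id")[time < 0], collapse = ", "), call. = FALSE)
  }
  status <- as.character(col("status"))
  event_status <- mapping$event_status %||% "Died of disease"
  censor_status <- mapping$censor_status %||%
    c("Living", "Died of other causes")
  unmapped <- setdiff(unique(status), c(event_status, censor_status))
  if (length(unmapped) > 0) {
    stop("Unmapped survival status value(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  event <- as.integer(status %in% event_status)

  tern <- function(x) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- "unknown"
    x[!x %in% ternary_levels] <- "unknown"
    x
  }
  chr_or_unknown <- function(x) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- "unknown"
    x
  }
  annotation <- tibble::tibble(
    sample_id = as.character(col("sample_id")),
    condition = chr_or_unknown(col("condition", "unknown")),
    batch = chr_or_unknown(col("batch", "unknown")),
    er = tern(col("er", "unknown")),
    pr = tern(col("pr", "unknown")),
    her2 = tern(col("her2", "unknown")),
    grade = chr_or_unknown(col("grade", "unknown")),
    tumor_size_mm = suppressWarnings(as.numeric(col("tumor_size_mm"))),
    age_years = suppressWarnings(as.numeric(col("age_years"))),
    subtype = chr_or_unknown(col("subtype", "unknown"))
  )
  dup <- unique(annotation$sample_id[duplicated(annotation$sample_id)])
  if (length(dup) > 0) {
    stop("Duplicate sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  list(
    annotation = annotation,
    survival = tibble::tibble(sample_id = annotation$sample_id,
                              time = time, event = event)
  )
}

#' Read a YAML or JSON configuration file
#'
#' @param path Path ending in `.yml`/`.yaml` or `.json`.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write a JSON run-metadata sidecar
#'
#' Records the seed, parameters and package version alongside any written
#' artifact so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run (or `NULL`).
#' @param params Named list of parameters.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, seed = NULL, params = list()) {
  meta <- list(
    package = "tamsig",
    version = as.character(utils::packageVersion("tamsig")),
    seed = seed,
    params = params
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
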