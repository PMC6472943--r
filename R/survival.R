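#' Kaplan-Meier survival curve
#'
#' Product-limit estimate over the observed time grid, computed with
#' `survival::survfit()`. With a `group` vector, one curve per group is
#' returned in long form.
#'
#' @param records Tibble with columns `time` (months, non-negative) and
#'   `event` (1 = disease-specific death / recurrence, 0 = censored).
#' @param group Optional grouping vector aligned to `records` (e.g.
#'   "high"/"low" signature expression).
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (and `group` when grouped). The
#'   estimate starts at 1 and is non-increasing within each group.
#' @export
km_curve <- function(records, group = NULL) {
  stopifnot(nrow(records) >= 1, all(records$time >= 0),
            all(records$event %in% c(0, 1)))
  df <- data.frame(time = records$time, event = records$event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, n_censor = fit$n.censor,
                          survival = fit$surv)
  } else {
    df$group <- as.character(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    out <- tibble::tibble(group = strata, time = fit$time,
                          n_risk = fit$n.risk, n_event = fit$n.event,
                          n_censor = fit$n.censor, survival = fit$surv)
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Fits `survival::coxph()` (Efron tie handling by default) on one or more
#' numeric covariates and reports, per covariate, the coefficient, hazard
#' ratio with 95% confidence interval, Wald z and Wald p. Rows with missing
#' covariate values are excluded listwise. Monotone partial likelihood
#' (perfect separation) is flagged in the `flagged` column rather than
#' silently returned.
#'
#' @param records Survival tibble (`time`, `event`); needs at least 1 event
#'   after listwise exclusion.
#' @param covariates Numeric vector, or data frame of numeric columns,
#'   aligned row-wise to `records`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level (default 0.95), normal approximation
#'   on the coefficient.
#' @return A tibble with columns `term`, `beta`, `hr`, `conf.low`,
#'   `conf.high`, `z`, `p.value`, `flagged`, plus attributes `n` and
#'   `n_event`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  if (is.null(dim(covariates))) {
    covariates <- data.frame(x = as.numeric(covariates))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == nrow(records))
  keep <- stats::complete.cases(covariates) & is.finite(records$time)
  df <- cbind(data.frame(.time = records$time[keep],
                         .event = records$event[keep]),
              covariates[keep, , drop = FALSE])
  if (sum(df$.event) < 1) {
    stop("Cox fit needs at least one event.", call. = FALSE)
  }
  terms <- names(covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", terms), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|Loglik", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = terms,
    beta = unname(beta),
    hr = exp(unname(beta)),
    conf.low = exp(unname(beta) - zq * se),
    conf.high = exp(unname(beta) + zq * se),
    z = unname(beta) / se,
    p.value = 2 * stats::pnorm(-abs(unname(beta) / se)),
    flagged = flagged
  )
  attr(out, "n") <- fit$n
  attr(out, "n_event") <- fit$nevent
  out
}

#' Encode clinical annotation as numeric Cox covariates
#'
#' Applies the conventional clinical dichotomizations: ER/PR/Her2 status as
#' 1 (+) / 0 (-) with unknown as `NA`; grade as ordinal 1-3; age
#' dichotomized at 55 years; tumor size dichotomized at 50 mm.
#'
#' @param annotation Annotation tibble (see [read_clinical_survival()]).
#' @param age_cut Age threshold in years (default 55).
#' @param size_cut Tumor-size threshold in mm (default 50).
#' @return A data frame of numeric covariates (`er`, `pr`, `her2`, `grade`,
#'   `age_over_55`, `size_over_50mm`) with `NA` for unknown values.
#' @export
encode_clinical <- function(annotation, age_cut = 55, size_cut = 50) {
  tern_num <- function(x) ifelse(x == "+", 1, ifelse(x == "-", 0, NA_real_))
  grade_num <- c(I = 1, II = 2, III = 3)[annotation$grade]
  data.frame(
    er = tern_num(annotation$er),
    pr = tern_num(annotation$pr),
    her2 = tern_num(annotation$her2),
    grade = unname(grade_num),
    age_over_55 = as.numeric(annotation$age_years > age_cut),
    size_over_50mm = as.numeric(annotation$tumor_size_mm > size_cut)
  )
}

#' Exhaustive optimal-cutpoint dichotomization scan
#'
#' Evaluates every possible expression cutoff: for each of the n-1 midpoints
#' between consecutive distinct sorted score values, samples are
#' dichotomized into high (> cutoff) and low groups, a univariate Cox model
#' is fitted on the indicator, and the p-value and hazard ratio are
#' recorded. The optimal cutoff is the candidate with the smallest p among
#' those where both arms have at least `min_group` samples; ties on p are
#' broken toward the more balanced split. Note that min-p selection over
#' many candidate cutoffs is optimistic under the null: the minimum p is
#' not a valid single-test p-value.
#'
#' By default candidates are ranked by the Cox likelihood-ratio p, which
#' stays well defined (the partial likelihood has a finite supremum) when a
#' split separates survival perfectly; the Wald p degenerates toward 1
#' under such monotone likelihoods, which would make min-p ranking
#' meaningless precisely at the strongest splits. `p_method = "score"`
#' (the log-rank test for a binary split) and `"wald"` are available.
#'
#' @param score Numeric per-sample score aligned to `records`; needs at
#'   least 2 distinct values.
#' @param records Survival tibble (`time`, `event`).
#' @param min_group Minimum samples per arm for a candidate to be eligible
#'   as the optimum (default 1, i.e. every possible cutoff).
#' @param ties Cox tie handling, passed to [cox_fit()].
#' @param p_method `"lrt"` (default), `"score"`, or `"wald"`.
#' @return An object of class `cutoff_scan`: list with `candidates` (tibble:
#'   `cutoff`, `n_low`, `n_high`, `hr`, `p`), `optimal_cutoff`, `optimal_p`,
#'   `optimal_hr`, and `significant` (cutoffs with p < 0.05).
#' @export
optimal_cutoff_scan <- function(score, records, min_group = 1,
                                ties = "efron",
                                p_method = c("lrt", "score", "wald")) {
  p_method <- match.arg(p_method)
  stopifnot(length(score) == nrow(records))
  vals <- sort(unique(score))
  if (length(vals) < 2) {
    stop("All scores identical: no possible cutoff.", call. = FALSE)
  }
  df0 <- data.frame(.time = records$time, .event = records$event)
  cuts <- (vals[-length(vals)] + vals[-1]) / 2
  rows <- lapply(cuts, function(cut) {
    high <- as.numeric(score > cut)
    fit <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(.time, .event) ~ high,
                      data = cbind(df0, high = high), ties = ties)),
      error = function(e) NULL)
    p <- if (is.null(fit)) NA_real_ else switch(
      p_method,
      lrt = stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]), df = 1,
                          lower.tail = FALSE),
      score = stats::pchisq(fit$score, df = 1, lower.tail = FALSE),
      wald = 2 * stats::pnorm(-abs(stats::coef(fit) / sqrt(diag(fit$var))))
    )
    tibble::tibble(
      cutoff = cut, n_low = sum(high == 0), n_high = sum(high == 1),
      hr = if (is.null(fit)) NA_real_ else unname(exp(stats::coef(fit))),
      p = unname(p)
    )
  })
  candidates <- dplyr::bind_rows(rows)
  eligible <- candidates[!is.na(candidates$p) &
                           pmin(candidates$n_low,
                                candidates$n_high) >= min_group, ]
  if (nrow(eligible) == 0) {
    stop("No eligible cutoff (min_group too large or all fits failed).",
         call. = FALSE)
  }
  # argmin p; ties toward the more balanced split
  best <- eligible[order(eligible$p,
                         abs(eligible$n_high - eligible$n_low)), ][1, ]
  structure(list(
    candidates = candidates,
    optimal_cutoff = best$cutoff,
    optimal_p = best$p,
    optimal_hr = best$hr,
    significant = candidates$cutoff[!is.na(candidates$p) &
                                      candidates$p < 0.05]
  ), class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf(
    "<cutoff_scan> %d candidate cutoffs, optimal %.4g (HR %.3f, p %.3g), %d significant\n",
    nrow(x$candidates), x$optimal_cutoff, x$optimal_hr, x$optimal_p,
    length(x$significant)))
  invisible(x)
}

#' @rdname optimal_cutoff_scan
#' @param x A `cutoff_scan`.
#' @param ... Unused.
#' @export
tidy.cutoff_scan <- function(x, ...) x$candidates

#' @rdname optimal_cutoff_scan
#' @export
glance.cutoff_scan <- function(x, ...) {
  tibble::tibble(optimal_cutoff = x$optimal_cutoff, hr = x$optimal_hr,
                 p.value = x$optimal_p,
                 n_candidates = nrow(x$candidates),
                 n_significant = length(x$significant))
}

#' Two-gene summed-expression cutpoint scan
#'
#' Builds a combined score for a gene pair as the sum of the two per-gene
#' normalized expression values (per-gene z-scores by default) and runs the
#' exhaustive cutpoint scan on it.
#'
#' @param expr An [expr_matrix] containing both genes.
#' @param genes Character vector of exactly two gene ids.
#' @param records Survival tibble aligned to the matrix columns.
#' @param normalize `"zscore"` (default), `"center"` (median-centered), or
#'   `"none"`, applied per gene before summing.
#' @param min_group,ties Passed to [optimal_cutoff_scan()].
#' @return A `cutoff_scan` (see [optimal_cutoff_scan()]); the combined score
#'   is attached as attribute `score`.
#' @export
two_gene_dichotomize <- function(expr, genes, records,
                                 normalize = c("zscore", "center", "none"),
                                 min_group = 1, ties = "efron") {
  normalize <- match.arg(normalize)
  stopifnot(inherits(expr, "expr_matrix"), length(genes) == 2)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    stop("Gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(ncol(expr) == nrow(records))
  norm_row <- function(x) {
    switch(normalize,
           zscore = if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                    else x - mean(x),
           center = x - stats::median(x),
           none = x)
  }
  m <- as_bare_matrix(expr[genes, , drop = FALSE])
  score <- norm_row(m[1, ]) + norm_row(m[2, ])
  out <- optimal_cutoff_scan(score, records, min_group = min_group,
                             ties = ties)
  attr(out, "score") <- score
  out
}

#' Univariate screening followed by a multivariate Cox model
#'
#' Fits one univariate Cox model per covariate; covariates with a Wald p
#' strictly below `threshold` are carried into a single joint multivariate
#' fit. If none passes, the multivariate table is empty (with a warning).
#'
#' @param records Survival tibble (`time`, `event`).
#' @param covariates Data frame of numeric covariates aligned to `records`.
#' @param threshold Univariate inclusion threshold on the Wald p
#'   (default 0.05).
#' @param ties Cox tie handling.
#' @return A list with `univariate` (tibble of per-covariate fits),
#'   `selected` (character vector), `multivariate` (tibble of the joint
#'   fit, empty if nothing passed).
#' @export
multivariate_selection <- function(records, covariates, threshold = 0.05,
                                   ties = "efron") {
  covariates <- as.data.frame(covariates)
  uni <- dplyr::bind_rows(lapply(names(covariates), function(nm) {
    cox_fit(records, covariates[, nm, drop = FALSE], ties = ties)
  }))
  selected <- uni$term[uni$p.value < threshold]
  if (length(selected) == 0) {
    warning("No covariate passed the univariate threshold; empty ",
            "multivariate model.", call. = FALSE)
    multi <- uni[0, ]
  } else {
    multi <- cox_fit(records, covariates[, selected, drop = FALSE],
                     ties = ties)
  }
  list(univariate = uni, selected = selected, multivariate = multi)
}
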