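#' Empirical-Bayes moderated two-group t-test
#'
#' Per gene, computes the pooled two-sample residual variance and shrinks it
#' toward an empirical-Bayes prior before forming the t statistic:
#' the prior degrees of freedom `d0` and prior variance `s0^2` are estimated
#' by method of moments on the log residual variances (the closed-form
#' log-normal/F moment match), the shrunken variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)`, and the moderated t is the log2 fold
#' change over its shrunken standard error with `d0 + d` total degrees of
#' freedom. Genes with zero residual variance get finite statistics through
#' the shrinkage. Fold change is the difference of group means on the log2
#' scale (group 2 minus group 1).
#'
#' When the estimated `d0` is infinite (log-variances underdispersed relative
#' to the sampling distribution), it is capped at `10 * d` so the result
#' stays finite while behaving as full shrinkage.
#'
#' @param expr An [expr_matrix] with log2norm units.
#' @param groups Two-level factor/character vector aligned to samples; the
#'   second level is the "treatment" (fold change is level2 - level1, levels
#'   in first-appearance order unless `groups` is a factor).
#' @param d0 Optional prior degrees-of-freedom override: `0` gives the
#'   ordinary pooled t, `Inf` full shrinkage to the prior variance
#'   (internally capped). `NULL` (default) estimates it from the data.
#' @return A tibble with columns `gene_id`, `log2fc`, `t_mod`, `df_total`,
#'   `p_raw`, `fdr`, sorted in input gene order; attributes `d0` and `s0_sq`
#'   carry the prior.
#' @export
fit_moderated_t <- function(expr, groups, d0 = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) != 2) {
    stop("groups must have exactly two levels.", call. = FALSE)
  }
  if (length(groups) != ncol(expr)) {
    stop("One group label per sample is required.", call. = FALSE)
  }
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) {
    stop("Each group needs at least 2 samples.", call. = FALSE)
  }
  m <- as_bare_matrix(expr)
  g1 <- m[, groups == levels(groups)[1], drop = FALSE]
  g2 <- m[, groups == levels(groups)[2], drop = FALSE]
  mean1 <- rowMeans(g1); mean2 <- rowMeans(g2)
  log2fc <- mean2 - mean1
  ss <- rowSums((g1 - mean1)^2) + rowSums((g2 - mean2)^2)
  d <- n1 + n2 - 2
  s2 <- ss / d

  if (is.null(d0)) {
    prior <- estimate_variance_prior(s2, d)
  } else {
    stopifnot(d0 >= 0)
    est <- estimate_variance_prior(s2, d)
    prior <- list(d0 = d0, s0_sq = est$s0_sq)
  }
  d0_use <- min(prior$d0, 10 * d)        # finite stand-in for d0 = Inf
  s2_tilde <- (d0_use * prior$s0_sq + d * s2) / (d0_use + d)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, log2fc / se, 0)
  df_total <- d0_use + d
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- tibble::tibble(
    gene_id = rownames(m), log2fc = unname(log2fc), t_mod = unname(t_mod),
    df_total = df_total, p_raw = unname(p_raw),
    fdr = unname(bh_adjust(p_raw))
  )
  attr(out, "d0") <- prior$d0
  attr(out, "s0_sq") <- prior$s0_sq
  out
}

# Method-of-moments estimate of the scaled inverse-chi-square prior on gene
# variances, from the mean and excess variance of log(s^2) (closed form on
# the log scale; genes with s^2 = 0 are excluded from moment estimation but
# still shrunk).
estimate_variance_prior <- function(s2, d) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2) {
    return(list(d0 = Inf, s0_sq = if (length(z)) exp(mean(z)) else 1e-8))
  }
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton iteration for the inverse of trigamma on (0, Inf).
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values by the BH step-up rule (sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in input
#' order). Delegates to `stats::p.adjust(method = "BH")` after validating the
#' input range.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Applies the FDR and fold-change gates: up-regulated genes need
#' `fdr <= max_fdr` and `log2fc >= min_up_log2fc`; down-regulated genes need
#' `fdr <= max_fdr` and `log2fc <= max_down_log2fc`. The two lists are
#' disjoint by construction.
#'
#' @param de A differential-expression tibble from [fit_moderated_t()].
#' @param max_fdr FDR gate (default 0.05).
#' @param min_up_log2fc Minimum log2 fold change for up-regulation
#'   (default 1.5).
#' @param max_down_log2fc Maximum log2 fold change for down-regulation
#'   (default -1.5).
#' @return A list with character vectors `up` and `down`.
#' @export
select_degs <- function(de, max_fdr = 0.05, min_up_log2fc = 1.5,
                        max_down_log2fc = -1.5) {
  stopifnot(max_fdr > 0, max_fdr < 1, min_up_log2fc > 0, max_down_log2fc < 0)
  list(
    up = de$gene_id[de$fdr <= max_fdr & de$log2fc >= min_up_log2fc],
    down = de$gene_id[de$fdr <= max_fdr & de$log2fc <= max_down_log2fc]
  )
}
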