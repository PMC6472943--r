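# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written from first principles (enumeration,
# direct likelihood maximization) so it checks the package implementation
# without sharing code with it.

make_expr <- function(values, units = "log2norm",
                      genes = sprintf("g%02d", seq_len(nrow(values))),
                      samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, units)
}

# Ordinary pooled two-sample t on one gene.
pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  tt <- (mean(x2) - mean(x1)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n1 + n2 - 2))
}

# Efron partial log-likelihood for a single numeric covariate.
efron_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sw_R <- sum(w[R]); sw_D <- sum(w[D])
    ll <- ll + sum(eta[D]) -
      sum(log(sw_R - (seq_len(d) - 1) / d * sw_D))
  }
  ll
}

# Independent Cox fit: maximize the Efron partial likelihood on a grid +
# golden-section, standard error from a central second difference.
oracle_cox <- function(time, event, x) {
  opt <- stats::optimize(function(b) efron_loglik(b, time, event, x),
                         interval = c(-15, 15), maximum = TRUE,
                         tol = 1e-10)
  beta <- opt$maximum
  h <- 1e-4
  info <- -(efron_loglik(beta + h, time, event, x) -
              2 * opt$objective +
              efron_loglik(beta - h, time, event, x)) / h^2
  se <- 1 / sqrt(info)
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Likelihood-ratio test from the Efron partial likelihood, maximized
# directly (the supremum is finite even under complete separation).
oracle_lrt <- function(time, event, x) {
  l0 <- efron_loglik(0, time, event, x)
  lhat <- stats::optimize(function(b) efron_loglik(b, time, event, x),
                          interval = c(-25, 25), maximum = TRUE,
                          tol = 1e-10)$objective
  stats::pchisq(2 * (lhat - l0), df = 1, lower.tail = FALSE)
}

# Brute-force re-scan of every possible cutoff with the oracle LR test.
oracle_cutoff_scan <- function(score, time, event, min_group = 1) {
  vals <- sort(unique(score))
  cuts <- (vals[-length(vals)] + vals[-1]) / 2
  res <- lapply(cuts, function(cut) {
    high <- as.numeric(score > cut)
    data.frame(cutoff = cut, n_low = sum(high == 0),
               n_high = sum(high == 1),
               p = oracle_lrt(time, event, high))
  })
  res <- do.call(rbind, res)
  eligible <- res[pmin(res$n_low, res$n_high) >= min_group, ]
  best <- eligible[order(eligible$p, abs(eligible$n_high - eligible$n_low)), ][1, ]
  list(candidates = res, optimal_cutoff = best$cutoff, optimal_p = best$p)
}

# AUC by exhaustive pair enumeration, ties counted one half.
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  pairs <- expand.grid(p = pos, n = neg)
  mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
}

# Constructed signature fixture: 40 planted module genes that pass all five
# gates, and 10 decoys engineered to fail exactly one gate each.
make_signature_fixture <- function(seed = 42, n_samples = 100) {
  withr::local_seed(seed)
  planted <- sprintf("SIG%02d", 1:40)
  decoys <- c(de_fc = "DEC_FC", de_fdr = "DEC_FDR",
              comp1 = "DEC_COMP1", comp2 = "DEC_COMP2",
              coex1 = "DEC_COEX1", coex2 = "DEC_COEX2",
              anch1 = "DEC_ANCH1", anch2 = "DEC_ANCH2",
              cell1 = "DEC_CELL1", cell2 = "DEC_CELL2")
  anchor <- "ANCHOR"
  genes <- c(planted, unname(decoys), anchor)

  de <- tibble::tibble(
    gene_id = genes,
    log2fc = ifelse(genes == "DEC_FC", 2,
                    ifelse(genes == anchor, 0.5, 4)),
    fdr = ifelse(genes == "DEC_FDR", 0.2, 0.01)
  )

  compendium <- tibble::tibble(
    set_id = c("MACROPHAGES", "IMMUNE_T"),
    description = c("macrophage lineage", "other immune cell type"),
    genes = list(c(planted[1:5], anchor), c("DEC_COMP1", "DEC_COMP2"))
  )

  n <- n_samples
  f_main <- stats::rnorm(n)        # module factor (planted + anchor + cell decoys)
  f_side <- stats::rnorm(n)        # factor shared only by the anchor decoys
  lam <- sqrt(1.5)                 # expected pairwise r = 0.6
  expr <- matrix(stats::rnorm(length(genes) * n, sd = 1),
                 nrow = length(genes), dimnames = list(genes, NULL))
  on_main <- c(planted, "DEC_CELL1", "DEC_CELL2", anchor)
  expr[on_main, ] <- expr[on_main, ] +
    lam * matrix(rep(f_main, each = length(on_main)), nrow = length(on_main))
  on_side <- c("DEC_ANCH1", "DEC_ANCH2")
  expr[on_side, ] <- expr[on_side, ] +
    2 * matrix(rep(f_side, each = 2), nrow = 2)
  # the stage-1/2 decoys must survive later gates if reached: put them on the
  # main factor too, so only their designed gate removes them
  on_main2 <- c("DEC_FC", "DEC_FDR", "DEC_COMP1", "DEC_COMP2")
  expr[on_main2, ] <- expr[on_main2, ] +
    lam * matrix(rep(f_main, each = 4), nrow = 4)
  colnames(expr) <- sprintf("p%03d", seq_len(n))
  tumor_expr <- expr_matrix(expr + 8, "log2norm")

  cl <- matrix(stats::rnorm(length(genes) * 20, mean = 2),
               nrow = length(genes),
               dimnames = list(genes, sprintf("cl%02d", 1:20)))
  cl[c("DEC_CELL1", "DEC_CELL2"), ] <- cl[c("DEC_CELL1", "DEC_CELL2"), ] + 7
  celllines <- expr_matrix(cl, "log2norm")

  list(de = de, compendium = compendium, tumor_expr = tumor_expr,
       celllines = celllines, planted = planted, anchor = anchor,
       config = signature_config(anchor_gene = anchor))
}
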