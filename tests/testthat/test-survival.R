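test_that("Kaplan-Meier estimate matches the hand product-limit values", {
  rec <- tibble::tibble(time = c(5, 10, 15), event = c(1, 1, 0))
  km <- km_curve(rec)
  expect_equal(km$survival[km$time == 5], 2 / 3)
  expect_equal(km$survival[km$time == 10], 1 / 3)
  expect_equal(km$survival[km$time == 15], 1 / 3)   # flat after censoring
  expect_true(all(diff(km$survival) <= 0))
})

test_that("Kaplan-Meier degenerate cases behave as declared", {
  all_cens <- tibble::tibble(time = c(3, 7, 9), event = c(0, 0, 0))
  expect_true(all(km_curve(all_cens)$survival == 1))
  rec <- tibble::tibble(time = c(5, 10, 15), event = c(1, 1, 0))
  doubled <- rec[rep(1:3, each = 2), ]
  expect_equal(km_curve(doubled)$survival, km_curve(rec)$survival)
  # no-censoring case equals the empirical survivor function
  rec2 <- tibble::tibble(time = c(2, 4, 6, 8), event = 1)
  km2 <- km_curve(rec2)
  expect_equal(km2$survival, c(0.75, 0.5, 0.25, 0))
})

test_that("Cox fit reproduces the analytic three-record toy example", {
  rec <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1))
  fit <- cox_fit(rec, c(1, 0, 1))
  expect_equal(fit$beta, -0.5 * log(2), tolerance = 1e-6)
  expect_equal(fit$hr, 2^(-0.5), tolerance = 1e-6)
  expect_true(fit$conf.low <= fit$hr && fit$hr <= fit$conf.high)
})

test_that("Cox fit agrees with the independent partial-likelihood oracle", {
  withr::local_seed(31)
  for (i in 1:4) {
    n <- 25
    tm <- round(rexp(n, 0.1), 1)          # induce some ties
    ev <- rbinom(n, 1, 0.7)
    x <- rnorm(n)
    if (sum(ev) == 0) next
    fit <- cox_fit(tibble::tibble(time = tm, event = ev), x)
    o <- oracle_cox(tm, ev, x)
    expect_equal(fit$beta, o$beta, tolerance = 1e-5)
    expect_equal(fit$p.value, o$p, tolerance = 1e-4)
  }
})

test_that("Cox fit flags degenerate inputs instead of failing silently", {
  rec <- tibble::tibble(time = 1:6, event = rep(1, 6))
  expect_error(cox_fit(tibble::tibble(time = 1:3, event = c(0, 0, 0)),
                       c(1, 0, 1)), "one event")
  # perfect separation: covariate orders survival exactly
  sep <- cox_fit(rec, c(1, 1, 1, 0, 0, 0))
  expect_true(sep$flagged)
  # null covariate at large n: HR near 1
  withr::local_seed(32)
  n <- 500
  fit0 <- cox_fit(tibble::tibble(time = rexp(n, 0.01),
                                 event = rbinom(n, 1, 0.5)), rnorm(n))
  expect_equal(fit0$hr, 1, tolerance = 0.25)
})

test_that("the cutpoint scan places the optimum between the designed
           groups", {
  rec <- tibble::tibble(time = c(10, 9, 2, 1), event = rep(1, 4))
  scan <- optimal_cutoff_scan(c(1, 2, 3, 4), rec)
  expect_gt(scan$optimal_cutoff, 2)
  expect_lt(scan$optimal_cutoff, 3)
  expect_equal(scan$optimal_p, min(scan$candidates$p, na.rm = TRUE))
  expect_equal(nrow(scan$candidates), 3)     # n - 1 possible cutoffs
  expect_true(all(scan$significant %in% scan$candidates$cutoff))
})

test_that("the scan equals an independent brute-force re-scan on small
           instances", {
  withr::local_seed(33)
  for (i in 1:4) {
    n <- sample(10:30, 1)
    sc <- rnorm(n)
    rec <- tibble::tibble(time = round(rexp(n, 0.05), 1),
                          event = rbinom(n, 1, 0.7))
    if (sum(rec$event) < 2) next
    mine <- optimal_cutoff_scan(sc, rec, min_group = 2)
    oracle <- oracle_cutoff_scan(sc, rec$time, rec$event, min_group = 2)
    expect_equal(mine$optimal_cutoff, oracle$optimal_cutoff)
    expect_equal(mine$optimal_p, oracle$optimal_p, tolerance = 1e-4)
    expect_equal(mine$candidates$p, oracle$candidates$p, tolerance = 1e-4)
  }
})

test_that("the scan rejects constant scores and respects min_group", {
  rec <- tibble::tibble(time = 1:4, event = rep(1, 4))
  expect_error(optimal_cutoff_scan(rep(2, 4), rec), "identical")
  scan <- optimal_cutoff_scan(c(1, 2, 3, 4), rec, min_group = 2)
  best_row <- scan$candidates[scan$candidates$cutoff == scan$optimal_cutoff, ]
  expect_gte(min(best_row$n_low, best_row$n_high), 2)
})

test_that("the two-gene score is linear: duplicated genes equal a single
           scaled scan", {
  withr::local_seed(34)
  n <- 30
  g <- rnorm(n, 8)
  m <- rbind(g1 = g, g2 = g, g3 = rnorm(n, 8))
  colnames(m) <- sprintf("p%02d", 1:n)
  em <- expr_matrix(m, "log2norm")
  rec <- tibble::tibble(time = rexp(n, 0.05), event = rbinom(n, 1, 0.8))
  two <- two_gene_dichotomize(em, c("g1", "g2"), rec)
  single <- optimal_cutoff_scan(2 * g, rec)
  # dichotomization depends only on score order, identical for both
  expect_equal(two$candidates$p, single$candidates$p, tolerance = 1e-10)
  expect_error(two_gene_dichotomize(em, c("g1", "missing"), rec), "missing")
  cm2 <- rbind(a = rep(1, n), b = rep(2, n))
  colnames(cm2) <- colnames(m)
  const <- expr_matrix(cm2, "log2norm")
  expect_error(two_gene_dichotomize(const, c("a", "b"), rec), "identical")
})

test_that("two-gene dichotomization splits in the direction of the planted
           hazard", {
  cfg <- sim_config(seed = 35, n_genes = 30, n_signal_genes = 2,
                    n_patients = 250, cox_beta = log(2.5))
  tum <- simulate_tumor_cohort(cfg, c("G0001", "G0002"))
  res <- two_gene_dichotomize(tum$expr, c("G0001", "G0002"), tum$survival,
                              min_group = 25)
  expect_gt(res$optimal_hr, 1)            # high expression is the risk group
  expect_lt(res$optimal_p, 0.05)
})

test_that("univariate screening feeds exactly the passing covariates into
           the joint model", {
  withr::local_seed(36)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n); junk <- rnorm(n)
  rate <- 0.01 * exp(0.8 * x1 + 0.8 * x2)
  rec <- tibble::tibble(time = rexp(n, rate), event = rbinom(n, 1, 0.8))
  covs <- data.frame(x1 = x1, x2 = x2, junk = junk)
  res <- multivariate_selection(rec, covs)
  expect_setequal(res$selected, c("x1", "x2"))
  expect_false("junk" %in% res$multivariate$term)
  # the joint fit recovers the simulated per-covariate hazard ratio
  # (univariate HRs attenuate under omitted covariates: non-collapsibility)
  mult_hr <- res$multivariate$hr[match(c("x1", "x2"), res$multivariate$term)]
  expect_equal(mult_hr, rep(exp(0.8), 2), tolerance = 0.15)
  uni_hr <- res$univariate$hr[match(c("x1", "x2"), res$univariate$term)]
  expect_true(all(uni_hr > 1.5))
  # single passing covariate: joint model equals its univariate model
  res1 <- multivariate_selection(rec, covs[, "x1", drop = FALSE])
  expect_equal(res1$multivariate$beta,
               res1$univariate$beta[res1$univariate$term == "x1"])
  # nothing passes: empty model with a warning
  rec0 <- tibble::tibble(time = rexp(n, 0.01), event = rbinom(n, 1, 0.5))
  expect_warning(res0 <- multivariate_selection(rec0,
                                                data.frame(junk = junk)),
                 "No covariate")
  expect_equal(nrow(res0$multivariate), 0)
})

test_that("clinical covariates encode with the conventional
           dichotomizations", {
  ann <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    condition = "tumor", batch = "b1",
    er = c("+", "-", "unknown"), pr = c("-", "-", "+"),
    her2 = c("+", "unknown", "-"),
    grade = c("I", "III", "II"),
    tumor_size_mm = c(60, 30, 50), age_years = c(70, 54, 56),
    subtype = "unknown")
  enc <- encode_clinical(ann)
  expect_equal(enc$er, c(1, 0, NA))
  expect_equal(enc$grade, c(1, 3, 2))
  expect_equal(enc$age_over_55, c(1, 0, 1))
  expect_equal(enc$size_over_50mm, c(1, 0, 0))
})
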