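test_that("CPM filter retains exactly the genes clearing the gate", {
  # gene1 has CPM (1000, 0, 0, 0) at library size 10,000 per sample
  m <- rbind(g1 = c(10, 0, 0, 0),
             g2 = c(9990, 10000, 10000, 10000))
  colnames(m) <- paste0("s", 1:4)
  em <- expr_matrix(m, "counts")
  expect_identical(rownames(filter_low_expression(em, 1, 1)), c("g1", "g2"))
  expect_identical(rownames(filter_low_expression(em, 1, 2)), "g2")
  # all-zero gene removed for any params
  m2 <- rbind(m, g0 = c(0, 0, 0, 0))
  expect_false("g0" %in%
                 rownames(filter_low_expression(expr_matrix(m2, "counts"),
                                                1, 1)))
})

test_that("CPM filter is the identity on strictly positive counts at a
           vacuously low gate", {
  withr::local_seed(2)
  m <- matrix(rpois(40, 50) + 1L, 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  em <- expr_matrix(m, "counts")
  expect_identical(filter_low_expression(em, 1e-9, 1), em)
})

test_that("CPM filter errors on a zero library and is monotone in params", {
  m <- cbind(s1 = c(1L, 2L), s2 = c(0L, 0L))
  rownames(m) <- c("a", "b")
  expect_error(filter_low_expression(expr_matrix(m, "counts")), "s2")
  withr::local_seed(3)
  big <- matrix(rnbinom(2000, mu = 20, size = 5), 200,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:10)))
  em <- expr_matrix(big, "counts")
  strict <- rownames(filter_low_expression(em, 5, 5))
  loose_cpm <- rownames(filter_low_expression(em, 2, 5))
  loose_n <- rownames(filter_low_expression(em, 5, 2))
  expect_true(all(strict %in% loose_cpm))
  expect_true(all(strict %in% loose_n))
})

test_that("TMM factors are 1 for proportional columns and geomean-1 always", {
  withr::local_seed(4)
  base <- rpois(300, 60)
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- sprintf("g%03d", seq_along(base))
  f <- normalization_factors(expr_matrix(m, "counts"))
  expect_equal(f$factor, c(1, 1))
  m2 <- cbind(s1 = base, s2 = base * 2L)
  rownames(m2) <- rownames(m)
  f2 <- normalization_factors(expr_matrix(m2, "counts"))
  expect_equal(f2$factor, c(1, 1))
  m3 <- matrix(rpois(300 * 6, 40), 300,
               dimnames = list(rownames(m), paste0("s", 1:6)))
  for (method in c("TMM", "upperquartile")) {
    f3 <- normalization_factors(expr_matrix(m3, "counts"), method)
    expect_equal(exp(mean(log(f3$factor))), 1, tolerance = 1e-8)
  }
})

test_that("normalization factors are permutation-equivariant in samples", {
  withr::local_seed(5)
  m <- matrix(rnbinom(300 * 5, mu = 30, size = 10), 300,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:5)))
  em <- expr_matrix(m, "counts")
  perm <- c(4, 2, 5, 1, 3)
  f <- normalization_factors(em)
  fp <- normalization_factors(em[, perm])
  expect_equal(fp$factor, f$factor[perm])
  expect_error(normalization_factors(
    expr_matrix(cbind(m, s6 = rep(0L, 300)), "counts")), "s6")
})

test_that("log-CPM matches the stated formula by hand", {
  m <- matrix(c(0L, 999L, 999001L), ncol = 1,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  le <- log_cpm(expr_matrix(m, "counts"), prior = 0.5)  # library = 1e6
  expect_equal(le["g1", "s1", drop = TRUE], log2(0.5))  # = -1
  expect_equal(le["g2", "s1", drop = TRUE], log2(999.5))  # ~ 9.966
  expect_equal(le["g1", "s1", drop = TRUE], -1)
  expect_error(log_cpm(expr_matrix(m, "counts"), prior = 0), "prior")
})

test_that("log-CPM is scale-invariant and strictly increasing in count", {
  withr::local_seed(6)
  m <- matrix(rpois(50, 1000) + 100L, 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  em <- expr_matrix(m, "counts")
  doubled <- expr_matrix(m * 2L, "counts")
  expect_equal(unclass(log_cpm(em)), unclass(log_cpm(doubled)),
               tolerance = 1e-3, ignore_attr = TRUE)
  # strictly increasing: bump one count
  m2 <- m; m2[3, 2] <- m2[3, 2] + 1L
  le <- log_cpm(em); le2 <- log_cpm(expr_matrix(m2, "counts"))
  expect_gt(le2[3, 2], le[3, 2])
})

test_that("median centering matches hand arithmetic and is idempotent", {
  em <- make_expr(rbind(c(1, 2, 4), c(7, 7, 7)))
  ct <- median_center(em)
  expect_equal(unname(unclass(ct)[1, ]), c(-1, 0, 2))
  expect_equal(unname(unclass(ct)[2, ]), c(0, 0, 0))
  expect_equal(unclass(median_center(ct)), unclass(ct),
               ignore_attr = TRUE)
  expect_identical(expr_units(ct), "centered")
})

test_that("batch adjustment removes a planted location shift", {
  withr::local_seed(7)
  ng <- 1000; n <- 40
  batch <- rep(c("b1", "b2"), each = n / 2)
  delta <- 2
  m <- matrix(rnorm(ng * n, mean = 6), ng,
              dimnames = list(sprintf("g%04d", 1:ng), paste0("s", 1:n)))
  m[, batch == "b2"] <- m[, batch == "b2"] + delta
  adj <- batch_adjust(expr_matrix(m, "log2norm"), batch)
  diff_post <- rowMeans(unclass(adj)[, batch == "b2"]) -
    rowMeans(unclass(adj)[, batch == "b1"])
  # the systematic component of the shift is gone ...
  expect_lt(abs(mean(diff_post)), 0.05 * delta)
  # ... and per-gene batch differences collapse to sampling noise
  expect_lt(mean(abs(diff_post)), 0.15 * delta)
})

test_that("batch adjustment equalizes a planted scale difference", {
  withr::local_seed(8)
  ng <- 1000; n <- 40
  batch <- rep(c("b1", "b2"), each = n / 2)
  m <- matrix(rnorm(ng * n, mean = 6), ng,
              dimnames = list(sprintf("g%04d", 1:ng), paste0("s", 1:n)))
  m[, batch == "b2"] <- 6 + (m[, batch == "b2"] - 6) * 2
  adj <- batch_adjust(expr_matrix(m, "log2norm"), batch)
  v1 <- mean(apply(unclass(adj)[, batch == "b1"], 1, stats::var))
  v2 <- mean(apply(unclass(adj)[, batch == "b2"], 1, stats::var))
  expect_equal(v2 / v1, 1, tolerance = 0.1)
})

test_that("batch adjustment degenerate cases behave as declared", {
  em <- make_expr(matrix(rnorm(20, 5), 4))
  expect_identical(batch_adjust(em, rep("b1", 5)), em)
  expect_error(batch_adjust(em, c("b1", "b1", "b1", "b1", "b2")), "b2")
})
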