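test_that("permutation tests behave at the extremes and enumerate exactly", {
  a <- c(1.2, 0.8, 1.1, 0.9, 1.0)
  p_same <- permutation_test(a, a, n_perm = 1000, seed = 1)$p
  expect_gt(p_same, 0.5)
  # exhaustive enumeration at n = 5 per group equals the brute-force oracle
  set.seed(2)
  b <- rnorm(5, 1.5, 0.3)
  ex <- permutation_test(a, b, exact = TRUE)
  expect_equal(ex$p, oracle_exact_perm_p(a, b))
  expect_identical(ex$n_permutations, 252L)
  # Monte-Carlo approximates the exhaustive answer
  mc <- permutation_test(a, b, n_perm = 20000, seed = 3)
  expect_equal(mc$p, ex$p, tolerance = 0.02)
  expect_gte(mc$p, 1 / 20001)
  # paired flavour: a strong consistent difference is detected
  d1 <- 1:8; d2 <- d1 + 2
  expect_lt(permutation_test(d2, d1, paired = TRUE, n_perm = 1000,
                             seed = 4)$p, 0.05)
  expect_error(permutation_test(numeric(0), a), "empty")
  expect_error(permutation_test(a, b[1:4], paired = TRUE, n_perm = 1000),
               "equal length")
})

test_that("permutation test type-I error is calibrated", {
  # 400 null replicates at 499 permutations each (cheap but valid p-values)
  set.seed(5)
  rej <- vapply(1:400, function(r) {
    x <- rnorm(12); y <- rnorm(12)
    permutation_test(x, y, n_perm = 1000, seed = r)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("adaptive FDR rejects sensibly and controls the error rate", {
  expect_false(any(fdr_adaptive(rep(1, 10))$mask))
  expect_true(fdr_adaptive(0.01)$mask)
  expect_error(fdr_adaptive(c(0.1, 0)), "p-values")
  # rejections are a superset of the first-stage step-up
  set.seed(6)
  for (i in 1:20) {
    p <- c(runif(15), runif(5)^4)
    f <- fdr_adaptive(p, 0.05)
    bh1 <- motorhgf:::bh_mask(p, 0.05 / 1.05)
    expect_true(all(f$mask[bh1]))
    expect_equal(f$threshold, if (any(f$mask)) max(p[f$mask]) else 0)
  }
  # mixture calibration: 80% null, 20% strong alternatives
  set.seed(7)
  fdp <- vapply(1:1000, function(r) {
    is_null <- c(rep(TRUE, 16), rep(FALSE, 4))
    p <- c(runif(16), rbeta(4, 0.05, 1))
    f <- fdr_adaptive(p, 0.05)
    if (!any(f$mask)) 0 else sum(f$mask & is_null) / sum(f$mask)
  }, numeric(1))
  expect_lte(mean(fdp), 0.055)
})

test_that("probability-of-superiority matches the double-loop oracle", {
  a <- c(3, 5, 7, 7, 9)
  b <- c(1, 5, 6, 8)
  es <- effect_size_delta(a, b, n_boot = 500, seed = 1)
  expect_equal(es$delta, oracle_delta(a, b))
  expect_identical(es$n_ties, 1L)
  expect_true(es$ci95[1] <= es$delta && es$delta <= es$ci95[2])
  # all of a above all of b
  expect_equal(effect_size_delta(10:12, 1:3, n_boot = 200,
                                 seed = 1)$delta, 1)
  # iid samples sit near 1/2
  set.seed(8)
  x <- rnorm(300); y <- rnorm(300)
  expect_equal(effect_size_delta(x, y, n_boot = 200, seed = 2)$delta, 0.5,
               tolerance = 0.08)
  # dependent version counts paired wins with tie correction
  aa <- c(2, 3, 4, 4, 6); bb <- c(1, 4, 4, 4, 5)
  dep <- effect_size_delta(aa, bb, dependent = TRUE, n_boot = 200, seed = 3)
  expect_equal(dep$delta, 2 / 3)  # two ties removed from the denominator
  expect_error(effect_size_delta(c(1, 1), c(1, 1), dependent = TRUE),
               "tied")
  # invariance under strictly monotone transforms
  expect_equal(effect_size_delta(exp(x), exp(y), n_boot = 10,
                                 seed = 4)$delta,
               effect_size_delta(x, y, n_boot = 10, seed = 4)$delta)
})

test_that("spearman_rho is a tie-aware rank correlation with valid p", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_rho(x, x * 2, n_perm = 1000, seed = 1)$rho, 1)
  expect_equal(spearman_rho(x, -x, n_perm = 1000, seed = 1)$rho, -1)
  set.seed(9)
  a <- sample(c(1, 2, 2, 3, 5, 8, 9))
  b <- sample(c(4, 4, 6, 7, 2, 2, 10))
  expect_equal(spearman_rho(a, b, n_perm = 1000, seed = 2)$rho,
               cor(rank(a), rank(b)))
  strong <- spearman_rho(1:20, (1:20) + rnorm(20, 0, 0.5), n_perm = 2000,
                         seed = 3)
  expect_lt(strong$p, 0.01)
  expect_error(spearman_rho(rep(1, 6), x), "constant")
  expect_error(spearman_rho(1:4, 1:4), "at least 5")
})

test_that("HRV metrics and their scale properties", {
  r <- seq(0, 30, by = 1)
  h <- hrv_metrics(r)
  expect_equal(h$cv_ibi, 0)
  expect_equal(h$mean_hr, 60)
  set.seed(10)
  t2 <- cumsum(abs(rnorm(50, 0.8, 0.05)))
  h1 <- hrv_metrics(t2)
  h2 <- hrv_metrics(t2 * 2)       # doubling intervals halves the rate
  expect_equal(h2$mean_hr, h1$mean_hr / 2)
  expect_equal(h2$cv_ibi, h1$cv_ibi)
  expect_error(hrv_metrics(c(1, 2)), "at least 3")
  expect_error(hrv_metrics(c(1, 3, 2)), "increasing")
})

test_that("pointwise time-course tests mask injected windows", {
  set.seed(11)
  nt <- 30
  a <- matrix(rnorm(10 * nt), 10)
  b <- matrix(rnorm(10 * nt), 10)
  b[, 10:15] <- b[, 10:15] + 2.5
  res <- pointwise_timecourse_test(a, b, n_perm = 1000, seed = 12)
  expect_true(all(res$mask[10:15]))
  expect_lt(sum(res$mask[-(10:15)]), 4)
  # single timepoint reduces to one permutation test plus trivial FDR
  one <- pointwise_timecourse_test(a[, 1, drop = FALSE],
                                   b[, 1, drop = FALSE],
                                   n_perm = 1000, seed = 13)
  direct <- permutation_test(a[, 1], b[, 1], n_perm = 1000, seed = 13 + 1)$p
  expect_equal(one$p, direct)
  expect_identical(one$mask, fdr_adaptive(direct)$mask)
  # channel dimension is averaged before testing
  arr_a <- array(rnorm(10 * 3 * nt), c(10, 3, nt))
  arr_b <- array(rnorm(10 * 3 * nt), c(10, 3, nt))
  res3 <- pointwise_timecourse_test(arr_a, arr_b, channels = 1:2,
                                    n_perm = 1000, seed = 14)
  expect_length(res3$p, nt)
  expect_error(pointwise_timecourse_test(a, b[, 1:10], n_perm = 1000),
               "grids")
})
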