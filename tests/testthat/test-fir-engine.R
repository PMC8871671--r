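test_that("median stratification partitions rows with >= on the high side", {
  d <- noise_dataset(n = 1000, K = 3, seed = 1)
  s <- median_stratify(d, c("X1", "X2"))
  expect_s3_class(s, "fir_strata")
  idx <- sort(unname(unlist(s$strata)))
  expect_identical(idx, 1:1000)                    # exact partition
  expect_equal(sum(lengths(s$strata)), 1000)       # no duplicates
  # independent medians halve twice: each stratum about a quarter
  expect_true(all(abs(lengths(s$strata) - 250) < 60))
  # thresholds are the empirical medians
  expect_equal(s$thresholds, c(median(d$x[, "X1"]), median(d$x[, "X2"])))
  # high strata take the ties (>= median)
  m1 <- s$thresholds[1]
  expect_true(all(d$x[c(s$strata$hi_hi, s$strata$hi_lo), "X1"] >= m1))
  expect_true(all(d$x[c(s$strata$lo_hi, s$strata$lo_lo), "X1"] < m1))
})

test_that("correlated pairs concentrate in the concordant strata", {
  m <- base_cormat()
  d <- simulate_dataset(m, n = 1e5, seed = 2)
  s <- median_stratify(d, c("X1", "X2"))
  # bivariate-normal orthant probability at rho = 0.8 (Monte-Carlo-free form)
  p <- orthant_prob(0.8)
  expect_lt(abs(length(s$strata$hi_hi) / d$n - p), 0.01)
  expect_lt(abs(length(s$strata$lo_lo) / d$n - p), 0.01)
})

test_that("ties at the median still give an exact partition", {
  set.seed(3)
  x <- cbind(X1 = rep(c(0, 1, 1, 2), length.out = 120),  # heavy ties at median 1
             X2 = rnorm(120), X3 = rnorm(120))
  d <- fir_dataset(rnorm(120), x)
  s <- median_stratify(d, c("X1", "X2"), min_stratum_size = 5L)
  expect_identical(sort(unname(unlist(s$strata))), 1:120)
  # rows equal to the median of X1 sit in the high strata
  at_median <- which(x[, "X1"] == median(x[, "X1"]))
  expect_true(all(at_median %in% c(s$strata$hi_hi, s$strata$hi_lo)))
})

test_that("undersized strata raise an error naming the stratum", {
  set.seed(4)
  x1 <- rnorm(120)
  x <- cbind(X1 = x1, X2 = x1, X3 = rnorm(120))  # perfectly concordant pair
  d <- fir_dataset(rnorm(120), x)
  expect_error(median_stratify(d, c("X1", "X2")), "stratum 'hi_lo'|stratum 'lo_hi'")
  d2 <- noise_dataset(n = 100, K = 3)
  d2$x[, 1] <- 5
  expect_error(median_stratify(d2, c("X1", "X2")), "constant")
})

test_that("compute_fir satisfies its arithmetic identity and is deterministic", {
  d <- noise_dataset(n = 200, K = 4, seed = 6)
  hp <- tiny_hp()
  r <- compute_fir(d, c("X1", "X3"), hp = hp, seed = 8, min_stratum_size = 30L)
  expect_s3_class(r, "fir_result")
  expect_identical(names(r$rmse_strata), c("hi_hi", "hi_lo", "lo_hi", "lo_lo"))
  expect_identical(r$mean_rmse_strata, mean(r$rmse_strata))
  expect_identical(r$fir, r$mean_rmse_strata / r$rmse_reduced)
  expect_true(r$fir > 0 && is.finite(r$fir))
  r2 <- compute_fir(d, c("X1", "X3"), hp = hp, seed = 8, min_stratum_size = 30L)
  expect_identical(r$fir, r2$fir)
})

test_that("scan_all_pairs covers C(K,2) lexicographic pairs", {
  hp <- tiny_hp(n_trees = 20L)
  for (K in c(3L, 5L)) {
    d <- noise_dataset(n = 220, K = K, seed = K)
    scan <- scan_all_pairs(d, hp = hp, seed = 1, min_stratum_size = 30L)
    expect_equal(scan$n_pairs, K * (K - 1) / 2)
    expect_equal(nrow(scan$table), K * (K - 1) / 2)
    expect_equal(nrow(scan$failed), 0)
    expect_true(all(scan$table$fir > 0 & is.finite(scan$table$fir)))
  }
  # lexicographic order of the first few pairs
  d <- noise_dataset(n = 220, K = 4, seed = 9)
  scan <- scan_all_pairs(d, hp = hp, seed = 1, min_stratum_size = 30L)
  expect_identical(scan$table$feature1[1:3], c("X1", "X1", "X1"))
  expect_identical(scan$table$feature2[1:3], c("X2", "X3", "X4"))
})

test_that("pairs that cannot stratify are recorded as failures, not dropped", {
  set.seed(10)
  x1 <- rnorm(200)
  x <- cbind(X1 = x1, X2 = x1 + rnorm(200, sd = 1e-6), X3 = rnorm(200),
             X4 = rnorm(200))
  d <- fir_dataset(rnorm(200), x)
  scan <- scan_all_pairs(d, hp = tiny_hp(n_trees = 20L), seed = 1,
                         min_stratum_size = 30L)
  expect_equal(scan$n_pairs, 6)
  expect_equal(nrow(scan$failed), 1)
  expect_identical(scan$failed$feature1, "X1")
  expect_identical(scan$failed$feature2, "X2")
  expect_match(scan$failed$reason, "stratum")
  expect_equal(nrow(scan$table), 5)
})

test_that("stratum fold reduction follows the one-fold-per-20-rows rule", {
  expect_equal(firtest:::stratum_cv_folds(125L, 10L), 6L)
  expect_equal(firtest:::stratum_cv_folds(250L, 10L), 10L)
  expect_equal(firtest:::stratum_cv_folds(45L, 10L), 2L)
})
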