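test_that("build_correlation_matrix assembles the stated blocks", {
  m <- base_cormat()
  v <- m$values
  expect_identical(m$labels, c("Y", paste0("X", 1:15)))
  expect_equal(dim(v), c(16L, 16L))
  expect_identical(v, t(v))            # symmetric by construction, exactly
  expect_equal(unname(diag(v)), rep(1, 16))
  expect_equal(v["X1", "X2"], 0.8)
  expect_equal(v["Y", "X1"], 0.3)
  expect_equal(v["Y", "X2"], 0.3)
  expect_equal(v["Y", "X3"], 0.5)
  expect_equal(v["X3", "X4"], 0.2)
  expect_equal(v["Y", "X6"], 0)
  expect_equal(v["X1", "X3"], 0)       # cross-block defaults to zero
  expect_equal(v["X6", "X7"], 0)
  expect_true(m$min_eigenvalue > 0)    # base design is realizable
})

test_that("all-zero correlation spec yields the identity matrix", {
  spec <- correlation_spec(rho_pair = 0, rho_interactive_y = 0,
                           rho_marginal_y = 0, rho_marginal_within = 0)
  m <- build_correlation_matrix(spec)
  expect_equal(unname(m$values), diag(16))
  expect_equal(m$min_eigenvalue, 1)
})

test_that("scenarios 3 and 4 are not positive definite as stated", {
  # independent oracle: direct eigen-decomposition of the raw block matrix
  for (sc in c("3", "4")) {
    m <- build_correlation_matrix(scenario_spec(sc))
    ev <- eigen(m$values, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(min(ev), 0)
    expect_equal(m$min_eigenvalue, min(ev))
  }
  # scenarios 1 and 2 are fine
  for (sc in c("1", "2"))
    expect_gt(build_correlation_matrix(scenario_spec(sc))$min_eigenvalue, 0)
})

test_that("correlation_spec rejects out-of-range values", {
  expect_error(correlation_spec(rho_pair = 1.2), "\\[-1, 1\\]")
  expect_error(correlation_spec(n_marginal = 0, n_noise = 0), "at least 3")
})

test_that("repair_positive_definite floors the eigenvalue and restores form", {
  tol <- 1e-8
  # already-PD input is returned unchanged
  m <- base_cormat()
  r <- repair_positive_definite(m, tol)
  expect_identical(r$values, m$values)
  expect_equal(attr(r, "max_change"), 0)
  ident <- build_correlation_matrix(
    correlation_spec(rho_pair = 0, rho_interactive_y = 0, rho_marginal_y = 0,
                     rho_marginal_within = 0))
  expect_identical(repair_positive_definite(ident, tol)$values, ident$values)

  # scenario 4 raw matrix gets repaired to the floor with unit diagonal
  m4 <- build_correlation_matrix(scenario_spec("4"))
  r4 <- repair_positive_definite(m4, tol)
  ev <- eigen(r4$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), tol)
  expect_equal(unname(diag(r4$values)), rep(1, 16))
  expect_identical(r4$values, t(r4$values))
  expect_gt(attr(r4, "max_change"), 0)

  # idempotence: repairing a repaired matrix changes nothing beyond tolerance
  r4b <- repair_positive_definite(r4, tol)
  expect_lte(max(abs(r4b$values - r4$values)), tol)
})

test_that("simulated data reproduce the specified correlations", {
  m <- base_cormat()
  d <- simulate_dataset(m, n = 1e5, seed = 11)
  expect_s3_class(d, "fir_dataset")
  expect_identical(d$feature_names, paste0("X", 1:15))
  expect_lt(abs(cor(d$x[, "X1"], d$x[, "X2"]) - 0.8), 0.01)
  expect_lt(abs(cor(d$y, d$x[, "X3"]) - 0.5), 0.02)
  expect_lt(abs(cor(d$y, d$x[, "X6"])), 0.02)
  expect_lt(abs(sd(d$y) - 1), 0.02)

  # independence limit: all-zero spec, every pairwise correlation near 0
  z <- build_correlation_matrix(
    correlation_spec(rho_pair = 0, rho_interactive_y = 0, rho_marginal_y = 0,
                     rho_marginal_within = 0, n_noise = 2))
  dz <- simulate_dataset(z, n = 1e5, seed = 12)
  cc <- cor(cbind(dz$y, dz$x))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
})

test_that("simulate_dataset is deterministic and validates its inputs", {
  m <- base_cormat()
  d1 <- simulate_dataset(m, n = 1000, seed = 5)
  d2 <- simulate_dataset(m, n = 1000, seed = 5)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$x, d2$x)
  d3 <- simulate_dataset(m, n = 1000, seed = 6)
  expect_false(identical(d1$y, d3$y))

  expect_error(simulate_dataset(m, n = 20, seed = 1), "at least 40")
  m4 <- build_correlation_matrix(scenario_spec("4"))
  expect_error(simulate_dataset(m4, n = 1000, seed = 1),
               "repair_positive_definite")
})

test_that("interaction injection shifts only the qualifying subgroup", {
  m <- base_cormat()
  d <- simulate_dataset(m, n = 1e5, seed = 21)
  eff <- interaction_effect("mild")
  di <- inject_interaction(d, c("X1", "X2"), eff, seed = 22)

  expect_identical(di$x, d$x)          # features bitwise unchanged
  rows <- which(d$x[, "X1"] > median(d$x[, "X1"]) &
                d$x[, "X2"] > median(d$x[, "X2"]))
  expect_identical(attr(di, "injected_rows"), rows)
  expect_identical(di$y[-rows], d$y[-rows])
  # subgroup mean shift matches the stated effect mean
  expect_lt(abs(mean(di$y[rows] - d$y[rows]) - 0.5), 0.02)
  # modified-row fraction matches the bivariate-normal orthant probability
  expect_lt(abs(length(rows) / d$n - orthant_prob(0.8)), 0.01)

  # uncorrelated pair: about a quarter of rows qualify
  di0 <- inject_interaction(d, c("X6", "X7"), eff, seed = 23)
  expect_lt(abs(length(attr(di0, "injected_rows")) / d$n - 0.25), 0.01)

  # effect level none returns the input untouched
  expect_identical(inject_interaction(d, c("X1", "X2"),
                                      interaction_effect("none"), seed = 1),
                   d)
})

test_that("injection effect levels and error paths", {
  expect_equal(interaction_effect("mild")$mean, 0.5)
  expect_equal(interaction_effect("moderate")$mean, 1)
  expect_equal(interaction_effect("considerable")$mean, 2)
  expect_equal(interaction_effect("mild")$sd, 1)
  expect_error(interaction_effect("mild", sd = 0), "positive")

  d <- noise_dataset(n = 100, K = 3)
  d$x[, 1] <- 1  # constant feature: median is not a usable splitter
  expect_error(inject_interaction(d, c("X1", "X2"),
                                  interaction_effect("mild"), seed = 1),
               "constant")
  expect_error(inject_interaction(d, c("X2", "X9"),
                                  interaction_effect("mild"), seed = 1),
               "not in dataset")
})
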