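test_that("wald_ci reproduces the printed interval convention", {
  expect_equal(round(wald_ci(0.14, 100), 2), c(0.07, 0.21))
  expect_equal(round(wald_ci(0.04, 100), 3), c(0.002, 0.078))
  expect_equal(wald_ci(0, 100), c(0, 0))
  expect_equal(wald_ci(1, 50), c(1, 1))
  # clipping to [0, 1]
  ci <- wald_ci(0.01, 20)
  expect_gte(ci[1], 0)
  # wilson option stays in range and contains the point estimate
  w <- wald_ci(0.04, 100, method = "wilson")
  expect_true(w[1] > 0 && w[2] < 1 && w[1] < 0.04 && w[2] > 0.04)
})

test_that("a single-repetition experiment with a forced rejection", {
  cfg <- experiment_config(n = 500,
                           effect = interaction_effect("considerable", mean = 25),
                           reps = 1, master_seed = 3, methods = "regression")
  res <- run_experiment(cfg)
  expect_equal(res$estimates$power, 1)
  expect_equal(res$estimates$ci_high, 1)   # clipped upper bound
  expect_equal(res$estimates$rejections, 1)
})

test_that("run_experiment is fully deterministic given its config", {
  cfg <- experiment_config(n = 500, effect = interaction_effect("moderate"),
                           reps = 3, master_seed = 17,
                           methods = c("xgb_fi", "regression"),
                           hp = tiny_hp(n_trees = 25L), scan_pairs = 5)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$rejections, r2$rejections)
  expect_equal(nrow(r1$failures), 0)
  expect_identical(colnames(r1$rejections), c("xgb_fi", "regression"))
})

test_that("scenario grids tabulate cells and continue past failures", {
  expect_equal(nrow(run_scenario_grid(list())), 0)

  cfgs <- list(
    experiment_config(n = 500, effect = interaction_effect("moderate"),
                      reps = 5, master_seed = 1, methods = "regression",
                      label = "a"),
    experiment_config(n = 1000, effect = interaction_effect("moderate"),
                      reps = 5, master_seed = 1, methods = "regression",
                      label = "b"),
    # n below the simulator's floor: this cell fails but the grid continues
    experiment_config(n = 30, effect = interaction_effect("none"),
                      reps = 5, master_seed = 1, methods = "regression",
                      label = "bad"))
  grid <- suppressWarnings(run_scenario_grid(cfgs))
  expect_equal(nrow(grid), 3)
  expect_identical(grid$label, c("a", "b", "bad"))
  expect_true(is.na(grid$power[3]) && nzchar(grid$error[3]))
  expect_true(all(!is.na(grid$power[1:2])))
  expect_true(all(grid$ci_high[1:2] >= grid$power[1:2], na.rm = TRUE))
})

test_that("experiment failure accounting enforces the 5% rule", {
  # a two-pair scan cannot form a fence (needs >= 4 FIRs): every xgb_fi
  # repetition fails, which exceeds the 5% tolerance and hard-errors
  cfg <- experiment_config(n = 500, effect = interaction_effect("none"),
                           reps = 2, master_seed = 5, methods = "xgb_fi",
                           hp = tiny_hp(n_trees = 10L),
                           scan_pairs = list(c("X1", "X2"), c("X3", "X4")))
  expect_error(suppressWarnings(run_experiment(cfg)), "failed")
})
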