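test_that("experiment-1 simulation has the design's shape and is reproducible", {
  p <- generating_params("exp1")
  d <- simulate_experiment1(p, exp1_design(), seed = 1)
  expect_equal(nrow(d), 300)
  expect_equal(length(unique(d$mesocosm_id)), 20)
  expect_true(all(d$stage %in% 1:4))
  expect_true(all(d$gonad_mass_g > 0))
  expect_true(all(d$diameter_mm >= 42.12 & d$diameter_mm <= 69.46))
  # per-cell animal counts match the design exactly
  expect_true(all(table(d$mesocosm_id) == 15))
  # byte-identical reproducibility of the CSV
  f1 <- tempfile(); f2 <- tempfile()
  write_animals_csv(simulate_experiment1(p, exp1_design(), seed = 9), f1)
  write_animals_csv(simulate_experiment1(p, exp1_design(), seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate stage probabilities produce degenerate stages", {
  p <- generating_params("exp1")
  for (sx in c("F", "M"))
    p$stage_probs[[sx]][] <- matrix(rep(c(0, 0, 0, 1),
                                        each = nrow(p$stage_probs[[sx]])),
                                    ncol = 4)
  d <- simulate_experiment1(p, exp1_design(), seed = 2)
  expect_true(all(d$stage == 4L))
})

test_that("empirical stage frequencies converge to generating values", {
  # law of large numbers at a single cell with random effects off
  p <- generating_params("exp1",
                         sigma_mesocosm = c(stage = 0, gonad = 0))
  d <- simulate_experiment1(p, one_cell_design(10000, "lanina", "la_nina",
                                               16), seed = 3)
  for (sx in c("F", "M")) {
    emp <- mean(d$stage[d$sex == sx] == 4)
    expect_equal(emp, p$stage_probs[[sx]]["lanina", 4], tolerance = 0.015)
  }
  # gonad-mass mean converges to the generating curve
  dF <- d[d$sex == "F", ]
  mu <- generating_gonad_mean(p, 16, dF$diameter_mm, "lanina")
  expect_equal(mean(dF$gonad_mass_g / mu), 1, tolerance = 0.02)
})

test_that("experiment-2 split-plot structure and location effects behave", {
  p2 <- generating_params("exp2")
  d2 <- simulate_experiment2(p2, exp2_design(), seed = 4)
  expect_equal(nrow(d2), 3 * 4 * 3 * 3)
  cells <- unique(d2[, c("treatment_label", "location", "mesocosm_id")])
  expect_equal(nrow(cells), 36)   # 3 treatments x 4 tanks x 3 locations
  expect_identical(simulate_experiment2(p2, exp2_design(), seed = 5),
                   simulate_experiment2(p2, exp2_design(), seed = 5))
  # with all random effects off, locations share the cell distributions
  p0 <- generating_params("exp2", sigma_location = 0,
                          sigma_mesocosm = c(stage = 0, gonad = 0))
  big <- exp2_design(n_tanks = 4L, n_per_location = 300L)
  db <- simulate_experiment2(p0, big, seed = 6)
  sub <- db[db$treatment_label == "10C" & db$sex == "F", ]
  byloc <- tapply(sub$stage == 4, sub$location, mean)
  expect_lt(max(abs(byloc - p0$stage_probs$F["10C", 4])), 0.05)
})

test_that("generating gonad curve reproduces the calibrated cell means", {
  p <- generating_params("exp1")
  expect_equal(generating_gonad_mean(p, 16), 11.84, tolerance = 1e-9)
  expect_equal(generating_gonad_mean(p, 20), 7.2, tolerance = 1e-9)
  expect_equal(1 - generating_gonad_mean(p, 20) /
                 generating_gonad_mean(p, 13), 0.42, tolerance = 1e-9)
  expect_equal(generating_gonad_mean(p, 20, treatment = "elnino"), 7.03,
               tolerance = 1e-9)
  expect_equal(generating_gonad_mean(p, 16, treatment = "lanina"), 8.69,
               tolerance = 1e-9)
  # allometry: a 60 mm animal carries more gonad than a 40 mm one
  expect_gt(generating_gonad_mean(p, 16, 60), generating_gonad_mean(p, 16, 40))
})

test_that("invalid generating parameters are rejected", {
  expect_error(generating_params("exp1", gamma_shape = -1), "positive")
  bad <- generating_params("exp1")$stage_probs
  bad$F[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(generating_params("exp1", stage_probs = bad), "sum to 1")
})
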