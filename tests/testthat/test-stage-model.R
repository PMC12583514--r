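# Hierarchical multinomial stage model with the GP temperature smoother.
# Full-scale recovery runs live in test-acceptance.R; these tests cover the
# model surface, the simplex and determinism contracts, and fast conjugate
# calibration checks.

test_that("predicted stage probabilities are simplexes and deterministic", {
  d <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                            seed = 31)
  fit <- fit_stage_model(d, stage_model_spec("exp1"), seed = 1,
                         n_chains = 2L, n_iter = 400L, n_warmup = 400L)
  p1 <- predict_stage_probs(fit, "F", "la_nina", 16)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-9))
  expect_identical(p1, predict_stage_probs(fit, "F", "la_nina", 16))
  # interpolation at a temperature off the design grid is still a simplex
  p15 <- predict_stage_probs(fit, "M", "constant", 15)
  expect_true(all(abs(rowSums(p15) - 1) < 1e-9))
  expect_warning(predict_stage_probs(fit, "F", "constant", 25),
                 "extrapolation|range")
  expect_error(predict_stage_probs(fit, "F", "nino", 20), "unknown")
  expect_error(predict_stage_probs(fit, "X", "constant", 16), "sex")
})

test_that("the stage model rejects incomplete data and flags separation", {
  d <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                            seed = 32)
  expect_error(fit_stage_model(d[, setdiff(names(d), "mean_temp_c")]),
               "missing covariates")
  expect_error(fit_stage_model(d[0, ]), "empty")
  dna <- d; dna$sex[1] <- NA
  expect_error(fit_stage_model(dna), "missing values")
  ddeg <- d; ddeg$stage <- 4L
  expect_warning(urchintherm:::stage_model_data(ddeg,
                                                stage_model_spec("exp1")),
                 "separation")
})

test_that("a monotone-decreasing truth is recovered as monotone", {
  # females collapse at high temperature in the defaults; the posterior
  # smoother must preserve p_IV(20) < p_IV(13)
  d <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                            seed = 33)
  fit <- fit_stage_model(d, stage_model_spec("exp1"), seed = 2,
                         n_chains = 2L, n_iter = 600L, n_warmup = 600L)
  p13 <- mean(predict_stage_probs(fit, "F", "constant", 13)[, "stage4"])
  p20 <- mean(predict_stage_probs(fit, "F", "constant", 20)[, "stage4"])
  expect_lt(p20, p13)
})

test_that("cell credible intervals are calibrated over replicated designs", {
  # 95% CrIs for p_IV should cover the generating value in >= 88% of
  # replicates; with random effects off, the saturated-cell posterior is
  # exact, making 50 replicates cheap.
  p0 <- generating_params("exp1",
                          sigma_mesocosm = c(stage = 0, gonad = 0))
  truth <- p0$stage_probs$F["lanina", 4]
  hits <- 0L
  for (k in 1:50) {
    d <- simulate_experiment1(p0, exp1_design(), seed = 400 + k)
    fit <- fit_stage_cells(d, stage_cells_spec("sex_treatment"),
                           n_chains = 2L, n_iter = 1000L, seed = k)
    ci <- hpd_interval(cell_probs(fit, "F:lanina")[, 4], 0.95)
    if (ci[1] <= truth && truth <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.88)
})

test_that("null data leave treatment contrasts covering zero", {
  # identical probabilities in all cells: the 95% CrI of the La Nina vs
  # El Nino stage-IV contrast covers 0 in >= 90% of replicates
  probs <- generating_params("exp1")$stage_probs
  for (sx in c("F", "M"))
    probs[[sx]][] <- matrix(rep(c(0.2, 0.2, 0.2, 0.4),
                                each = nrow(probs[[sx]])), ncol = 4)
  p0 <- generating_params("exp1", stage_probs = probs,
                          sigma_mesocosm = c(stage = 0, gonad = 0))
  cover <- 0L
  for (k in 1:50) {
    d <- simulate_experiment1(p0, exp1_design(), seed = 500 + k)
    fit <- fit_stage_cells(d, stage_cells_spec("sex_treatment"),
                           n_chains = 2L, n_iter = 1000L, seed = k)
    dif <- cell_probs(fit, "F:lanina")[, 4] -
      cell_probs(fit, "F:elnino")[, 4]
    ci <- hpd_interval(dif, 0.95)
    if (ci[1] <= 0 && 0 <= ci[2]) cover <- cover + 1L
  }
  expect_gte(cover / 50, 0.9)
})

test_that("the exp2 variant fits categorical cells with location effects", {
  d2 <- simulate_experiment2(generating_params("exp2"), exp2_design(),
                             seed = 34)
  fit <- fit_stage_model(d2, stage_model_spec("exp2"), seed = 3,
                         n_chains = 2L, n_iter = 500L, n_warmup = 500L)
  expect_true("log_sigma_loc" %in% dimnames(fit$draws$draws)[[3]])
  p10 <- predict_stage_probs(fit, "F", "10C", 10)
  p20 <- predict_stage_probs(fit, "F", "20C", 20)
  expect_true(all(abs(rowSums(p10) - 1) < 1e-9))
  # the strong suppression at 20 C relative to 10 C is recovered in sign
  expect_lt(mean(p20[, "stage4"]), mean(p10[, "stage4"]))
})
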