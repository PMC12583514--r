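test_that("gonad model rejects invalid masses and diameters", {
  d <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                            seed = 41)
  bad <- d; bad$gonad_mass_g[c(5, 9)] <- 0
  expect_error(fit_gonad_model(bad), "rows: 5, 9")
  bad2 <- d; bad2$diameter_mm[1] <- -3
  expect_error(fit_gonad_model(bad2), "diameters")
  expect_error(fit_gonad_model(d[0, ]), "empty")
})

test_that("standardized mass is positive, draw-deterministic, and tracks allometry", {
  d <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                            seed = 42)
  fit <- fit_gonad_model(d, seed = 1, n_chains = 2L, n_iter = 600L,
                         n_warmup = 600L)
  m16 <- standardized_mass(fit, "constant", 16)
  expect_true(all(m16 > 0))
  expect_identical(m16, standardized_mass(fit, "constant", 16))
  # the generating allometry is positive: bigger animals, more gonad
  expect_gt(mean(standardized_mass(fit, "constant", 16, 60)),
            mean(standardized_mass(fit, "constant", 16, 45)))
  expect_error(standardized_mass(fit, "mystery", 16), "not in fitted")
})

test_that("a zero allometry coefficient is recovered as null", {
  p <- generating_params("exp1", allometry = 0,
                         sigma_mesocosm = c(stage = 0.25, gonad = 0))
  d <- simulate_experiment1(p, exp1_design(), seed = 43)
  fit <- fit_gonad_model(d, seed = 2, n_chains = 2L, n_iter = 800L,
                         n_warmup = 600L)
  gam <- draws_of(fit, "log_diameter")
  ci <- hpd_interval(gam, 0.95)
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
  # and the fitted masses no longer depend on diameter
  r <- mean(standardized_mass(fit, "constant", 16, 65)) /
    mean(standardized_mass(fit, "constant", 16, 45))
  expect_equal(r, 1, tolerance = 0.1)
})

test_that("a log-linear truth is reproduced by the cubic fit", {
  # beta2 = beta3 = 0: the richer model must not distort a straight line
  p <- generating_params("exp1",
                         gonad_curve = c(log(25) - 0.08 * 10, -0.08, 0, 0),
                         treatment_offsets = c(elnino = 0, lanina = 0),
                         sigma_mesocosm = c(stage = 0.25, gonad = 0))
  # 100 animals per mesocosm: cell-mean noise ~2%, so a 5% band tests the
  # polynomial's shape rather than sampling noise
  d <- simulate_experiment1(p, exp1_design(n_per_mesocosm = 100L), seed = 44)
  fit <- fit_gonad_model(d, seed = 3, n_chains = 2L, n_iter = 800L,
                         n_warmup = 600L)
  for (tc in c(10, 13, 16, 18, 20)) {
    truth <- generating_gonad_mean(p, tc)
    got <- mean(standardized_mass(fit, "constant", tc))
    expect_equal(got / truth, 1, tolerance = 0.05)
  }
})

test_that("the La Nina deficit is recovered with the correct sign", {
  d <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                            seed = 45)
  fit <- fit_gonad_model(d, seed = 4, n_chains = 2L, n_iter = 800L,
                         n_warmup = 600L)
  dln <- draws_of(fit, "delta_la_nina")
  expect_lt(mean(dln), 0)
  expect_gt(mean(dln < 0), 0.8)   # most posterior mass on a deficit
})

test_that("simulate_from_fitted draws Gamma masses at a parameter draw", {
  d <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                            seed = 46)
  fit <- fit_gonad_model(d, seed = 5, n_chains = 2L, n_iter = 400L,
                         n_warmup = 400L)
  dr <- list(coefs = colMeans(draws_matrix(fit$draws))[1:fit$gd$p],
             phi = 10)
  sim <- simulate_from_fitted(fit, dr, exp1_design(), seed = 9)
  expect_equal(nrow(sim), 300)
  expect_true(all(sim$gonad_mass_g > 0))
  expect_identical(sim, simulate_from_fitted(fit, dr, exp1_design(),
                                             seed = 9))
})
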