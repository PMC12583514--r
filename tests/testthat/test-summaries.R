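test_that("HPD intervals match the exhaustive shortest-window search", {
  set.seed(11)
  for (rgen in list(function(n) rnorm(n),
                    function(n) rexp(n),
                    function(n) rbeta(n, 0.5, 3))) {
    x <- rgen(800)
    for (mass in c(0.5, 0.9, 0.95)) {
      got <- hpd_interval(x, mass)
      xs <- sort(x)
      m <- ceiling(mass * length(xs))
      widths <- xs[m:length(xs)] - xs[1:(length(xs) - m + 1)]
      expect_equal(unname(got["upper"] - got["lower"]), min(widths))
      expect_true(got["lower"] %in% xs && got["upper"] %in% xs)
    }
  }
})

test_that("HPD matches known densities and the coda cross-check", {
  set.seed(12)
  z <- rnorm(1e5)
  h <- hpd_interval(z, 0.95)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.03)
  e <- rexp(1e5)
  he <- hpd_interval(e, 0.95)
  expect_lt(he[["lower"]], 0.01)    # mode-at-zero density starts at 0
  expect_equal(unname(hpd_interval(rep(3.5, 500), 0.9)), c(3.5, 3.5))
  expect_error(hpd_interval(rnorm(10), 0.95), "at least")
  skip_if_not_installed("coda")
  cd <- coda::HPDinterval(coda::as.mcmc(z), prob = 0.95)
  # coda's window is one draw wider (round vs ceiling); agreement is to
  # within a single order statistic
  expect_equal(unname(h), unname(as.vector(cd)), tolerance = 1e-3)
})

test_that("contrasts are draw-wise and use the reported conventions", {
  a <- rep(0.89, 200); b <- rep(0.15, 200)
  sc <- stage_contrast(a, b)
  expect_equal(unique(sc$draws), 74)
  expect_equal(sc$summary$mean, 74)
  expect_equal(sc$summary$definition, "percentage_point")
  expect_equal(stage_contrast(rep(0.92, 200),
                              rep(0.44, 200))$summary$mean, 48)
  same <- stage_contrast(a, a)
  expect_equal(same$summary$hpd95_lower, same$summary$hpd95_upper)

  rr <- relative_reduction(rep(11.84, 200), rep(8.69, 200))
  expect_equal(rr$summary$mean, 1 - 8.69 / 11.84, tolerance = 1e-12)
  expect_equal(relative_reduction(rep(12.41, 200),
                                  rep(7.2, 200))$summary$mean, 0.42,
               tolerance = 0.002)
  expect_equal(relative_reduction(rep(5, 200), rep(5, 200))$summary$mean, 0)
  expect_error(relative_reduction(rep(-1, 200), rep(1, 200)), "positive")
  expect_error(stage_contrast(rnorm(200), rnorm(150)), "resample")
  # transform-then-summarize: nonlinear contrast differs from
  # mean-then-transform on skewed draws
  set.seed(13)
  A <- rlnorm(5000); B <- rlnorm(5000, -0.5)
  rr2 <- relative_reduction(A, B)
  expect_false(isTRUE(all.equal(rr2$summary$mean, 1 - mean(B) / mean(A),
                                tolerance = 1e-3)))
})

test_that("Bayesian P follows both tail conventions", {
  expect_equal(bayesian_p(rep(1, 200))$p_greater, 1)
  set.seed(14)
  sym <- rnorm(2e4)
  expect_equal(bayesian_p(sym)$p_greater, 0.5, tolerance = 0.02)
  shifted <- rnorm(2e5) + 0.5
  bp <- bayesian_p(shifted)
  expect_equal(bp$p_greater, pnorm(0.5), tolerance = 0.01)
  expect_equal(bp$two_sided, 2 * (1 - pnorm(0.5)), tolerance = 0.01)
  expect_error(bayesian_p(rnorm(10)), "at least")
})

test_that("split-Rhat separates converged from disparate chains", {
  set.seed(15)
  iid <- matrix(rnorm(4e4), ncol = 4)
  expect_lt(split_rhat(iid), 1.005)
  apart <- cbind(rnorm(500), rnorm(500, 5))
  expect_gt(split_rhat(apart), 1.1)
  # within-chain drift is caught by the split
  drift <- cbind(c(rnorm(500, 0), rnorm(500, 3)),
                 c(rnorm(500, 0), rnorm(500, 3)))
  expect_gt(split_rhat(drift), 1.1)
  expect_equal(split_rhat(matrix(2, 100, 4)), 1)
  expect_error(split_rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(split_rhat(matrix(rnorm(6), ncol = 2)), "4 draws")
})

test_that("summary tables nest the 90% HPD inside the 95% HPD", {
  set.seed(16)
  st <- summary_table(rgamma(5000, 3), "x")
  expect_lte(st$hpd95_lower, st$hpd90_lower)
  expect_gte(st$hpd95_upper, st$hpd90_upper)
  expect_lte(st$hpd90_lower, st$mean)
  expect_gte(st$hpd90_upper, st$mean)
})
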