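# Bridge-sampling marginal likelihoods against conjugate closed forms, and
# Bayes-factor behavior.

test_that("bridge estimate matches the Dirichlet-multinomial closed form", {
  counts <- matrix(c(3L, 2L, 1L, 0L), 1, 4,
                   dimnames = list("all", paste0("stage", 1:4)))
  # log joint with the multinomial-counts likelihood (coefficient included)
  lcoef <- lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  base_lp <- urchintherm:::stage_cells_lp(counts, 1)
  lp <- function(th) base_lp(th)$lp + lcoef
  set.seed(1)
  n <- 4000
  g <- matrix(rgamma(n * 4, shape = rep(counts + 1, each = n)), n, 4)
  p <- g / rowSums(g)
  th <- log(p[, 2:4] / p[, 1])
  br <- log_marginal_bridge(th, lp, seed = 2)
  exact <- lcoef + dm_log_marginal_cat(as.vector(counts), 1)
  expect_lt(abs(br$log_ml - exact), 0.05)
  expect_true(br$converged)
})

test_that("bridge estimate matches the normal-normal closed form", {
  set.seed(3)
  y <- rnorm(20, 1.5, 1)              # known sd 1; prior mu ~ N(0, 2^2)
  post_var <- 1 / (20 + 1 / 4)
  mu <- matrix(rnorm(4000, post_var * sum(y), sqrt(post_var)), ncol = 1)
  lj <- function(m) sum(dnorm(y, m, 1, log = TRUE)) +
    dnorm(m, 0, 2, log = TRUE)
  br <- log_marginal_bridge(mu, lj, seed = 4)
  S <- diag(20) + 4                    # marginal covariance of y
  exact <- -0.5 * 20 * log(2 * pi) -
    0.5 * as.numeric(determinant(S)$modulus) -
    0.5 * drop(y %*% solve(S, y))
  expect_lt(abs(br$log_ml - exact), 0.02)
})

test_that("independent bridge runs agree within their Monte Carlo error", {
  counts <- matrix(c(12L, 7L, 25L, 40L), 1, 4,
                   dimnames = list("all", paste0("stage", 1:4)))
  lp <- urchintherm:::stage_cells_lp(counts, 1)
  set.seed(5)
  n <- 3000
  g <- matrix(rgamma(n * 4, shape = rep(counts + 1, each = n)), n, 4)
  p <- g / rowSums(g)
  th <- log(p[, 2:4] / p[, 1])
  b1 <- log_marginal_bridge(th, lp, seed = 11)
  b2 <- log_marginal_bridge(th, lp, seed = 12)
  expect_lt(abs(b1$log_ml - b2$log_ml),
            3 * sqrt(b1$mc_error^2 + b2$mc_error^2) + 1e-6)
})

test_that("Bayes factors are antisymmetric and self-comparison gives 1", {
  d <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                            seed = 51)
  full <- fit_stage_cells(d, stage_cells_spec("sex_treatment"), seed = 1)
  null <- fit_stage_cells(d, stage_cells_spec("sex"), seed = 2)
  ab <- bayes_factor(full, null, seed = 3)
  ba <- bayes_factor(null, full, c("null", "full"), seed = 3)
  expect_identical(ab$log_bf, -ba$log_bf)
  # a model against an independent refit of itself: BF ~ 1
  null2 <- fit_stage_cells(d, stage_cells_spec("sex"), seed = 9)
  self <- bayes_factor(null, null2, c("a", "b"), seed = 4)
  expect_lt(abs(self$log_bf), 4 * self$mc_error + 0.02)
  # mismatched data are refused
  d2 <- simulate_experiment1(generating_params("exp1"), exp1_design(),
                             seed = 52)
  other <- fit_stage_cells(d2, stage_cells_spec("sex"), seed = 5)
  expect_error(bayes_factor(full, other), "same dataset")
})

test_that("verdict bands follow the reported evidence scale", {
  expect_match(bf_verdict(250), "decisive")
  expect_match(bf_verdict(19), "strong")
  expect_match(bf_verdict(3), "weak")
  expect_match(bf_verdict(0.05), "second")
})

test_that("Bayes factors increase with simulated effect size", {
  design <- exp1_design()
  base <- c(0.25, 0.25, 0.25, 0.25)
  med_bf <- vapply(c(0, 1.2, 2.4), function(eff) {
    bfs <- vapply(1:6, function(k) {
      pr <- generating_params("exp1")$stage_probs
      for (sx in c("F", "M")) {
        m <- matrix(base, nrow(pr[[sx]]), 4, byrow = TRUE)
        shift <- exp(eff * (seq_len(nrow(m)) - 4) / 4)
        m[, 4] <- m[, 4] * shift
        m <- m / rowSums(m)
        dimnames(m) <- dimnames(pr[[sx]])
        pr[[sx]] <- m
      }
      p <- generating_params("exp1", stage_probs = pr,
                             sigma_mesocosm = c(stage = 0, gonad = 0))
      d <- simulate_experiment1(p, design, seed = 700 + 10 * eff + k)
      f <- fit_stage_cells(d, stage_cells_spec("sex_treatment"),
                           n_chains = 2L, n_iter = 1000L, seed = k)
      n <- fit_stage_cells(d, stage_cells_spec("sex"),
                           n_chains = 2L, n_iter = 1000L, seed = k + 50)
      bayes_factor(f, n, seed = k)$log_bf
    }, numeric(1))
    median(bfs)
  }, numeric(1))
  expect_true(all(diff(med_bf) > 0))
  expect_lt(med_bf[1], 0)       # Occam: the null wins under a null truth
})
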