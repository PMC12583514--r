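# Generic Hamiltonian Monte Carlo on an unconstrained parameter space.
# Models supply the unnormalized log joint density and its analytic gradient;
# the sampler handles step-size adaptation (dual averaging), a diagonal mass
# matrix estimated during warmup, and jittered path lengths.

leapfrog <- function(theta, p, eps, L, lp_grad, inv_mass) {
  g <- lp_grad(theta)$grad
  for (l in seq_len(L)) {
    p <- p + 0.5 * eps * g
    theta <- theta + eps * (inv_mass * p)
    g <- lp_grad(theta)$grad
    if (any(!is.finite(g))) return(list(theta = theta, p = p, ok = FALSE))
    p <- p + 0.5 * eps * g
  }
  list(theta = theta, p = p, ok = TRUE)
}

hamiltonian <- function(lp, p, inv_mass) -lp + 0.5 * sum(inv_mass * p^2)

find_initial_stepsize <- function(theta, lp_grad, inv_mass) {
  eps <- 0.1
  d <- length(theta)
  p <- stats::rnorm(d, 0, sqrt(1 / inv_mass))
  h0 <- hamiltonian(lp_grad(theta)$lp, p, inv_mass)
  step <- leapfrog(theta, p, eps, 1L, lp_grad, inv_mass)
  ratio <- if (step$ok)
    exp(h0 - hamiltonian(lp_grad(step$theta)$lp, step$p, inv_mass)) else 0
  dir <- if (ratio > 0.5) 1 else -1
  for (i in 1:30) {
    eps <- eps * 2^dir
    step <- leapfrog(theta, p, eps, 1L, lp_grad, inv_mass)
    ratio <- if (step$ok)
      exp(h0 - hamiltonian(lp_grad(step$theta)$lp, step$p, inv_mass)) else 0
    if ((dir == 1 && ratio < 0.5) || (dir == -1 && ratio > 0.5)) break
  }
  max(eps, 1e-6)
}

hmc_chain <- function(lp_grad, init, n_warmup, n_iter, seed,
                      L_range = c(8L, 16L), target_accept = 0.8) {
  set.seed(seed)
  d <- length(init)
  theta <- init
  inv_mass <- rep(1, d)
  eps <- find_initial_stepsize(theta, lp_grad, inv_mass)

  # Dual-averaging state (Hoffman & Gelman 2014 defaults).
  da_init <- function(eps0) list(mu = log(10 * eps0), log_eps_bar = 0,
                                 h_bar = 0, t0 = 10, gamma = 0.05,
                                 kappa = 0.75, t = 0)
  da <- da_init(eps)
  da_update <- function(da, accept_prob, target) {
    da$t <- da$t + 1
    w <- 1 / (da$t + da$t0)
    da$h_bar <- (1 - w) * da$h_bar + w * (target - accept_prob)
    log_eps <- da$mu - sqrt(da$t) / da$gamma * da$h_bar
    w2 <- da$t^(-da$kappa)
    da$log_eps_bar <- w2 * log_eps + (1 - w2) * da$log_eps_bar
    da$eps <- exp(log_eps)
    da
  }

  # Stan-style warmup: a fast step-size buffer, expanding slow windows that
  # each end with a mass-matrix update and dual-averaging restart, and a
  # terminal fast buffer that settles the step size under the final metric.
  init_buffer <- min(75L, floor(n_warmup * 0.15))
  term_buffer <- min(50L, floor(n_warmup * 0.1))
  slow_end <- n_warmup - term_buffer
  window_ends <- integer(0)
  w_start <- init_buffer + 1L; w_len <- 25L
  while (w_start <= slow_end) {
    w_end <- min(w_start + w_len - 1L, slow_end)
    if (slow_end - w_end < 2L * w_len) w_end <- slow_end
    window_ends <- c(window_ends, w_end)
    w_start <- w_end + 1L; w_len <- w_len * 2L
  }

  draws <- matrix(NA_real_, n_iter, d)
  n_divergent <- 0L
  accept_sum <- 0

  one_step <- function(theta, eps) {
    p <- stats::rnorm(d, 0, sqrt(1 / inv_mass))
    cur <- lp_grad(theta)
    h0 <- hamiltonian(cur$lp, p, inv_mass)
    L <- sample(L_range[1]:L_range[2], 1L)
    step <- leapfrog(theta, p, eps, L, lp_grad, inv_mass)
    if (!step$ok) return(list(theta = theta, accept = 0, divergent = TRUE))
    h1 <- hamiltonian(lp_grad(step$theta)$lp, step$p, inv_mass)
    dh <- h0 - h1
    divergent <- !is.finite(dh) || dh < -50
    accept <- if (is.finite(dh)) min(1, exp(dh)) else 0
    if (!divergent && stats::runif(1) < accept) theta <- step$theta
    list(theta = theta, accept = accept, divergent = divergent)
  }

  warm_store <- matrix(NA_real_, n_warmup, d)
  win_begin <- init_buffer + 1L
  for (i in seq_len(n_warmup)) {
    st <- one_step(theta, da$eps %||% eps)
    theta <- st$theta
    da <- da_update(da, st$accept, target_accept)
    warm_store[i, ] <- theta
    if (i %in% window_ends) {
      rows <- win_begin:i
      v <- apply(warm_store[rows, , drop = FALSE], 2L, stats::var)
      n_w <- length(rows)
      v <- n_w / (n_w + 5) * v + 5 / (n_w + 5) * 1e-3  # regularized
      inv_mass <- pmax(v, 1e-8)
      # Restart dual averaging around the current step size under the new
      # metric (re-probing from scratch is fragile in stiff models).
      da <- da_init(max(exp(da$log_eps_bar), 1e-5))
      win_begin <- i + 1L
    }
  }
  eps <- exp(da$log_eps_bar)

  for (i in seq_len(n_iter)) {
    st <- one_step(theta, eps * stats::runif(1, 0.9, 1.1))
    theta <- st$theta
    if (st$divergent) n_divergent <- n_divergent + 1L
    accept_sum <- accept_sum + st$accept
    draws[i, ] <- theta
  }
  list(draws = draws, eps = eps, n_divergent = n_divergent,
       accept_rate = accept_sum / n_iter)
}

#' Sample an unconstrained target with Hamiltonian Monte Carlo
#'
#' Runs several independent chains of HMC with dual-averaging step-size
#' adaptation, a diagonal mass matrix estimated during warmup, and path
#' lengths jittered uniformly over `L_range` to avoid resonance.
#'
#' @param lp_grad Function of the parameter vector returning
#'   `list(lp = , grad = )` -- the unnormalized log joint density (including
#'   any change-of-variable Jacobians) and its gradient.
#' @param init Either a numeric vector used (jittered) for every chain, or a
#'   function `function(chain)` returning a per-chain initial vector.
#' @param param_names Character vector of parameter names.
#' @param n_chains,n_warmup,n_iter Chains, warmup iterations (discarded), and
#'   retained iterations per chain.
#' @param seed Integer seed; chain c uses `spawn_seed(seed, c)`.
#' @param L_range Integer range of leapfrog steps per iteration.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @return A [posterior_draws] object.
#' @export
hmc_sample <- function(lp_grad, init, param_names,
                       n_chains = 4L, n_warmup = 500L, n_iter = 1500L,
                       seed = 1L, L_range = c(8L, 16L),
                       target_accept = 0.8) {
  d <- length(param_names)
  init_fn <- if (is.function(init)) init else {
    base <- init
    function(chain) {
      set.seed(spawn_seed(seed, 90 + chain))
      base + stats::rnorm(d, 0, 0.05)
    }
  }
  chains <- lapply(seq_len(n_chains), function(c) {
    hmc_chain(lp_grad, init_fn(c), n_warmup, n_iter,
              seed = spawn_seed(seed, c), L_range = L_range,
              target_accept = target_accept)
  })
  arr <- array(NA_real_, c(n_iter, n_chains, d),
               dimnames = list(NULL, NULL, param_names))
  for (c in seq_len(n_chains)) arr[, c, ] <- chains[[c]]$draws
  posterior_draws(arr, seed = seed,
                  diagnostics = list(
                    eps = vapply(chains, `[[`, numeric(1), "eps"),
                    accept_rate = vapply(chains, `[[`, numeric(1),
                                         "accept_rate"),
                    n_divergent = vapply(chains, `[[`, integer(1),
                                         "n_divergent")))
}
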