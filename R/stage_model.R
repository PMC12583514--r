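# Hierarchical Bayesian multinomial model of gametogenic stage (I-IV).
# Stage I is the reference category. Per-treatment-type baseline stage
# proportions carry Dirichlet(1) priors (mapped to the logit scale); sex and
# sex-by-treatment effects are normal logit offsets; the response to mean
# temperature is a Gaussian-process smoother (squared-exponential kernel,
# shared hyperparameters across stages) over standardized temperature; and
# mesocosms (plus, for the split-plot experiment, source locations)
# contribute scalar random intercepts on the non-reference logits.

#' Stage-model specification
#'
#' @param experiment `"exp1"` (GP smoother over mean temperature) or
#'   `"exp2"` (categorical terms only, location random effects).
#' @param use_gp Include the GP temperature smoother (default: exp1 only).
#' @param location_effects Include source-location random intercepts
#'   (default: exp2 only).
#' @param sex_prior_sd Normal prior SD for sex and sex-by-treatment logit
#'   offsets.
#' @param meso_prior_sd Half-normal prior scale for the mesocosm intercept
#'   SD.
#' @param gp_jitter Diagonal jitter for the GP Gram matrix.
#' @param alpha Dirichlet concentration for baseline stage proportions.
#' @return A `stage_model_spec` object.
#' @export
stage_model_spec <- function(experiment = c("exp1", "exp2"),
                             use_gp = NULL, location_effects = NULL,
                             sex_prior_sd = 2.5, meso_prior_sd = 1,
                             gp_jitter = 1e-6, alpha = 1) {
  experiment <- match.arg(experiment)
  structure(list(experiment = experiment,
                 use_gp = use_gp %||% (experiment == "exp1"),
                 location_effects = location_effects %||%
                   (experiment == "exp2"),
                 sex_prior_sd = sex_prior_sd,
                 meso_prior_sd = meso_prior_sd,
                 gp_jitter = gp_jitter, alpha = alpha),
            class = "stage_model_spec")
}

# Assemble the fixed data structures the log-joint needs.
stage_model_data <- function(data, spec) {
  need <- c("stage", "sex", "treatment_label", "treatment_type",
            "mean_temp_c", "mesocosm_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  if (any(is.na(data[need])))
    stop("missing values in required covariates")
  if (!all(data$stage %in% 1:4)) stop("stages must be coded 1..4")

  # Exp 1 uses treatment *type* cells (constant / el_nino / la_nina; the
  # constant gradient is carried by the GP). Exp 2 has no smoother, so each
  # treatment level is its own categorical cell.
  cellv <- if (spec$experiment == "exp2") data$treatment_label
           else data$treatment_type
  types <- sort(unique(cellv))
  type_idx <- match(cellv, types)
  male <- as.numeric(data$sex == "M")
  meso <- sort(unique(data$mesocosm_id))
  meso_idx <- match(data$mesocosm_id, meso)
  center <- mean(data$mean_temp_c); scale <- stats::sd(data$mean_temp_c)
  if (!is.finite(scale) || scale == 0) scale <- 1
  xu <- sort(unique((data$mean_temp_c - center) / scale))
  j_idx <- match((data$mean_temp_c - center) / scale, xu)
  Y <- matrix(0, nrow(data), 3)
  for (s in 2:4) Y[data$stage == s, s - 1] <- 1

  loc <- NULL; loc_idx <- NULL
  if (spec$location_effects) {
    if (!"location" %in% names(data) || any(is.na(data$location)))
      stop("location_effects requested but location column is missing/NA")
    loc <- sort(unique(data$location))
    loc_idx <- match(data$location, loc)
  }
  # Separation diagnostic: every sex x treatment cell in one stage.
  cellcounts <- stage_counts(data, "sex_treatment")
  if (all(rowSums(cellcounts > 0) <= 1L))
    warning("all animals share one stage in every cell; ",
            "likelihood is degenerate (separation)")

  list(n = nrow(data), types = types, type_idx = type_idx, male = male,
       meso = meso, meso_idx = meso_idx, xu = xu, j_idx = j_idx,
       J = length(xu), M = length(meso), Tn = length(types),
       center = center, scale = scale, Y = Y,
       loc = loc, loc_idx = loc_idx, L = length(loc))
}

# Parameter layout: named index list into the flat unconstrained vector.
stage_model_layout <- function(sd, spec) {
  idx <- list(); pos <- 0L
  add <- function(name, k) {
    idx[[name]] <<- if (k > 0) pos + seq_len(k) else integer(0)
    pos <<- pos + k
  }
  add("b", 3L * sd$Tn)
  add("beta", 3L)
  n_nonref <- max(sd$Tn - 1L, 0L)
  add("gamma", 3L * n_nonref)
  if (spec$use_gp) {
    add("f", 6L * sd$J)     # per-sex, per-stage smooths (F then M blocks)
    add("log_ell", 1L)
    add("log_sgp", 1L)
  }
  add("z_meso", sd$M)
  add("log_sigma_meso", 1L)
  if (spec$location_effects) {
    add("z_loc", sd$L)
    add("log_sigma_loc", 1L)
  }
  idx$total <- pos
  idx
}

stage_param_names <- function(sd, spec, idx) {
  nm <- character(idx$total)
  nm[idx$b] <- as.vector(t(outer(sd$types, paste0("logit", 2:4), paste,
                                 sep = ".")))
  nm[idx$beta] <- paste0("beta_male.logit", 2:4)
  if (length(idx$gamma))
    nm[idx$gamma] <- as.vector(t(outer(sd$types[-1],
                                       paste0("gamma.logit", 2:4),
                                       paste, sep = ".")))
  if (spec$use_gp) {
    fcols <- paste0(".", rep(c("F", "M"), each = 3), ".logit",
                    rep(2:4, 2))
    nm[idx$f] <- as.vector(outer(paste0("f", seq_len(sd$J)), fcols, paste0))
    nm[idx$log_ell] <- "log_ell"; nm[idx$log_sgp] <- "log_sgp"
  }
  nm[idx$z_meso] <- paste0("z_meso.", sd$meso)
  nm[idx$log_sigma_meso] <- "log_sigma_meso"
  if (spec$location_effects) {
    nm[idx$z_loc] <- paste0("z_loc.", sd$loc)
    nm[idx$log_sigma_loc] <- "log_sigma_loc"
  }
  nm
}

# Build the unnormalized log joint and its analytic gradient.
stage_model_lp <- function(sd, spec, idx) {
  Y <- sd$Y
  male <- sd$male
  ssd2 <- spec$sex_prior_sd^2
  D2 <- outer(sd$xu, sd$xu, function(a, b) (a - b)^2)
  n_nonref <- max(sd$Tn - 1L, 0L)

  reject <- list(lp = -Inf, grad = rep(0, idx$total))
  function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 60))
      return(reject)    # numerically hopeless region; reject the trajectory
    b <- matrix(theta[idx$b], sd$Tn, 3, byrow = TRUE)
    beta <- theta[idx$beta]
    gamma <- if (n_nonref > 0)
      matrix(theta[idx$gamma], n_nonref, 3, byrow = TRUE)
    else matrix(0, 0, 3)
    gamma_full <- rbind(0, gamma)            # constant row is the reference
    z <- theta[idx$z_meso]
    sig_m <- exp(theta[idx$log_sigma_meso])
    delta <- sig_m * z

    eta <- b[sd$type_idx, , drop = FALSE] +
      male * (matrix(beta, sd$n, 3, byrow = TRUE) +
                gamma_full[sd$type_idx, , drop = FALSE]) +
      delta[sd$meso_idx]

    lp <- 0; g_ell <- NULL; g_sgp <- NULL
    if (spec$use_gp) {
      # Non-centered GP: latent z ~ N(0, I), f = chol(K) z; the likelihood
      # sees the column-centered field (the smooth carries only the
      # temperature *shape*; its level belongs to the baselines and sex
      # offsets, which removes a prior-only flat ridge between them).
      z_gp <- matrix(theta[idx$f], sd$J, 6)  # cols: F logit2..4, M logit2..4
      if (abs(theta[idx$log_ell]) > 15 || abs(theta[idx$log_sgp]) > 15)
        return(reject)
      ell <- exp(theta[idx$log_ell]); sgp <- exp(theta[idx$log_sgp])
      K0 <- sgp^2 * exp(-D2 / (2 * ell^2))
      K <- K0 + diag(spec$gp_jitter, sd$J)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) return(reject)
      Lc <- t(ch)
      f <- Lc %*% z_gp
      lp <- lp - 0.5 * sum(z_gp^2) +
        dfoldnorm_log(ell, 1, 1) + theta[idx$log_ell] +
        dfoldnorm_log(sgp, 1, 1) + theta[idx$log_sgp]
      fc <- sweep(f, 2L, colMeans(f))
      fall <- fc[sd$j_idx, , drop = FALSE]
      eta <- eta + fall[, 1:3] * (1 - male) + fall[, 4:6] * male
    }
    nu <- NULL
    if (spec$location_effects) {
      zl <- theta[idx$z_loc]
      sig_l <- exp(theta[idx$log_sigma_loc])
      nu <- sig_l * zl
      eta <- eta + nu[sd$loc_idx]
      lp <- lp - 0.5 * sum(zl^2) +
        dfoldt_log(sig_l, 3, 0.1) + theta[idx$log_sigma_loc]
    }

    lse <- log1p(rowSums(exp(eta)))          # eta relative to stage-I logit 0
    big <- pmax(eta[, 1], eta[, 2], eta[, 3]) > 30   # guard overflow
    if (any(big))
      lse[big] <- row_logsumexp(cbind(0, eta[big, , drop = FALSE]))
    lp <- lp + sum(eta * Y) - sum(lse)

    P <- exp(eta - lse)                      # probs of stages 2..4
    R <- Y - P

    # Dirichlet(alpha) + logit-Jacobian on each baseline simplex.
    pb <- row_softmax(cbind(0, b))
    a <- spec$alpha
    lp <- lp + a * sum(log(pb)) +
      sd$Tn * (lgamma(4 * a) - 4 * lgamma(a))
    gb <- rowsum(R, sd$type_idx) + a * (1 - 4 * pb[, 2:4, drop = FALSE])

    lp <- lp - 0.5 * sum(beta^2) / ssd2 - 0.5 * sum(gamma^2) / ssd2 -
      0.5 * sum(z^2) -
      0.5 * sig_m^2 / spec$meso_prior_sd^2 + theta[idx$log_sigma_meso]

    Rmale <- rowsum(R * male, sd$type_idx)
    gbeta <- colSums(Rmale) - beta / ssd2
    ggamma <- if (n_nonref > 0)
      Rmale[-1, , drop = FALSE] - gamma / ssd2 else NULL

    rmeso <- rowsum(rowSums(R), sd$meso_idx)
    gz <- sig_m * rmeso - z
    gsig <- sig_m * sum(z * rmeso) -
      sig_m^2 / spec$meso_prior_sd^2 + 1

    grad <- numeric(idx$total)
    grad[idx$b] <- as.vector(t(gb))
    grad[idx$beta] <- gbeta
    if (n_nonref > 0) grad[idx$gamma] <- as.vector(t(ggamma))
    if (spec$use_gp) {
      gf_lik <- cbind(rowsum(R * (1 - male), sd$j_idx),
                      rowsum(R * male, sd$j_idx))
      gc <- sweep(gf_lik, 2L, colMeans(gf_lik))      # centering projector
      grad[idx$f] <- as.vector(crossprod(Lc, gc) - z_gp)
      # d chol(K) via dL = L Phi(L^-1 dK L^-T), Phi = lower tri, half diag.
      dchol_dot <- function(dK) {
        Mh <- forwardsolve(Lc, t(forwardsolve(Lc, dK)))
        Mh[upper.tri(Mh)] <- 0
        diag(Mh) <- diag(Mh) / 2
        sum(gc * ((Lc %*% Mh) %*% z_gp))
      }
      grad[idx$log_ell] <- dchol_dot(K0 * D2 / ell^2) +
        dfoldnorm_grad(ell, 1, 1) * ell + 1
      grad[idx$log_sgp] <- dchol_dot(2 * K0) +
        dfoldnorm_grad(sgp, 1, 1) * sgp + 1
    }
    grad[idx$z_meso] <- gz
    grad[idx$log_sigma_meso] <- gsig
    if (spec$location_effects) {
      rloc <- rowsum(rowSums(R), sd$loc_idx)
      grad[idx$z_loc] <- sig_l * rloc - zl
      grad[idx$log_sigma_loc] <- sig_l * sum(zl * rloc) +
        dfoldt_grad(sig_l, 3, 0.1) * sig_l + 1
    }
    list(lp = lp, grad = grad)
  }
}

#' Fit the hierarchical stage model
#'
#' Samples the posterior of the multinomial stage model with HMC (analytic
#' gradients). In `mode = "test"` the sampler runs 4 chains of 3,000
#' retained iterations after 1,000 warmup (a smoke-scale run whose reported
#' quantities are judged against split-Rhat < 1.01); `mode = "paper"` runs
#' 4 x 12,000 after 2,000 warmup, the full-length setting judged against
#' 1.001.
#'
#' @param data Animal-record data frame.
#' @param spec A [stage_model_spec()].
#' @param seed Integer seed.
#' @param mode `"test"` or `"paper"` (ignored if `n_iter` is given).
#' @param n_chains,n_iter,n_warmup Optional explicit MCMC shape.
#' @return A `stage_model_fit` with fields `draws` ([posterior_draws]),
#'   `log_joint` (unconstrained log joint closure, for bridge sampling),
#'   `spec`, `sd` (prepared data), `idx` (parameter layout),
#'   `data_fingerprint`.
#' @export
fit_stage_model <- function(data, spec = stage_model_spec("exp1"),
                            seed = 1L, mode = c("test", "paper"),
                            n_chains = 4L, n_iter = NULL, n_warmup = NULL) {
  mode <- match.arg(mode)
  if (is.null(n_iter))
    n_iter <- if (mode == "paper") 12000L else 3000L
  if (is.null(n_warmup))
    n_warmup <- if (mode == "paper") 2000L else 1000L
  if (nrow(data) == 0L) stop("empty dataset")
  sdat <- stage_model_data(data, spec)
  idx <- stage_model_layout(sdat, spec)
  lp <- stage_model_lp(sdat, spec, idx)

  init <- function(chain) {
    set.seed(spawn_seed(seed, 900 + chain))
    th <- numeric(idx$total)
    counts <- rowsum(cbind(1 - rowSums(sdat$Y), sdat$Y), sdat$type_idx)
    p <- (counts + 1) / rowSums(counts + 1)
    th[idx$b] <- as.vector(t(log(p[, 2:4, drop = FALSE] / p[, 1])))
    th[idx$log_sigma_meso] <- log(0.2)
    th <- th + stats::rnorm(idx$total, 0, 0.05)
    th
  }
  draws <- hmc_sample(lp, init, stage_param_names(sdat, spec, idx),
                      n_chains = n_chains, n_warmup = n_warmup,
                      n_iter = n_iter, seed = seed, target_accept = 0.9)
  structure(list(draws = draws, log_joint = lp, spec = spec, sd = sdat,
                 idx = idx, data_fingerprint = data_fingerprint(data)),
            class = "stage_model_fit")
}

#' @export
print.stage_model_fit <- function(x, ...) {
  cat(sprintf(
    "<stage_model_fit> %s: %d animals, %d types, %d mesocosms%s, max Rhat %.4f\n",
    x$spec$experiment, x$sd$n, x$sd$Tn, x$sd$M,
    if (x$spec$use_gp) sprintf(", GP over %d temperatures", x$sd$J) else "",
    max(x$draws$rhat)))
  invisible(x)
}

#' Posterior stage-probability draws at a covariate combination
#'
#' Evaluates, for every retained draw, the 4-vector of stage probabilities
#' for a given sex, treatment type and mean temperature, at the median
#' mesocosm (random effects set to zero). Temperatures away from the fitted
#' design points are interpolated through the GP conditional mean; queries
#' outside the fitted temperature range trigger a warning.
#'
#' @param fit A `stage_model_fit`.
#' @param sex `"F"` or `"M"`.
#' @param treatment_type Treatment cell: for Experiment 1, `"constant"`,
#'   `"el_nino"` or `"la_nina"` (the constant gradient is resolved by
#'   `mean_temp_c` through the smoother); for Experiment 2, the treatment
#'   label (`"10C"`, `"20C"`, `"elnino"`).
#' @param mean_temp_c Mean temperature in deg C.
#' @return Draws x 4 matrix; every row sums to 1.
#' @export
predict_stage_probs <- function(fit, sex, treatment_type, mean_temp_c) {
  sdat <- fit$sd; idx <- fit$idx; spec <- fit$spec
  t <- match(treatment_type, sdat$types)
  if (is.na(t)) stop("unknown treatment_type: ", treatment_type)
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  m <- draws_matrix(fit$draws)
  nd <- nrow(m)
  male <- as.numeric(sex == "M")

  eta <- m[, idx$b[(3 * (t - 1) + 1):(3 * t)], drop = FALSE]
  if (male == 1) {
    eta <- eta + m[, idx$beta, drop = FALSE]
    if (t > 1 && length(idx$gamma))
      eta <- eta + m[, idx$gamma[(3 * (t - 2) + 1):(3 * (t - 1))],
                     drop = FALSE]
  }
  if (spec$use_gp) {
    x <- (mean_temp_c - sdat$center) / sdat$scale
    if (x < min(sdat$xu) - 1e-9 || x > max(sdat$xu) + 1e-9)
      warning("mean_temp_c outside the fitted temperature range; ",
              "GP extrapolation")
    j <- which(abs(sdat$xu - x) < 1e-9)
    cols <- 3 * male + 1:3            # F block first, then M block
    D2 <- outer(sdat$xu, sdat$xu, function(a, b) (a - b)^2)
    d2s <- (x - sdat$xu)^2
    exact <- length(j) == 1L
    fstar <- matrix(0, nd, 3)
    ells <- exp(m[, idx$log_ell]); sgps <- exp(m[, idx$log_sgp])
    Z6 <- array(m[, idx$f], c(nd, sdat$J, 6))
    for (d in seq_len(nd)) {
      K <- sgps[d]^2 * exp(-D2 / (2 * ells[d]^2)) +
        diag(spec$gp_jitter, sdat$J)
      fd <- t(chol(K)) %*% Z6[d, , cols]          # J x 3 latent field
      v <- if (exact) fd[j, ] else {
        ks <- sgps[d]^2 * exp(-d2s / (2 * ells[d]^2))
        crossprod(fd, solve(K, ks))
      }
      fstar[d, ] <- v - colMeans(fd)             # centered smooth
    }
    eta <- eta + fstar
  }
  p <- row_softmax(cbind(0, eta))
  colnames(p) <- paste0("stage", 1:4)
  p
}
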