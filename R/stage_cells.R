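# Categorical (cell-wise) stage models with Dirichlet priors: the
# hypothesis-testing arm used for Bayes factors and their simulation-based
# calibration. A model is a set of stage-probability simplexes indexed by
# design cells; the full model ("treatment, sex and interaction") uses
# sex x treatment cells, the null uses sex-only cells. The Dirichlet prior
# makes the posterior exactly sampleable, and every fit carries an
# unconstrained-scale log-joint closure for bridge sampling.

cell_levels_for <- function(cells_by, data) {
  switch(cells_by,
         sex_treatment = sort(unique(paste(data$sex, data$treatment_label,
                                           sep = ":"))),
         sex = sort(unique(data$sex)),
         treatment = sort(unique(data$treatment_label)),
         sex_treatment_location = sort(unique(paste(
           data$sex, data$treatment_label, data$location, sep = ":"))),
         none = "all",
         stop("unknown cells_by: ", cells_by))
}

cell_id_of <- function(cells_by, data) {
  switch(cells_by,
         sex_treatment = paste(data$sex, data$treatment_label, sep = ":"),
         sex = data$sex,
         treatment = data$treatment_label,
         sex_treatment_location = paste(data$sex, data$treatment_label,
                                        data$location, sep = ":"),
         none = rep("all", nrow(data)))
}

#' Specification of a categorical stage-cell model
#'
#' @param cells_by How design cells are formed: `"sex_treatment"` (the full
#'   model: treatment, sex and their interaction), `"sex"` (the null used
#'   against it), `"treatment"`, `"sex_treatment_location"` (the
#'   Experiment-2 full model with location interactions) or `"none"`.
#' @param alpha Dirichlet concentration (default 1: equal prior odds, high
#'   uncertainty).
#' @return An object of class `stage_cells_spec`.
#' @export
stage_cells_spec <- function(cells_by = "sex_treatment", alpha = 1) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  structure(list(cells_by = cells_by, alpha = alpha),
            class = "stage_cells_spec")
}

# Stage counts per cell: cells x 4 matrix.
stage_counts <- function(data, cells_by) {
  lv <- cell_levels_for(cells_by, data)
  id <- factor(cell_id_of(cells_by, data), levels = lv)
  tab <- table(id, factor(data$stage, levels = 1:4))
  m <- matrix(as.integer(tab), nrow = length(lv), ncol = 4,
              dimnames = list(lv, paste0("stage", 1:4)))
  m
}

# Log joint (per-animal categorical likelihood + Dirichlet prior +
# logit-transform Jacobian) on the unconstrained scale: theta holds
# log(p_s / p_1) for s = 2..4, cells stacked.
stage_cells_lp <- function(counts, alpha) {
  C <- nrow(counts)
  alpha4 <- rep(alpha, length.out = 4)
  lognorm <- C * (lgamma(sum(alpha4)) - sum(lgamma(alpha4)))
  function(theta) {
    th <- matrix(theta, C, 3, byrow = TRUE)
    eta <- cbind(0, th)
    lse <- row_logsumexp(eta)
    logp <- eta - lse
    # (alpha - 1) from the prior plus +1 from the Jacobian gives alpha.
    lp <- sum(counts * logp) +
      sum(logp %*% alpha4) + lognorm
    grad <- (counts[, 2:4, drop = FALSE] +
               matrix(alpha4[2:4], C, 3, byrow = TRUE)) -
      (rowSums(counts) + sum(alpha4)) * exp(logp[, 2:4, drop = FALSE])
    list(lp = lp, grad = as.vector(t(grad)))
  }
}

#' Fit a categorical stage-cell model
#'
#' Posterior over per-cell stage-probability simplexes under a Dirichlet
#' prior. With `method = "exact"` the conjugate Dirichlet posterior is
#' sampled directly (independent draws, organised into pseudo-chains so the
#' usual diagnostics apply); `method = "hmc"` samples the identical
#' posterior on the unconstrained logit scale with HMC, which the conjugate
#' closed form then cross-validates.
#'
#' @param data Animal-record data frame (needs `stage`, `sex`,
#'   `treatment_label`, and `location` for location cells).
#' @param spec A [stage_cells_spec()].
#' @param method `"exact"` or `"hmc"`.
#' @param n_chains,n_iter,n_warmup MCMC shape (warmup ignored for exact).
#' @param seed Integer seed.
#' @return A `stage_cells_fit`: fields `draws` ([posterior_draws] on the
#'   unconstrained scale), `probs` (draws x cells x 4 stage-probability
#'   array), `counts`, `log_joint`, `spec`, `data_fingerprint`.
#' @export
fit_stage_cells <- function(data, spec = stage_cells_spec(),
                            method = c("exact", "hmc"),
                            n_chains = 4L, n_iter = 1500L, n_warmup = 500L,
                            seed = 1L) {
  method <- match.arg(method)
  if (nrow(data) == 0L) stop("empty dataset")
  if (any(!data$stage %in% 1:4)) stop("stages must be coded 1..4")
  counts <- stage_counts(data, spec$cells_by)
  if (all(apply(counts > 0, 1L, sum) <= 1L))
    warning("every cell has all animals in a single stage; ",
            "likelihood is degenerate (separation)")
  alpha4 <- rep(spec$alpha, length.out = 4)
  C <- nrow(counts)
  par_names <- as.vector(t(outer(rownames(counts), paste0("logit", 2:4),
                                 paste, sep = ".")))
  lp <- stage_cells_lp(counts, spec$alpha)

  if (method == "exact") {
    arr <- array(NA_real_, c(n_iter, n_chains, 3 * C),
                 dimnames = list(NULL, NULL, par_names))
    for (ch in seq_len(n_chains)) {
      set.seed(spawn_seed(seed, ch))
      for (c in seq_len(C)) {
        g <- matrix(stats::rgamma(n_iter * 4, shape = rep(counts[c, ] + alpha4,
                                                          each = n_iter)),
                    n_iter, 4)
        p <- g / rowSums(g)
        arr[, ch, (3 * (c - 1) + 1):(3 * c)] <- log(p[, 2:4] / p[, 1])
      }
    }
    draws <- posterior_draws(arr, seed = seed,
                             diagnostics = list(method = "exact"))
  } else {
    init <- function(chain) {
      set.seed(spawn_seed(seed, 90 + chain))
      emp <- (counts + 1) / rowSums(counts + 1)
      as.vector(t(log(emp[, 2:4] / emp[, 1]))) +
        stats::rnorm(3 * C, 0, 0.1)
    }
    draws <- hmc_sample(lp, init, par_names, n_chains = n_chains,
                        n_warmup = n_warmup, n_iter = n_iter, seed = seed)
  }

  m <- draws_matrix(draws)
  probs <- array(NA_real_, c(nrow(m), C, 4),
                 dimnames = list(NULL, rownames(counts), paste0("stage", 1:4)))
  for (c in seq_len(C)) {
    eta <- cbind(0, m[, (3 * (c - 1) + 1):(3 * c), drop = FALSE])
    probs[, c, ] <- row_softmax(eta)
  }
  structure(list(draws = draws, probs = probs, counts = counts,
                 log_joint = lp, spec = spec,
                 n_animals = nrow(data),
                 data_fingerprint = data_fingerprint(data)),
            class = "stage_cells_fit")
}

#' @export
print.stage_cells_fit <- function(x, ...) {
  cat(sprintf("<stage_cells_fit> %d cells (%s), %d animals, max Rhat %.4f\n",
              nrow(x$counts), x$spec$cells_by, x$n_animals,
              max(x$draws$rhat)))
  invisible(x)
}

#' Per-draw stage probabilities for one cell
#'
#' @param fit A `stage_cells_fit`.
#' @param cell Cell name (row name of `fit$counts`).
#' @return Draws x 4 matrix of stage probabilities (rows sum to 1).
#' @export
cell_probs <- function(fit, cell) {
  if (!cell %in% dimnames(fit$probs)[[2]])
    stop("unknown cell: ", cell)
  fit$probs[, cell, ]
}

#' Draw cell simplexes from the Dirichlet prior
#'
#' @param spec A [stage_cells_spec()].
#' @param cell_names Character vector of cell names the draw should cover.
#' @param seed Integer seed.
#' @return List with `probs`: a cells x 4 matrix of stage probabilities.
#' @export
prior_draw <- function(spec, cell_names, seed = 1L) {
  set.seed(seed)
  alpha4 <- rep(spec$alpha, length.out = 4)
  g <- matrix(stats::rgamma(length(cell_names) * 4,
                            shape = rep(alpha4, each = length(cell_names))),
              length(cell_names), 4)
  probs <- g / rowSums(g)
  dimnames(probs) <- list(cell_names, paste0("stage", 1:4))
  list(probs = probs)
}

#' @describeIn simulate_from_fitted Stage-cell models: animals are generated
#'   under the design (sexes Bernoulli(0.5), diameters uniform) and stages
#'   drawn from the cell simplexes in `draw$probs`; gonad masses are
#'   nuisance fill (Gamma around 8 g) since the model does not describe
#'   them.
#' @export
simulate_from_fitted.stage_cells_spec <- function(model, draw, design, seed) {
  set.seed(seed)
  cells <- design$cells
  rows <- vector("list", nrow(cells))
  counter <- 0L
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    n <- cell$n_animals
    if (n == 0L) next
    sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
    diam <- stats::runif(n, design$diameter_range_mm[1],
                         design$diameter_range_mm[2])
    fake <- data.frame(sex = sex, treatment_label = cell$treatment_label,
                       location = if (is.null(cell$location)) NA_character_
                                  else cell$location)
    id <- cell_id_of(model$cells_by, fake)
    if (any(!id %in% rownames(draw$probs)))
      stop("draw does not cover cell(s): ",
           paste(setdiff(id, rownames(draw$probs)), collapse = ", "))
    stage <- vapply(seq_len(n), function(i)
      sample.int(4L, 1L, prob = draw$probs[id[i], ]), integer(1))
    rows[[k]] <- data.frame(
      animal_id = sprintf("a%04d", counter + seq_len(n)),
      mesocosm_id = cell$mesocosm_id,
      location = if (is.null(cell$location)) NA_character_ else cell$location,
      treatment_label = cell$treatment_label,
      treatment_type = cell$treatment_type,
      mean_temp_c = cell$mean_temp_c,
      sex = sex, diameter_mm = diam, stage = stage,
      gonad_mass_g = stats::rgamma(n, 10, rate = 10 / 8))
    counter <- counter + n
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(animal_id = character(), mesocosm_id = character(),
                      location = character(), treatment_label = character(),
                      treatment_type = character(), mean_temp_c = numeric(),
                      sex = character(), diameter_mm = numeric(),
                      stage = integer(), gonad_mass_g = numeric())
  rownames(out) <- NULL
  out
}
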