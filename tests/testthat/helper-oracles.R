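# Shared test helpers: central-difference gradients and small designs.

fd_grad <- function(lp, theta, eps = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (lp(tp)$lp - lp(tm)$lp) / (2 * eps)
  }, numeric(1))
}

# A single-cell design with one mesocosm holding n animals.
one_cell_design <- function(n, label = "16C", type = "constant",
                            temp = 16) {
  structure(list(
    experiment = "exp1",
    cells = data.frame(treatment_label = label, treatment_type = type,
                       mean_temp_c = temp, mesocosm_id = "meso_1",
                       n_animals = n),
    locations = NULL,
    diameter_range_mm = c(42.12, 69.46)), class = "experiment_design")
}

# Closed-form log marginal of a single Dirichlet-multinomial cell under the
# per-animal categorical likelihood (no multinomial coefficient).
dm_log_marginal_cat <- function(counts, alpha = 1) {
  a <- rep(alpha, length(counts))
  (sum(lgamma(a + counts)) - lgamma(sum(a + counts))) -
    (sum(lgamma(a)) - lgamma(sum(a)))
}
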