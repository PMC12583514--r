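# Labelled MCMC draws with chain structure and convergence diagnostics.

#' Posterior draws container
#'
#' Stores draws as an iterations x chains x parameters array together with
#' per-parameter split-Rhat, the sampler seed, and sampler diagnostics. A fit
#' is flagged non-converged if any retained parameter has split-Rhat at or
#' above 1.001 (the convergence rule used for the full-length analyses;
#' short smoke runs are judged against 1.01).
#'
#' @param draws Numeric array `[iteration, chain, parameter]` with parameter
#'   dimnames.
#' @param seed Seed used by the sampler.
#' @param diagnostics Optional list of sampler diagnostics.
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, seed = NA_integer_, diagnostics = list()) {
  stopifnot(length(dim(draws)) == 3L)
  rhat <- apply(draws, 3L, function(m) split_rhat(m))
  structure(list(draws = draws, seed = seed, rhat = rhat,
                 diagnostics = diagnostics,
                 converged = all(rhat < 1.001, na.rm = TRUE)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<posterior_draws> %d iterations x %d chains x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("  max split-Rhat %.4f (%s); divergences: %s\n",
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged at 1.001" else "see $rhat",
              paste(x$diagnostics$n_divergent %||% "NA", collapse = "/")))
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param fit A `posterior_draws` object.
#' @return A (iterations * chains) x parameters matrix, chains stacked.
#' @export
draws_matrix <- function(fit) {
  d <- dim(fit$draws)
  m <- matrix(aperm(fit$draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(fit$draws)[[3]]
  m
}

#' Extract a single named parameter across all chains
#'
#' @param fit A `posterior_draws` object, or any model fit carrying one in
#'   its `draws` field.
#' @param name Parameter name.
#' @return Numeric vector of pooled draws.
#' @export
draws_of <- function(fit, name) {
  if (!inherits(fit, "posterior_draws")) fit <- fit$draws
  as.vector(fit$draws[, , name])
}

#' Check the convergence gate
#'
#' @param fit A `posterior_draws` object.
#' @param threshold Split-Rhat threshold (1.001 for full-length runs; 1.01
#'   for short smoke runs).
#' @return Logical.
#' @export
rhat_ok <- function(fit, threshold = 1.001) {
  all(fit$rhat < threshold, na.rm = TRUE)
}

# Serialize draws to a plain-text columnar file plus a JSON diagnostics
# report (Rhat table, seed).
#' Write draws and diagnostics to disk
#'
#' Writes pooled draws to a CSV (one column per parameter) and a JSON
#' diagnostics report with the per-parameter split-Rhat, seed and sampler
#' diagnostics.
#'
#' @param fit A `posterior_draws` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_draws <- function(fit, dir, prefix = "fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_draws.csv"))
  utils::write.csv(as.data.frame(draws_matrix(fit)), csv, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_diagnostics.json"))
  jsonlite::write_json(
    list(seed = fit$seed, rhat = as.list(fit$rhat),
         converged = fit$converged,
         n_divergent = fit$diagnostics$n_divergent %||% NA),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(draws = csv, diagnostics = js))
}
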