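# Internal helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix (used by multinomial likelihoods).
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# Softmax over rows; x has one column per category (including the reference).
row_softmax <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

#' Derive a stage seed from the run seed
#'
#' A single run seed expands to per-stage seeds via a fixed counter scheme
#' (`seed * 101 + stage_index`, folded into the 31-bit integer range), so
#' pipeline stages can be rerun in isolation while remaining reproducible.
#'
#' @param seed Integer run seed.
#' @param k Integer stage counter (0, 1, 2, ...).
#' @return An integer seed.
#' @export
spawn_seed <- function(seed, k) {
  as.integer((as.double(seed) * 101 + k) %% 2147483647)
}

# Cheap data fingerprint used to refuse Bayes-factor comparisons across
# different datasets (no external digest dependency).
data_fingerprint <- function(data) {
  paste(nrow(data),
        sum(as.integer(data$stage)),
        format(sum(data$mean_temp_c), digits = 12),
        format(sum(data$diameter_mm), digits = 12),
        sep = ":")
}

# Log density of a folded normal with location `mu`, scale `sd`, folded at 0.
dfoldnorm_log <- function(x, mu, sd) {
  ifelse(x < 0, -Inf,
         log(stats::dnorm(x, mu, sd) + stats::dnorm(x, -mu, sd)))
}

# Derivative of dfoldnorm_log with respect to x.
dfoldnorm_grad <- function(x, mu, sd) {
  a <- stats::dnorm(x, mu, sd)
  b <- stats::dnorm(x, -mu, sd)
  (-(x - mu) / sd^2 * a - (x + mu) / sd^2 * b) / (a + b)
}

# Log density of a folded (half) student-t with df nu and scale s, lower
# bound 0 (the hyperprior used for location/random-effect scales).
dfoldt_log <- function(x, nu, scale) {
  ifelse(x < 0, -Inf,
         log(2) + stats::dt(x / scale, df = nu, log = TRUE) - log(scale))
}

dfoldt_grad <- function(x, nu, scale) {
  z <- x / scale
  -(nu + 1) * z / (nu + z^2) / scale
}

# Multivariate normal log density with mean m and Cholesky factor L of the
# covariance (lower triangular). x may be a matrix (rows = points).
dmvnorm_chol_log <- function(x, m, L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  d <- ncol(x)
  z <- forwardsolve(L, t(x) - m)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

# Draw n points from MVN(m, L %*% t(L)).
rmvnorm_chol <- function(n, m, L) {
  d <- length(m)
  z <- matrix(stats::rnorm(n * d), nrow = d)
  t(L %*% z + m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
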