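# Squared-exponential covariance for the Gaussian-process temperature
# smoother. Inputs are standardized before kernel evaluation.

#' Squared exponential covariance
#'
#' `sigma^2 * exp(-(x1 - x2)^2 / (2 * l^2))`. Vectorized over `x1`/`x2`.
#'
#' @param x1,x2 Standardized inputs.
#' @param length_scale Kernel length scale (> 0).
#' @param scale Kernel scale sigma (> 0); the zero-distance covariance is
#'   `scale^2`.
#' @return Covariance value(s).
#' @export
sq_exp_kernel <- function(x1, x2, length_scale, scale) {
  if (length_scale <= 0 || scale <= 0)
    stop("kernel hyperparameters must be positive")
  scale^2 * exp(-(x1 - x2)^2 / (2 * length_scale^2))
}

#' Gram matrix of the squared-exponential kernel
#'
#' @param x Standardized input vector.
#' @inheritParams sq_exp_kernel
#' @param jitter Value added to the diagonal for numerical positive
#'   definiteness (default 1e-6).
#' @return A `length(x)` square covariance matrix.
#' @export
sq_exp_gram <- function(x, length_scale, scale, jitter = 1e-6) {
  K <- outer(x, x, sq_exp_kernel, length_scale = length_scale, scale = scale)
  K + diag(jitter, length(x))
}
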