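# Posterior summarization: highest-posterior-density intervals, derived
# contrasts on the scales the study reports, Bayesian P values, and the
# split-chain potential scale reduction factor.

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws.
#'
#' @param samples Numeric vector of posterior draws (>= 100 unless
#'   `min_draws` is lowered).
#' @param mass Probability mass, strictly between 0 and 1 (default 0.95).
#' @param min_draws Minimum number of draws required.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(1e4), 0.95)
#' @export
hpd_interval <- function(samples, mass = 0.95, min_draws = 100L) {
  if (length(samples) < min_draws)
    stop("need at least ", min_draws, " draws for an HPD interval")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- 1:(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  k <- which.min(widths)
  c(lower = x[k], upper = x[k + m - 1L])
}

#' Posterior summary table for a set of draws
#'
#' @param draws Numeric vector of draws.
#' @param label Quantity label.
#' @param definition `"percentage_point"` or `"relative"` (contrast
#'   convention tag) or `"value"`.
#' @return One-row data frame with posterior mean and nested 90/95% HPDs.
#' @export
summary_table <- function(draws, label, definition = "value") {
  h90 <- hpd_interval(draws, 0.90)
  h95 <- hpd_interval(draws, 0.95)
  data.frame(quantity = label, mean = mean(draws),
             hpd90_lower = h90[[1]], hpd90_upper = h90[[2]],
             hpd95_lower = h95[[1]], hpd95_upper = h95[[2]],
             n_draws = length(draws), definition = definition)
}

#' Stage-IV contrast in percentage points
#'
#' Draw-wise difference `A - B` of two sets of per-draw proportions,
#' reported on the percentage scale (so a drop from 0.89 to 0.15 is 74
#' percentage points). Transform-then-summarize: the contrast is computed
#' per draw, then summarized.
#'
#' @param drawsA,drawsB Per-draw proportions (equal length, or set
#'   `resample = TRUE` to bootstrap-match lengths).
#' @param label Quantity label.
#' @param resample Resample the shorter vector to match lengths.
#' @return List with `draws` (percentage points) and `summary` (a
#'   [summary_table()] row).
#' @export
stage_contrast <- function(drawsA, drawsB, label = "stage_contrast",
                           resample = FALSE) {
  if (length(drawsA) != length(drawsB)) {
    if (!resample) stop("mismatched draw lengths; set resample = TRUE")
    n <- max(length(drawsA), length(drawsB))
    drawsA <- sample(drawsA, n, replace = TRUE)
    drawsB <- sample(drawsB, n, replace = TRUE)
  }
  d <- 100 * (drawsA - drawsB)
  list(draws = d, summary = summary_table(d, label, "percentage_point"))
}

#' Relative reduction contrast
#'
#' Draw-wise `1 - B/A` for per-draw positive quantities (e.g. standardized
#' gonad masses), summarized as a proportion.
#'
#' @inheritParams stage_contrast
#' @return List with `draws` (proportions) and `summary`.
#' @export
relative_reduction <- function(drawsA, drawsB, label = "relative_reduction",
                               resample = FALSE) {
  if (length(drawsA) != length(drawsB)) {
    if (!resample) stop("mismatched draw lengths; set resample = TRUE")
    n <- max(length(drawsA), length(drawsB))
    drawsA <- sample(drawsA, n, replace = TRUE)
    drawsB <- sample(drawsB, n, replace = TRUE)
  }
  if (any(drawsA <= 0)) stop("denominator draws must be positive")
  d <- 1 - drawsB / drawsA
  list(draws = d, summary = summary_table(d, label, "relative"))
}

#' Bayesian P value for a posterior difference
#'
#' The study reports "Bayesian P" without defining the tail convention, so
#' both are returned: the one-sided posterior tail probabilities and the
#' two-sided value `2 * min(P(d > 0), P(d < 0))` (the default headline
#' value).
#'
#' @param draws Per-draw differences (>= 100 draws).
#' @return List with `p_greater`, `p_less` and `two_sided`.
#' @export
bayesian_p <- function(draws) {
  if (length(draws) < 100L) stop("need at least 100 draws")
  pg <- mean(draws > 0)
  pl <- mean(draws < 0)
  list(p_greater = pg, p_less = pl, two_sided = min(1, 2 * min(pg, pl)))
}

#' Split-chain potential scale reduction factor (split-Rhat)
#'
#' Each chain is split in half and the classic potential scale reduction
#' factor is computed on the split chains. Chains that are constant (zero
#' within- and between-variance, e.g. a degenerate parameter) return 1 by
#' convention.
#'
#' @param chains A draws x chains numeric matrix (>= 2 chains, >= 4 draws
#'   per chain).
#' @return The split-Rhat value.
#' @export
split_rhat <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  if (ncol(chains) < 2L) stop("need at least 2 chains")
  if (n < 4L) stop("need at least 4 draws per chain")
  half <- floor(n / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(chains)), function(c)
    cbind(chains[1:half, c], chains[(n - half + 1):n, c])))
  m <- ncol(split)
  nn <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2L, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) {
    if (B <= 1e-300) return(1)  # constant chains: defined limit
    return(Inf)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
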