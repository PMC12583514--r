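# Thermal schedules: constant incubations and simulated El Nino / La Nina
# event trajectories, with the acclimation ramps that precede them.

PHYS_BOUNDS <- c(5, 25)    # physically admissible mesocosm temperatures, deg C
MAX_DAILY_STEP <- 0.5      # one manual set-point adjustment per day, deg C

#' Construct a ThermalSchedule object
#'
#' @param temp_c Numeric vector of daily set-point temperatures (deg C), one
#'   value per day, ramp days first.
#' @param treatment_label One of `"constant"`, `"el_nino"`, `"la_nina"`.
#' @param level_tag Short text tag for the level, e.g. `"16C"` or `"elnino"`.
#' @param ramp_days Number of leading acclimation-ramp days. Ramp days are
#'   pre-treatment: they are excluded from the analysis window over which the
#'   realized mean is computed.
#' @return An object of class `thermal_schedule` with fields `temp_c`,
#'   `day_index` (0-based), `treatment_label`, `level_tag`, `ramp_days` and
#'   `realized_mean_c` (mean over the post-ramp window).
#' @export
thermal_schedule <- function(temp_c, treatment_label, level_tag,
                             ramp_days = 0L) {
  stopifnot(length(temp_c) > ramp_days)
  out <- structure(
    list(temp_c = as.numeric(temp_c),
         day_index = seq_along(temp_c) - 1L,
         treatment_label = match.arg(treatment_label,
                                     c("constant", "el_nino", "la_nina")),
         level_tag = level_tag,
         ramp_days = as.integer(ramp_days),
         realized_mean_c = mean(temp_c[(ramp_days + 1L):length(temp_c)])),
    class = "thermal_schedule")
  validate_schedule(out)
  out
}

#' Validate a thermal schedule's physical and operational constraints
#'
#' Checks finiteness, the physical temperature bounds, the 0.5 deg C per day
#' set-point adjustment limit within the post-ramp analysis window (ramps may
#' move up to 1 deg C per day), that constant schedules are flat after the
#' ramp, and that the recorded realized mean matches the trajectory.
#'
#' @param schedule A `thermal_schedule`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_schedule <- function(schedule) {
  t <- schedule$temp_c
  if (!all(is.finite(t)))
    stop("schedule contains non-finite temperatures")
  if (any(t < PHYS_BOUNDS[1] | t > PHYS_BOUNDS[2]))
    stop("temperatures outside physical bounds [", PHYS_BOUNDS[1], ", ",
         PHYS_BOUNDS[2], "] degC")
  r <- schedule$ramp_days
  post <- t[(r + 1L):length(t)]
  if (length(post) > 1L) {
    steps <- abs(diff(post))
    if (any(steps > MAX_DAILY_STEP + 1e-9))
      stop("daily step exceeds ", MAX_DAILY_STEP,
           " degC in the analysis window")
  }
  if (r > 1L && any(abs(diff(t[1:(r + 1L)])) > 1 + 1e-9))
    stop("ramp step exceeds 1 degC per day")
  if (schedule$treatment_label == "constant" &&
      stats::var(post) > 1e-18)
    stop("constant schedule is not flat after the ramp")
  if (abs(schedule$realized_mean_c - mean(post)) > 1e-9)
    stop("realized_mean_c does not match the trajectory")
  invisible(TRUE)
}

#' @export
print.thermal_schedule <- function(x, ...) {
  cat(sprintf(
    "<thermal_schedule> %s [%s]: %d days (%d ramp), realized mean %.2f degC\n",
    x$treatment_label, x$level_tag, length(x$temp_c), x$ramp_days,
    x$realized_mean_c))
  invisible(x)
}

#' Constant-temperature schedule with a linear acclimation ramp
#'
#' The ramp runs linearly from the ambient `start_c` to `target_c` over
#' `ramp_days` days (reaching target on day `ramp_days`), after which the
#' set point is held constant. The realized mean is computed over the
#' post-ramp window only.
#'
#' @param target_c Target constant temperature (deg C), within \[5, 25\].
#' @param n_days Total number of post-ramp treatment days.
#' @param start_c Ambient temperature at the start of the ramp (deg C).
#' @param ramp_days Length of the acclimation ramp in days (0 for none).
#' @param level_tag Optional level tag; defaults to e.g. `"16C"`.
#' @return A `thermal_schedule`.
#' @examples
#' s <- make_constant_schedule(16, n_days = 70, start_c = 13.3, ramp_days = 14)
#' s$realized_mean_c  # 16
#' @export
make_constant_schedule <- function(target_c, n_days, start_c = 13.3,
                                   ramp_days = 14L,
                                   level_tag = sprintf("%gC", target_c)) {
  if (n_days <= 0) stop("n_days must be positive")
  if (ramp_days < 0) stop("ramp_days must be non-negative")
  if (target_c < PHYS_BOUNDS[1] || target_c > PHYS_BOUNDS[2])
    stop("target_c outside physical bounds [5, 25] degC")
  ramp <- if (ramp_days > 0)
    start_c + (target_c - start_c) * (0:(ramp_days - 1L)) / ramp_days
  else numeric(0)
  temps <- c(ramp, rep(target_c, n_days))
  thermal_schedule(temps, "constant", level_tag, ramp_days = ramp_days)
}

# Mean of the plateau-then-decline trajectory as a function of the real-valued
# plateau length a (days at start_c before a linear decline reaching end_c on
# the final day).
event_mean_given_plateau <- function(a, start_c, end_c, n_days) {
  d <- 0:(n_days - 1L)
  rate <- (start_c - end_c) / (n_days - 1 - a)
  mean(pmax(end_c, pmin(start_c, start_c - rate * (d - a))))
}

# Mirror image: decline at the start, plateau of length b at end_c.
event_mean_given_tail <- function(b, start_c, end_c, n_days) {
  d <- 0:(n_days - 1L)
  rate <- (start_c - end_c) / (n_days - 1 - b)
  mean(pmax(end_c, pmin(start_c, start_c - rate * d)))
}

#' Seasonal-event schedule (El Nino / La Nina style decline)
#'
#' Builds a monotone non-increasing daily trajectory from `start_c` to
#' `end_c` whose mean over the window equals `target_mean_c`. The shape is a
#' two-segment trajectory: a plateau at `start_c` followed by a constant-rate
#' decline to `end_c` (or, when the target mean falls below the midpoint, an
#' immediate decline followed by a plateau at `end_c`), with the plateau
#' length solved so the window mean matches the target. Daily steps never
#' exceed 0.5 deg C, mirroring manual daily set-point adjustment.
#'
#' @param start_c Seasonal peak temperature (first day), deg C.
#' @param end_c Final temperature (last day), deg C; `start_c >= end_c`.
#' @param target_mean_c Required mean of the window, between `end_c` and
#'   `start_c`.
#' @param n_days Window length in days.
#' @param treatment_label `"el_nino"` or `"la_nina"`.
#' @param level_tag Optional tag.
#' @return A `thermal_schedule` with zero ramp days (ramps are handled by the
#'   experiment-level schedule builders).
#' @examples
#' en <- make_event_schedule(21, 18, 20, 70, "el_nino")
#' round(en$realized_mean_c, 2)  # 20
#' @export
make_event_schedule <- function(start_c, end_c, target_mean_c, n_days,
                                treatment_label = "el_nino",
                                level_tag = treatment_label) {
  if (n_days <= 0) stop("n_days must be positive")
  if (start_c < end_c) stop("start_c must be >= end_c (seasonal decline)")
  if (target_mean_c > start_c || target_mean_c < end_c)
    stop("target_mean_c must lie between end_c and start_c")
  if (start_c == end_c)
    return(thermal_schedule(rep(start_c, n_days), treatment_label, level_tag))

  drop <- start_c - end_c
  # Longest admissible plateau given the 0.5 degC/day rate bound.
  a_max <- n_days - 1 - drop / MAX_DAILY_STEP
  if (a_max < 0)
    stop("infeasible: decline from ", start_c, " to ", end_c, " cannot be ",
         "completed in ", n_days, " days at 0.5 degC/day")
  mid <- event_mean_given_plateau(0, start_c, end_c, n_days)
  lo <- event_mean_given_tail(a_max, start_c, end_c, n_days)
  hi <- event_mean_given_plateau(a_max, start_c, end_c, n_days)
  if (target_mean_c > hi + 1e-9 || target_mean_c < lo - 1e-9)
    stop("infeasible: target mean ", target_mean_c,
         " outside achievable range [", round(lo, 3), ", ", round(hi, 3), "]")

  d <- 0:(n_days - 1L)
  if (target_mean_c >= mid) {
    a <- stats::uniroot(function(a)
      event_mean_given_plateau(a, start_c, end_c, n_days) - target_mean_c,
      c(0, a_max), tol = 1e-10)$root
    rate <- drop / (n_days - 1 - a)
    temps <- pmax(end_c, pmin(start_c, start_c - rate * (d - a)))
  } else {
    b <- stats::uniroot(function(b)
      event_mean_given_tail(b, start_c, end_c, n_days) - target_mean_c,
      c(0, a_max), tol = 1e-10)$root
    rate <- drop / (n_days - 1 - b)
    temps <- pmax(end_c, pmin(start_c, start_c - rate * d))
  }
  thermal_schedule(temps, treatment_label, level_tag)
}

#' Mean temperature over a day window of a schedule
#'
#' @param schedule A `thermal_schedule`.
#' @param window Integer day indices (0-based) to average over; defaults to
#'   the post-ramp analysis window.
#' @return Mean temperature in deg C.
#' @export
schedule_mean <- function(schedule, window = NULL) {
  if (is.null(window))
    window <- schedule$ramp_days:(length(schedule$temp_c) - 1L)
  if (length(window) == 0) stop("empty window")
  if (any(window < 0 | window >= length(schedule$temp_c)))
    stop("window outside schedule")
  mean(schedule$temp_c[window + 1L])
}

#' Default Experiment-1 mesocosm schedules
#'
#' Twenty mesocosms: six constant levels (10, 13, 16, 17, 18, 20 deg C, two
#' mesocosms each) plus El Nino (21 -> 18 deg C, mean 20) and La Nina
#' (18 -> 14 deg C, mean 16), four mesocosms each. A two-week acclimation
#' ramp from ambient 13.3 deg C precedes each constant treatment; the event
#' treatments use the same ramp to their starting temperature (ramp steps may
#' exceed 0.5 deg C/day, which only applies within the analysis window).
#'
#' @param n_days Post-ramp window length in days (default 70, a 10-week
#'   exposure).
#' @param ramp_days Acclimation ramp length (default 14).
#' @param start_c Ambient temperature (default 13.3 deg C).
#' @return A named list of 20 `thermal_schedule`s, names = mesocosm ids.
#' @export
exp1_schedules <- function(n_days = 70L, ramp_days = 14L, start_c = 13.3) {
  levels_c <- c(10, 13, 16, 17, 18, 20)
  out <- list()
  for (lv in levels_c)
    for (r in 1:2)
      out[[sprintf("meso_%gC_%d", lv, r)]] <-
        make_constant_schedule(lv, n_days, start_c, ramp_days)
  for (r in 1:4) {
    en <- make_event_schedule(21, 18, 20, n_days, "el_nino")
    ramp <- start_c + (21 - start_c) * (0:(ramp_days - 1L)) / ramp_days
    out[[sprintf("meso_elnino_%d", r)]] <-
      thermal_schedule(c(ramp, en$temp_c), "el_nino", "elnino", ramp_days)
    ln <- make_event_schedule(18, 14, 16, n_days, "la_nina")
    ramp <- start_c + (18 - start_c) * (0:(ramp_days - 1L)) / ramp_days
    out[[sprintf("meso_lanina_%d", r)]] <-
      thermal_schedule(c(ramp, ln$temp_c), "la_nina", "lanina", ramp_days)
  }
  out
}

#' Write / read schedule CSV
#'
#' One row per mesocosm-day with columns `mesocosm_id`, `day_index`,
#' `temp_c`.
#'
#' @param schedules Named list of `thermal_schedule`s (names = mesocosm ids).
#' @param path File path.
#' @return `write_schedule_csv` returns the path invisibly;
#'   `read_schedule_csv` returns a data frame.
#' @export
write_schedule_csv <- function(schedules, path) {
  rows <- do.call(rbind, lapply(names(schedules), function(id) {
    s <- schedules[[id]]
    data.frame(mesocosm_id = id, day_index = s$day_index, temp_c = s$temp_c)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
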