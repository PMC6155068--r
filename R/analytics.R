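#' Circular summary statistics of a set of bearings
#'
#' Computes the vector-mean direction, the sample mean resultant length
#' `R`, the circular standard deviation `sqrt(-2 log R)` (radians) and the
#' precision index `1 / sqrt(-2 log R)` -- the inverse circular SD, large
#' when bearings are concentrated. `R = 1` (all bearings identical) is
#' flagged as infinite precision; `R = 0` gives precision 0.
#'
#' @param bearings numeric vector of bearings in degrees (any frame).
#' @return an object of class `circular_summary`: a list with fields `n`,
#'   `mean_bearing` (degrees in [0, 360)), `resultant_length`,
#'   `circular_sd` (radians), `precision_index`.
#' @export
#' @examples
#' circular_summary(c(0, 90))   # R = sqrt(0.5), precision ~1.20
circular_summary <- function(bearings) {
  if (length(bearings) < 1L) stop("at least one bearing is required")
  s <- mean(sin_deg(bearings))
  c_ <- mean(cos_deg(bearings))
  r <- min(1, sqrt(s^2 + c_^2))
  mean_bearing <- wrap_circle(deg(atan2(s, c_)))
  if (r >= 1 - 1e-12) {
    csd <- 0
    prec <- Inf
  } else if (r <= 1e-12) {
    csd <- Inf
    prec <- 0
  } else {
    csd <- sqrt(-2 * log(r))
    prec <- 1 / csd
  }
  structure(list(n = length(bearings), mean_bearing = mean_bearing,
                 resultant_length = r, circular_sd = csd,
                 precision_index = prec),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("Circular summary (n = %d): mean %.1f deg, R = %.4f, precision index %.3f\n",
              x$n, x$mean_bearing, x$resultant_length, x$precision_index))
  invisible(x)
}

path_length <- function(traj) {
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Escape value of a trajectory
#'
#' Net displacement projected onto the light-propagation axis, divided by
#' the total path length: 1 for an ideal straight escape directly away
#' from the source, -1 for a straight path into the light, 0 for net
#' movement perpendicular to the light axis. For unit-step simulator
#' trajectories the path length equals the number of events, so this is
#' the per-step displacement away from the light.
#'
#' @param traj a data frame with columns `x` and `y` (simulator trajectory
#'   or tracking table), at least 2 rows.
#' @param source a [light_source()] giving the propagation bearing.
#' @return scalar escape value in `[-1, 1]`.
#' @export
escape_value <- function(traj, source = light_source(180)) {
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 samples")
  len <- path_length(traj)
  if (len <= 0) stop("degenerate trajectory with zero path length")
  psi <- source$propagation_bearing
  dx <- traj$x[nrow(traj)] - traj$x[1L]
  dy <- traj$y[nrow(traj)] - traj$y[1L]
  (dx * sin_deg(psi) + dy * cos_deg(psi)) / len
}

#' Exit bearing of a trajectory
#'
#' Bearing of the final position relative to the start, expressed in the
#' light frame: the direction *toward* the source is 0 deg, angles grow
#' clockwise, straight away from the light is 180 deg.
#'
#' @inheritParams escape_value
#' @return bearing in degrees, [0, 360).
#' @export
exit_bearing <- function(traj, source = light_source(180)) {
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 samples")
  dx <- traj$x[nrow(traj)] - traj$x[1L]
  dy <- traj$y[nrow(traj)] - traj$y[1L]
  b <- deg(atan2(dx, dy))
  wrap_circle(b - (source$propagation_bearing + 180))
}

#' Per-trajectory summary
#'
#' @inheritParams escape_value
#' @return one-row `data.frame` with `exit_bearing`, `escape_value`,
#'   `n_events`, `reached_edge`.
#' @export
summarize_trajectory <- function(traj, source = light_source(180)) {
  data.frame(exit_bearing = exit_bearing(traj, source),
             escape_value = escape_value(traj, source),
             n_events = nrow(traj) - 1L,
             reached_edge = isTRUE(attr(traj, "reached_edge")))
}

#' Cohort summary table
#'
#' Applies [summarize_trajectory()] to every agent of a simulated cohort,
#' using the cohort's first light source as the reference frame.
#'
#' @param cohort a `planarian_cohort` from [run_cohort()].
#' @return `data.frame` with one row per agent (column `agent_id` first).
#' @export
summarize_cohort <- function(cohort) {
  cfg <- attr(cohort, "config")
  src <- cfg$sources[[1L]]
  rows <- lapply(seq_along(cohort), function(i)
    cbind(agent_id = i, summarize_trajectory(cohort[[i]], src)))
  do.call(rbind, rows)
}

#' Twin-tail separation of exit bearings
#'
#' Exit bearings (light at 0 deg) are split at 180 deg into a left group
#' (`< 180`) and a right group (`>= 180`); the separation is the absolute
#' difference of the two group medians. This quantifies the angular gap
#' between the two escape-trajectory clusters created by the posterior
#' blind field.
#'
#' @param bearings exit bearings in degrees, [0, 360), light frame.
#' @return object of class `twin_tail`: list with `left_median`,
#'   `right_median`, `separation`, `n_left`, `n_right`.
#' @export
#' @examples
#' twin_tail_separation(c(170, 170, 190, 190))
twin_tail_separation <- function(bearings) {
  bearings <- wrap_circle(bearings)
  left <- bearings[bearings < 180]
  right <- bearings[bearings >= 180]
  if (length(left) == 0L || length(right) == 0L)
    stop("both exit-bearing groups must be non-empty; ",
         "fall back to circular SD reporting for one-sided cohorts")
  lm_ <- stats::median(left)
  rm_ <- stats::median(right)
  structure(list(left_median = lm_, right_median = rm_,
                 separation = abs(rm_ - lm_),
                 n_left = length(left), n_right = length(right)),
            class = "twin_tail")
}

#' @export
print.twin_tail <- function(x, ...) {
  cat(sprintf("Twin-tail separation %.1f deg (left median %.1f, n = %d; right median %.1f, n = %d)\n",
              x$separation, x$left_median, x$n_left, x$right_median, x$n_right))
  invisible(x)
}

#' Rose-plot binning of bearings
#'
#' Bins bearings into `n_bins` equal sectors centered on 0,
#' `360/n_bins`, ... degrees; with the default 4 bins these are the
#' toward-light, right, away and left quadrants (each sector spans the
#' half-angle on either side of its center). Returns percentages.
#'
#' @param bearings bearings in degrees, light frame (toward source = 0).
#' @param n_bins number of sectors.
#' @return named numeric vector of percentages summing to 100; for 4 bins
#'   the names are `toward`, `right`, `away`, `left`.
#' @export
#' @examples
#' rose_histogram(c(10, 350, 180, 185))
rose_histogram <- function(bearings, n_bins = 4) {
  if (length(bearings) < 1L) stop("at least one bearing is required")
  w <- 360 / n_bins
  idx <- floor(wrap_circle(bearings + w / 2) / w) + 1L
  pct <- 100 * tabulate(idx, nbins = n_bins) / length(bearings)
  names(pct) <- if (n_bins == 4) c("toward", "right", "away", "left")
                else paste0("deg", (seq_len(n_bins) - 1L) * w)
  pct
}

#' Turn-angle versus light-angle regression
#'
#' Ordinary least squares of turn magnitude on light-angle magnitude,
#' fitted on all pairs and on the subset with `|light angle| <= split`.
#' Light received from beyond the split (the posterior blind field) evokes
#' random turning, so restricting to the responsive range raises the
#' coefficient of determination.
#'
#' @param light_angle,turn_angle paired angles in degrees.
#' @param split cut on `|light_angle|`, degrees (default 130, the upper
#'   edge of the response band at bf 40, tau 0.5).
#' @return named numeric vector `c(r2_all, r2_below_split)`.
#' @export
turn_light_regression <- function(light_angle, turn_angle, split = 130) {
  stopifnot(length(light_angle) == length(turn_angle))
  r2 <- function(x, y) {
    if (length(x) < 3L) stop("need at least 3 pairs in each subset")
    if (stats::var(x) == 0 || stats::var(y) == 0)
      stop("degenerate variance in regression input")
    summary(stats::lm(y ~ x))$r.squared
  }
  ax <- abs(wrap_signed(light_angle))
  ay <- abs(wrap_signed(turn_angle))
  keep <- ax <= split
  c(r2_all = r2(ax, ay), r2_below_split = r2(ax[keep], ay[keep]))
}

#' Extract wigwag events from a heading time series
#'
#' A wigwag swing reverses the direction of heading change. Heading
#' increments larger than `deadband` (suppressing tracking jitter) are
#' classified by sign; each sign reversal marks a turning event. Every
#' complete segment between consecutive reversals yields one observation:
#' the accumulated heading change over the segment (the swing angle) and
#' the time between the two reversals (the inter-wigwag interval). A
#' constant or monotone heading series yields no events.
#'
#' @param t sample times, seconds, non-decreasing.
#' @param phi headings, degrees.
#' @param deadband minimum increment magnitude counted as movement, degrees.
#' @return list with numeric vectors `angles` (degrees), `intervals`
#'   (seconds) and `event_times` (seconds, one per reversal).
#' @export
extract_wigwag <- function(t, phi, deadband = 1) {
  stopifnot(length(t) == length(phi), length(t) >= 3L, !is.unsorted(t))
  d <- wrap_signed(diff(phi))
  cand <- which(abs(d) > deadband)
  empty <- list(angles = numeric(0), intervals = numeric(0),
                event_times = numeric(0))
  if (length(cand) < 2L) return(empty)
  s <- sign(d[cand])
  run_start <- c(TRUE, s[-1L] != s[-length(s)])
  reversals <- cand[run_start][-1L]          # first run has no preceding reversal
  if (length(reversals) < 1L) return(empty)
  phi_u <- c(0, cumsum(d))                   # unwrapped heading, aligned to samples
  times <- t[reversals]
  if (length(reversals) < 2L)
    return(list(angles = numeric(0), intervals = numeric(0),
                event_times = times))
  j <- seq_len(length(reversals) - 1L)
  list(angles = phi_u[reversals[j + 1L]] - phi_u[reversals[j]],
       intervals = diff(times),
       event_times = times)
}

#' Maximum-likelihood fits of the wigwag distributions
#'
#' Normal MLE (mean and 1/n-variance SD) for the swing angles; log-normal
#' MLE -- i.e. the normal MLE of the log intervals -- for the inter-event
#' intervals.
#'
#' @param angles swing angles, degrees (`n >= 2`).
#' @param intervals inter-event intervals, seconds, strictly positive
#'   (`n >= 2`).
#' @return object of class `wigwag_fit`: list with `normal_mean_mle`,
#'   `normal_sd_mle` (degrees), `lognormal_mu_mle`, `lognormal_sigma_mle`,
#'   plus the data and counts.
#' @export
fit_wigwag_distributions <- function(angles, intervals) {
  stopifnot(length(angles) >= 2L, length(intervals) >= 2L)
  if (any(intervals <= 0)) stop("intervals must be strictly positive")
  m <- mean(angles)
  s <- sqrt(mean((angles - m)^2))
  lg <- log(intervals)
  mu <- mean(lg)
  sig <- sqrt(mean((lg - mu)^2))
  structure(list(angles = angles, intervals = intervals,
                 normal_mean_mle = m, normal_sd_mle = s,
                 lognormal_mu_mle = mu, lognormal_sigma_mle = sig,
                 n_angles = length(angles), n_intervals = length(intervals)),
            class = "wigwag_fit")
}

#' @export
print.wigwag_fit <- function(x, ...) {
  cat(sprintf("Wigwag fits: angles ~ Normal(%.2f, %.2f^2) deg (n = %d); ",
              x$normal_mean_mle, x$normal_sd_mle, x$n_angles))
  cat(sprintf("intervals ~ logN(mu = %.3f, sigma = %.3f) s (n = %d)\n",
              x$lognormal_mu_mle, x$lognormal_sigma_mle, x$n_intervals))
  invisible(x)
}
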