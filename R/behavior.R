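#' Behavioral parameters of the turning model
#'
#' Bundles the decision-rule and wigwag self-motion parameters. Defaults
#' are the fitted values for *Dugesia japonica*: response threshold 0.5 (of
#' a maximum input 1.0), turn-gain coefficient 3 applied on the radian
#' scale, wigwag swing angles Normal(0, 18.7 deg^2), and inter-wigwag
#' intervals log-normal with log-mean -0.15 and log-SD 0.44 (seconds).
#'
#' @param tau response threshold in (0, 1): the minimum absolute left-right
#'   input difference that triggers a turn.
#' @param gain dimensionless proportionality coefficient of the turn.
#' @param gain_units `"radians"` (default) or `"degrees"`: scale on which
#'   `gain * (|R - L| - tau)` is read before the heading update. The
#'   radian reading makes typical turns tens of degrees, comparable to a
#'   wigwag head swing; the degree reading is exposed for comparison.
#' @param wigwag_angle_sd SD of the wigwag swing angle, degrees.
#' @param wigwag_log_mean log-mean `mu` of the inter-wigwag interval
#'   distribution, log-seconds.
#' @param wigwag_log_sd log-SD `sigma` of the interval distribution.
#' @param wigwag_enabled logical; when `FALSE`, [sample_wigwag_angle()]
#'   returns zeros but the event clock still runs on the log-normal.
#' @return an object of class `behavior_params`.
#' @export
behavior_params <- function(tau = 0.5, gain = 3,
                            gain_units = c("radians", "degrees"),
                            wigwag_angle_sd = 18.7,
                            wigwag_log_mean = -0.15,
                            wigwag_log_sd = 0.44,
                            wigwag_enabled = TRUE) {
  gain_units <- match.arg(gain_units)
  stopifnot(tau > 0, tau < 1, gain > 0,
            wigwag_angle_sd > 0, wigwag_log_sd > 0,
            is.logical(wigwag_enabled), length(wigwag_enabled) == 1L)
  structure(
    list(tau = tau, gain = gain, gain_units = gain_units,
         wigwag_angle_sd = wigwag_angle_sd,
         wigwag_log_mean = wigwag_log_mean,
         wigwag_log_sd = wigwag_log_sd,
         wigwag_enabled = wigwag_enabled),
    class = "behavior_params")
}

#' @export
print.behavior_params <- function(x, ...) {
  cat("Behavior parameters: tau =", x$tau, " gain =", x$gain,
      paste0("(", x$gain_units, ")"), "\n")
  cat("  wigwag:", if (x$wigwag_enabled) "enabled" else "disabled",
      " angle SD =", x$wigwag_angle_sd, "deg",
      " interval logN(mu =", x$wigwag_log_mean, ", sigma =", x$wigwag_log_sd, ")\n")
  invisible(x)
}

#' One application of the threshold-gated turning rule
#'
#' If the absolute input difference is at or below the threshold the
#' heading changes only by the wigwag term `xi`. Above threshold the agent
#' turns away from the brighter side by `gain * (|R - L| - tau)` (read in
#' radians by default, then expressed in degrees), plus `xi`. In the
#' body frame `phi = -theta`, so turning away moves the light bearing
#' toward the posterior.
#'
#' @param phi heading(s) in degrees (direction of movement, arena frame).
#' @param inputs matrix or vector of eye inputs with elements/columns
#'   `left` and `right`, as from [eye_inputs()] or [perceived_inputs()].
#' @param params a [behavior_params()] object.
#' @param xi wigwag perturbation(s) in degrees (0 when wigwag is disabled).
#' @return updated heading(s), normalized to (-180, 180].
#' @export
#' @examples
#' p <- behavior_params()
#' turn_update(0, eye_inputs(90, eye_geometry(40)), p)   # ~ -75.6 deg turn
turn_update <- function(phi, inputs, params = behavior_params(), xi = 0) {
  if (is.null(dim(inputs))) inputs <- matrix(inputs, ncol = 2,
                                             dimnames = list(NULL, c("left", "right")))
  d <- inputs[, "right"] - inputs[, "left"]
  scale <- if (params$gain_units == "radians") 180 / pi else 1
  turn <- ifelse(abs(d) > params$tau,
                 -sign(d) * params$gain * (abs(d) - params$tau) * scale,
                 0)
  unname(wrap_signed(phi + turn + xi))
}

#' Draw wigwag swing angles
#'
#' Swing angles are Normal(0, `wigwag_angle_sd`^2) degrees; with wigwag
#' disabled the draw is identically zero (the event clock is unaffected).
#'
#' @param n number of draws.
#' @param params a [behavior_params()] object.
#' @return numeric vector of length `n`, degrees.
#' @export
sample_wigwag_angle <- function(n, params = behavior_params()) {
  if (!params$wigwag_enabled) return(rep(0, n))
  stats::rnorm(n, mean = 0, sd = params$wigwag_angle_sd)
}

#' Draw inter-wigwag intervals
#'
#' Intervals between successive wigwag events are log-normal with
#' parameters (`wigwag_log_mean`, `wigwag_log_sd`) on the natural-log
#' scale; draws are strictly positive. Intervals are drawn regardless of
#' `wigwag_enabled`, so disabling wigwag removes the angular noise without
#' changing the event clock.
#'
#' @inheritParams sample_wigwag_angle
#' @return numeric vector of length `n`, seconds.
#' @export
sample_wigwag_interval <- function(n, params = behavior_params()) {
  stats::rlnorm(n, meanlog = params$wigwag_log_mean, sdlog = params$wigwag_log_sd)
}

#' Natural-scale moments of a log-normal interval distribution
#'
#' Converts log-scale parameters to the natural-scale mean
#' `exp(mu + sigma^2/2)` and variance `(exp(sigma^2) - 1) exp(2 mu + sigma^2)`.
#'
#' @param mu log-mean (log-seconds).
#' @param sigma log-SD, `>= 0`.
#' @return named numeric vector `c(mean, variance)` in seconds, seconds^2.
#' @export
#' @examples
#' lognormal_moments(-0.15, 0.44)
lognormal_moments <- function(mu, sigma) {
  stopifnot(sigma >= 0)
  c(mean = exp(mu + sigma^2 / 2),
    variance = (exp(sigma^2) - 1) * exp(2 * mu + sigma^2))
}

#' Probability that a wigwag swing exceeds the front blind-like spot
#'
#' Two-tailed tail mass `P(|X| > half_angle)` for
#' `X ~ Normal(0, wigwag_sd^2)`, i.e. `2 * (1 - Phi(half_angle / wigwag_sd))`.
#' With the default geometry (half-angle ~15 deg, swing SD 18.7 deg) about
#' 42% of swings carry the light bearing outside the front blind-like spot,
#' which is what lets an animal facing the light pick a side.
#'
#' @param half_angle half-angle of the front blind-like spot, degrees, `>= 0`.
#' @param wigwag_sd SD of the wigwag swing angle, degrees, `> 0`.
#' @return exceedance probability in (0, 1].
#' @export
#' @examples
#' exceedance_probability(15, 18.7)   # ~0.42
exceedance_probability <- function(half_angle, wigwag_sd) {
  stopifnot(all(half_angle >= 0), wigwag_sd > 0)
  2 * stats::pnorm(half_angle / wigwag_sd, lower.tail = FALSE)
}

#' Expected time to turn away from head-on light
#'
#' Geometric-waiting-time estimate: with one Bernoulli trial of success
#' probability `p` per wigwag event and `mean_interval` seconds between
#' events, the expected wait is `mean_interval / p`. At the published 42%
#' exceedance and one event per 0.7 s this is ~1.7 s.
#'
#' @param p per-event success probability in (0, 1].
#' @param mean_interval mean inter-event interval, seconds.
#' @return expected waiting time, seconds.
#' @export
expected_turnaway_time <- function(p, mean_interval) {
  stopifnot(length(p) == 1L, length(mean_interval) == 1L, mean_interval > 0)
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  mean_interval / p
}
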