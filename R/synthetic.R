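#' Parameters for the synthetic video-tracking generator
#'
#' Describes a virtual tracking session of gliding planarians in physical
#' units (mm, s): constant gliding speed ~1.0 mm/s sampled at the video
#' frame rate, heading piecewise constant between wigwag events whose
#' times come from the log-normal interval clock and whose swing angles
#' are normal with SD 18.7 deg. Successive swings alternate direction
#' (head sways out, then back), with magnitudes `|Normal(0, sd)|`, so the
#' marginal swing distribution is still `Normal(0, sd)` while the heading
#' series shows the oscillation that reversal-based event extraction
#' expects. Optionally the threshold-gated phototaxis turn rule runs on
#' top of the sway.
#'
#' @param speed gliding speed, mm/s.
#' @param frame_rate sampling rate, Hz.
#' @param wigwag_angle_sd swing SD, degrees (0 allowed: straight gliding).
#' @param wigwag_log_mean,wigwag_log_sd log-normal interval parameters.
#' @param phototaxis_enabled logical; apply the turning rule at events.
#' @param bf_deg,tau,gain model parameters used when phototaxis is on and
#'   by [generate_turn_dataset()].
#' @param turn_noise_sd measurement noise added to model turns in
#'   [generate_turn_dataset()], degrees.
#' @param light_from_deg arena-frame bearing the light arrives from.
#' @param arena_radius arena radius, mm; animals are tracked until they
#'   cross it (or `duration` elapses).
#' @param duration tracked time per animal, seconds.
#' @param seed master seed for the generator.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(speed = 1.0, frame_rate = 30,
                            wigwag_angle_sd = 18.7,
                            wigwag_log_mean = -0.15, wigwag_log_sd = 0.44,
                            phototaxis_enabled = FALSE,
                            bf_deg = 40, tau = 0.5, gain = 3,
                            turn_noise_sd = 10,
                            light_from_deg = 0,
                            arena_radius = 40, duration = 60, seed = 1) {
  stopifnot(speed > 0, frame_rate > 0, wigwag_angle_sd >= 0,
            wigwag_log_sd > 0, arena_radius > 0, duration > 0)
  structure(list(speed = speed, frame_rate = frame_rate,
                 wigwag_angle_sd = wigwag_angle_sd,
                 wigwag_log_mean = wigwag_log_mean,
                 wigwag_log_sd = wigwag_log_sd,
                 phototaxis_enabled = isTRUE(phototaxis_enabled),
                 bf_deg = bf_deg, tau = tau, gain = gain,
                 turn_noise_sd = turn_noise_sd,
                 light_from_deg = wrap_circle(light_from_deg),
                 arena_radius = arena_radius, duration = duration,
                 seed = as.integer(seed)),
            class = "tracking_params")
}

# event schedule for one animal: times, headings after each event
wigwag_schedule <- function(params, h0) {
  mean_iv <- exp(params$wigwag_log_mean + params$wigwag_log_sd^2 / 2)
  n_guess <- max(16L, ceiling(2 * params$duration / mean_iv))
  iv <- stats::rlnorm(n_guess, params$wigwag_log_mean, params$wigwag_log_sd)
  while (sum(iv) < params$duration)
    iv <- c(iv, stats::rlnorm(n_guess, params$wigwag_log_mean, params$wigwag_log_sd))
  times <- cumsum(iv)
  times <- times[times <= params$duration]
  n <- length(times)
  if (n == 0L) return(list(times = numeric(0), headings = numeric(0)))
  mags <- abs(stats::rnorm(n, 0, params$wigwag_angle_sd))
  signs <- (if (stats::runif(1) < 0.5) 1 else -1) * (-1)^(seq_len(n) - 1L)
  swings <- signs * mags
  geom <- eye_geometry(params$bf_deg)
  bp <- behavior_params(tau = params$tau, gain = params$gain)
  h <- h0
  headings <- numeric(n)
  for (j in seq_len(n)) {
    if (params$phototaxis_enabled) {
      theta <- wrap_signed(params$light_from_deg - h)
      h <- turn_update(h, eye_inputs(theta, geom), bp, xi = swings[j])
    } else {
      h <- wrap_signed(h + swings[j])
    }
    headings[j] <- h
  }
  list(times = times, headings = headings, swings = swings)
}

#' Generate a synthetic video-tracking table
#'
#' Emulates a tracking export: one row per video frame and animal, with
#' positions in mm advanced at constant speed along a heading that is
#' piecewise constant between wigwag events. Deterministic per seed; each
#' animal uses an independent substream.
#'
#' @param params a [tracking_params()] object.
#' @param n_animals number of animals.
#' @param include_heading logical; emit the `heading_deg` column (turn it
#'   off to exercise position-only analysis, where headings are re-derived
#'   from displacement vectors).
#' @return a `data.frame` of class `tracking_table` with columns
#'   `animal_id`, `frame`, `t_s`, `x_mm`, `y_mm` and optionally
#'   `heading_deg`; attributes `params` and `swings` (the ground-truth
#'   swing angles the generator applied, pooled over animals).
#' @export
#' @examples
#' trk <- generate_tracking(tracking_params(duration = 5, seed = 7), n_animals = 2)
#' head(trk)
generate_tracking <- function(params = tracking_params(), n_animals = 1L,
                              include_heading = TRUE) {
  stopifnot(n_animals >= 1)
  step <- params$speed / params$frame_rate
  per_animal <- function(i) {
    set.seed(substream_seed(params$seed, i, block = 7L))
    h0 <- wrap_signed(stats::runif(1, 0, 360))
    sched <- wigwag_schedule(params, h0)
    t_frames <- seq(0, params$duration, by = 1 / params$frame_rate)
    h_all <- c(h0, sched$headings)
    h_at <- h_all[findInterval(t_frames, sched$times) + 1L]
    nf <- length(t_frames)
    # heading during frame interval f is the heading at its start
    x <- c(0, cumsum(step * sin_deg(h_at[-nf])))
    y <- c(0, cumsum(step * cos_deg(h_at[-nf])))
    inside <- sqrt(x^2 + y^2) < params$arena_radius
    last <- if (all(inside)) nf else min(which(!inside))
    keep <- seq_len(last)
    out <- data.frame(animal_id = i, frame = keep - 1L,
                      t_s = t_frames[keep], x_mm = x[keep], y_mm = y[keep])
    if (include_heading) out$heading_deg <- h_at[keep]
    list(table = out, swings = sched$swings)
  }
  parts <- lapply(seq_len(n_animals), per_animal)
  tab <- do.call(rbind, lapply(parts, `[[`, "table"))
  structure(tab, class = c("tracking_table", "data.frame"), params = params,
            swings = unlist(lapply(parts, `[[`, "swings")))
}

#' Generate a synthetic turn-angle versus light-angle dataset
#'
#' Emulates the scatter of single-turn measurements under light from
#' random directions: inside the response band the turn is the
#' model-prescribed turn-away plus normal measurement noise; outside it
#' (front blind-like spot and posterior blind field) turns are uniform on
#' (-180, 180], emulating undirected reorientation.
#'
#' @param params a [tracking_params()] object (uses `bf_deg`, `tau`,
#'   `gain`, `turn_noise_sd`, `seed`).
#' @param n number of measurements.
#' @return `data.frame` with columns `light_angle_deg`, `turn_angle_deg`,
#'   `in_band`.
#' @export
generate_turn_dataset <- function(params = tracking_params(), n = 1000L) {
  stopifnot(n >= 1)
  set.seed(substream_seed(params$seed, 0L, block = 11L))
  geom <- eye_geometry(params$bf_deg)
  theta <- wrap_signed(stats::runif(n, -180, 180))
  d <- input_difference(theta, geom)
  in_band <- abs(d) > params$tau
  turn <- ifelse(in_band,
                 -sign(d) * params$gain * (abs(d) - params$tau) * 180 / pi +
                   stats::rnorm(n, 0, params$turn_noise_sd),
                 stats::runif(n, -180, 180))
  data.frame(light_angle_deg = theta, turn_angle_deg = wrap_signed(turn),
             in_band = in_band)
}
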