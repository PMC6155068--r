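#' Directional light source
#'
#' Arena illumination is modelled as parallel rays: the physical source
#' sits far from the small arena, so the light bearing seen by an agent
#' depends only on its heading, never on its position.
#'
#' @param propagation_bearing arena-frame bearing (degrees, compass
#'   convention: 0 = arena north, clockwise) in which the rays travel.
#'   Light *arrives from* `propagation_bearing + 180`.
#' @param active logical flag.
#' @return an object of class `light_source`.
#' @export
light_source <- function(propagation_bearing, active = TRUE) {
  stopifnot(is.numeric(propagation_bearing), length(propagation_bearing) == 1L)
  structure(list(propagation_bearing = wrap_circle(propagation_bearing),
                 active = isTRUE(active)),
            class = "light_source")
}

#' Per-eye perturbation model
#'
#' Captures the two experimental manipulations of the eyes: anaesthetic
#' silencing scales an eye's input by a gain in `[0, 1]` (0 = fully
#' silenced), and eyecup removal deletes the pigment shield so the eye
#' responds to light from either side (`|sin|` instead of the clamped sine).
#'
#' @param left_gain,right_gain input multipliers in `[0, 1]`.
#' @param left_unshielded,right_unshielded logical; `TRUE` removes the
#'   directional shielding of that eye.
#' @return an object of class `perturbation_config`.
#' @export
perturbation_config <- function(left_gain = 1, right_gain = 1,
                                left_unshielded = FALSE, right_unshielded = FALSE) {
  stopifnot(left_gain >= 0, left_gain <= 1, right_gain >= 0, right_gain <= 1)
  structure(list(left_gain = left_gain, right_gain = right_gain,
                 left_unshielded = isTRUE(left_unshielded),
                 right_unshielded = isTRUE(right_unshielded)),
            class = "perturbation_config")
}

#' Simulation configuration
#'
#' Assembles geometry, behavior, light sources, perturbations and arena
#' settings into one validated object. `"oa1l"` is the one-source
#' orientation assay (rays travelling toward arena bearing 180, i.e. light
#' from arena north); `"oa2l"` adds a second, antiparallel source, which
#' removes the posterior blind field.
#'
#' Distances are in unit steps (one step per wigwag event, the literal
#' reading of the position recursion); with gliding speed ~1 mm/s and mean
#' event interval ~0.95 s one step corresponds to roughly 1 mm, so the
#' default radius 40 matches the 4-cm assay arena.
#'
#' @param assay `"oa1l"` or `"oa2l"`.
#' @param bf_deg binocular field, degrees.
#' @param tau,gain,gain_units,wigwag_enabled,wigwag_angle_sd,wigwag_log_mean,wigwag_log_sd
#'   behavioral parameters; see [behavior_params()].
#' @param perturbation a [perturbation_config()] object.
#' @param arena_radius arena radius in unit steps.
#' @param max_events cap on events per agent (guards non-termination;
#'   trajectories stopped by the cap are flagged, not errors).
#' @param n_agents default cohort size for [run_cohort()].
#' @param seed master seed; per-agent substreams are derived from it by
#'   counter, so enlarging a cohort never reshuffles earlier agents.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(bf_deg = 40, n_agents = 5, seed = 1)
sim_config <- function(assay = c("oa1l", "oa2l"), bf_deg = 40,
                       tau = 0.5, gain = 3, gain_units = "radians",
                       wigwag_enabled = TRUE, wigwag_angle_sd = 18.7,
                       wigwag_log_mean = -0.15, wigwag_log_sd = 0.44,
                       perturbation = perturbation_config(),
                       arena_radius = 40, max_events = 400,
                       n_agents = 60, seed = 1) {
  assay <- match.arg(assay)
  stopifnot(arena_radius > 0, max_events > 0, n_agents >= 1,
            is.numeric(seed), length(seed) == 1L)
  sources <- list(light_source(180))
  if (assay == "oa2l") sources <- c(sources, list(light_source(0)))
  structure(
    list(assay = assay,
         geom = eye_geometry(bf_deg),
         params = behavior_params(tau = tau, gain = gain, gain_units = gain_units,
                                  wigwag_angle_sd = wigwag_angle_sd,
                                  wigwag_log_mean = wigwag_log_mean,
                                  wigwag_log_sd = wigwag_log_sd,
                                  wigwag_enabled = wigwag_enabled),
         sources = sources,
         perturbation = perturbation,
         arena_radius = arena_radius,
         max_events = as.integer(max_events),
         n_agents = as.integer(n_agents),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", toupper(x$assay),
      " bf =", x$geom$binocular_field, "deg",
      " tau =", x$params$tau,
      " wigwag", if (x$params$wigwag_enabled) "on" else "off", "\n")
  cat("  arena radius", x$arena_radius, "steps, max", x$max_events,
      "events,", x$n_agents, "agents, seed", x$seed, "\n")
  invisible(x)
}

#' Light bearing in the body frame
#'
#' Bearing of the incoming light relative to the agent's anterior axis:
#' 0 when heading straight into the source, +/-180 when moving away,
#' positive when the source lies to the agent's right.
#'
#' @param phi heading(s), degrees, arena frame.
#' @param source a [light_source()] object.
#' @return bearing(s) in (-180, 180].
#' @export
light_bearing <- function(phi, source) {
  if (!source$active) stop("light source is not active")
  wrap_signed(source$propagation_bearing + 180 - phi)
}

#' Perceived eye inputs under multiple sources and perturbations
#'
#' Each eye sums its per-source input (clamped sine for a shielded eye,
#' `|sin|` for an unshielded one), the sum is scaled by the eye's gain, and
#' the result is clamped to `[0, 1]`. Summation-then-clamp is the minimal
#' linear combination rule for the two-source assay.
#'
#' @param thetas numeric vector of body-frame light bearings, one per
#'   active source.
#' @param geom an [eye_geometry()] object.
#' @param pert a [perturbation_config()] object.
#' @return named numeric vector `c(left, right)`, both in `[0, 1]`.
#' @export
perceived_inputs <- function(thetas, geom = eye_geometry(),
                             pert = perturbation_config()) {
  stopifnot(length(thetas) >= 1L)
  b <- geom$obliqueness
  raw_l <- -sin_deg(thetas - b)
  raw_r <-  sin_deg(thetas + b)
  l <- if (pert$left_unshielded)  abs(raw_l) else pmax(0, raw_l)
  r <- if (pert$right_unshielded) abs(raw_r) else pmax(0, raw_r)
  c(left  = min(1, pert$left_gain  * sum(pmin(l, 1))),
    right = min(1, pert$right_gain * sum(pmin(r, 1))))
}

#' Advance one wigwag event
#'
#' Draws the inter-event interval and (if enabled) the wigwag swing, moves
#' the agent one unit step along its current heading, and applies the
#' turning rule; the updated heading takes effect at the next event (the
#' position recursion advances with the heading held over the interval
#' just elapsed). Consumes the R random number stream; callers seed it
#' (see [run_agent()]).
#'
#' @param state list with fields `x`, `y`, `phi`, `t`.
#' @param config a [sim_config()] object.
#' @return the updated state list.
#' @export
step_agent <- function(state, config) {
  k <- sample_wigwag_interval(1L, config$params)
  xi <- if (config$params$wigwag_enabled)
    sample_wigwag_angle(1L, config$params) else 0
  active <- vapply(config$sources, function(s) s$active, logical(1))
  inputs <- if (!any(active)) c(left = 0, right = 0) else {
    thetas <- vapply(config$sources[active], function(s)
      light_bearing(state$phi, s), numeric(1))
    perceived_inputs(thetas, config$geom, config$perturbation)
  }
  list(x = state$x + sin_deg(state$phi),
       y = state$y + cos_deg(state$phi),
       phi = turn_update(state$phi, inputs, config$params, xi),
       t = state$t + k)
}

# derive a 32-bit substream seed from the master seed and a counter
substream_seed <- function(seed, index, block = 0L) {
  (as.numeric(seed) + 104729 * as.numeric(index) +
     15485863 * as.numeric(block)) %% 2147483647
}

#' Simulate one agent
#'
#' Starts at the arena center with a heading drawn uniformly on
#' [0, 360) (or `phi0` if given) and iterates [step_agent()] until the
#' agent crosses the arena edge or `max_events` is reached. Fully
#' reproducible: the agent's substream seed is derived from
#' `config$seed` and `agent_index`.
#'
#' @param config a [sim_config()] object.
#' @param agent_index 1-based counter selecting the agent's substream.
#' @param phi0 optional fixed initial heading, degrees (arena frame).
#' @return a `data.frame` of class `planarian_trajectory` with columns
#'   `event`, `t_s`, `x`, `y`, `phi_deg` (event 0 is the initial state)
#'   and attributes `reached_edge`, `agent_index`, `config`.
#' @export
run_agent <- function(config, agent_index = 1L, phi0 = NULL) {
  set.seed(substream_seed(config$seed, agent_index))
  if (is.null(phi0)) phi0 <- stats::runif(1, 0, 360)
  state <- list(x = 0, y = 0, phi = wrap_signed(phi0), t = 0)
  n <- 0L
  rows <- vector("list", config$max_events + 1L)
  rows[[1L]] <- state
  while (sqrt(state$x^2 + state$y^2) < config$arena_radius &&
         n < config$max_events) {
    state <- step_agent(state, config)
    n <- n + 1L
    rows[[n + 1L]] <- state
  }
  rows <- rows[seq_len(n + 1L)]
  traj <- data.frame(
    event = 0:n,
    t_s = vapply(rows, `[[`, numeric(1), "t"),
    x = vapply(rows, `[[`, numeric(1), "x"),
    y = vapply(rows, `[[`, numeric(1), "y"),
    phi_deg = vapply(rows, `[[`, numeric(1), "phi"))
  structure(traj,
            class = c("planarian_trajectory", "data.frame"),
            reached_edge = sqrt(state$x^2 + state$y^2) >= config$arena_radius,
            agent_index = as.integer(agent_index),
            config = config)
}

#' Simulate a cohort of independent agents
#'
#' @param config a [sim_config()] object.
#' @param n cohort size (defaults to `config$n_agents`).
#' @return a list of [run_agent()] trajectories of class
#'   `planarian_cohort`, with the config attached as an attribute.
#' @export
run_cohort <- function(config, n = config$n_agents) {
  stopifnot(n >= 1)
  structure(lapply(seq_len(n), function(i) run_agent(config, i)),
            class = "planarian_cohort", config = config)
}

#' @export
print.planarian_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Cohort of", length(x), "simulated agents (", toupper(cfg$assay),
      ", bf =", cfg$geom$binocular_field, "deg, wigwag",
      if (cfg$params$wigwag_enabled) "on" else "off", ")\n")
  invisible(x)
}

#' Escape-value sweep over binocular-field angles
#'
#' Runs one cohort per binocular-field value and summarizes the escape
#' value (see [escape_value()]). The default configuration disables the
#' wigwag term: the sweep isolates how the visual-field geometry alone
#' shapes escape efficiency, which is where the optimum near a 40-degree
#' binocular field (and the large fluctuations outside it, driven by
#' front-blind starters walking into the light) arises.
#'
#' @param bf_values binocular-field angles, degrees; duplicates are
#'   dropped with a warning.
#' @param n agents per cohort.
#' @param config template [sim_config()]; each cohort gets a fresh seed
#'   block so cohorts are independent but reproducible.
#' @return a `data.frame` with columns `bf_deg`, `n`, `mean_escape`,
#'   `sd_escape`.
#' @export
sweep_binocular_field <- function(bf_values, n = 200,
                                  config = sim_config(wigwag_enabled = FALSE)) {
  if (length(bf_values) == 0) stop("bf_values must be non-empty")
  if (anyDuplicated(bf_values)) {
    warning("duplicate bf values dropped")
    bf_values <- unique(bf_values)
  }
  rows <- lapply(seq_along(bf_values), function(b) {
    cfg <- config
    cfg$geom <- eye_geometry(bf_values[b])
    cfg$seed <- substream_seed(config$seed, 0L, block = b)
    cohort <- run_cohort(cfg, n)
    esc <- vapply(cohort, escape_value, numeric(1), source = cfg$sources[[1]])
    data.frame(bf_deg = bf_values[b], n = n,
               mean_escape = mean(esc), sd_escape = stats::sd(esc))
  })
  do.call(rbind, rows)
}

#' Plot a cohort's trajectories
#'
#' Basic diagnostic plot: all trajectories from the arena center, the
#' arena edge, and the light direction.
#'
#' @param x a `planarian_cohort`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.planarian_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  r <- cfg$arena_radius
  graphics::plot(NA, xlim = c(-r, r) * 1.05, ylim = c(-r, r) * 1.05,
                 asp = 1, xlab = "x (steps)", ylab = "y (steps)", ...)
  a <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(r * cos(a), r * sin(a), col = "grey60")
  for (traj in x) graphics::lines(traj$x, traj$y,
                                  col = grDevices::adjustcolor("black", 0.4))
  graphics::arrows(0, r * 1.02, 0, r * 0.85, length = 0.08, col = "orange", lwd = 2)
  invisible(x)
}
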