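# brute-force oracles kept independent of the closed-form code paths

# first positive bearing where |R - L| reaches tau, by 0.01-degree grid scan;
# NA when no grid point exceeds tau
grid_blind_half_angle <- function(bf, tau, step = 0.01) {
  theta <- seq(step, 180, by = step)
  d <- abs(input_difference(theta, eye_geometry(bf)))
  hit <- which(d >= tau)
  if (length(hit) == 0L) return(NA_real_)
  theta[hit[1L]]
}

# contiguous band of bearings with |R - L| > tau, by grid scan
grid_response_band <- function(bf, tau, step = 0.01) {
  theta <- seq(step, 180, by = step)
  d <- abs(input_difference(theta, eye_geometry(bf)))
  hit <- which(d > tau)
  if (length(hit) == 0L) return(c(NA_real_, NA_real_))
  c(theta[hit[1L]], theta[hit[length(hit)]])
}

# straight unit-step path in a chosen arena direction
straight_path <- function(bearing_deg, n = 20) {
  s <- seq(0, n)
  data.frame(x = s * sinpi(bearing_deg / 180), y = s * cospi(bearing_deg / 180))
}

# wigwag-off twin-tail separation of one simulated cohort
cohort_twin_tail <- function(seed, n = 40, bf = 40) {
  cfg <- sim_config(bf_deg = bf, wigwag_enabled = FALSE, n_agents = n, seed = seed)
  per <- summarize_cohort(run_cohort(cfg))
  twin_tail_separation(per$exit_bearing)$separation
}
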