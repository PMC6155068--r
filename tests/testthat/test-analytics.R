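test_that("circular summary reproduces hand-computed resultant lengths", {
  cs <- circular_summary(c(0, 90))
  expect_equal(cs$resultant_length, sqrt(0.5), tolerance = 1e-9)
  expect_equal(cs$precision_index, 1.2011, tolerance = 1e-4)
  expect_equal(cs$mean_bearing, 45, tolerance = 1e-9)

  concentrated <- circular_summary(rep(123, 7))
  expect_equal(concentrated$resultant_length, 1)
  expect_true(is.infinite(concentrated$precision_index))

  balanced <- circular_summary(c(0, 90, 180, 270))
  expect_equal(balanced$resultant_length, 0, tolerance = 1e-9)
  expect_equal(balanced$precision_index, 0)

  expect_error(circular_summary(numeric(0)))
})

test_that("precision index degrades monotonically with added angular noise", {
  set.seed(31)
  base <- rep(180, 400)
  prec <- vapply(c(2, 8, 20, 45, 80), function(s)
    circular_summary(base + rnorm(400, 0, s))$precision_index, numeric(1))
  expect_true(all(diff(prec) < 0))
})

test_that("escape value projects net displacement onto the light axis", {
  src <- light_source(180)
  expect_equal(escape_value(straight_path(180), src), 1, tolerance = 1e-12)
  expect_equal(escape_value(straight_path(0), src), -1, tolerance = 1e-12)
  expect_equal(escape_value(straight_path(90), src), 0, tolerance = 1e-12)
  expect_error(escape_value(straight_path(0)[1, , drop = FALSE], src))

  # invariance under rigid rotation of trajectory and source together
  set.seed(33)
  traj <- run_agent(sim_config(n_agents = 1, seed = 19), 1)
  e0 <- escape_value(traj, light_source(180))
  for (rot in c(45, 130, 270)) {
    r <- rot * pi / 180
    rotated <- data.frame(x = traj$x * cos(r) + traj$y * sin(r),
                          y = -traj$x * sin(r) + traj$y * cos(r))
    expect_equal(escape_value(rotated, light_source(180 + rot)), e0,
                 tolerance = 1e-9)
  }
})

test_that("twin-tail separation splits exit bearings at 180 degrees", {
  tt <- twin_tail_separation(c(170, 170, 190, 190))
  expect_equal(tt$left_median, 170)
  expect_equal(tt$right_median, 190)
  expect_equal(tt$separation, 20)

  tt2 <- twin_tail_separation(c(150, 160, 170, 190, 200, 210))
  expect_equal(tt2$separation, 40)

  expect_error(twin_tail_separation(c(10, 20, 30)), "non-empty")

  # mirror-symmetrized sample: separation is twice the one-sided median deviation
  set.seed(35)
  right <- runif(51, 181, 250)
  tt3 <- twin_tail_separation(c(right, 360 - right))
  expect_equal(tt3$separation, 2 * abs(median(right) - 180), tolerance = 1e-9)
})

test_that("rose binning uses quadrants centred on the light axes", {
  expect_equal(unname(rose_histogram(rep(180, 9))["away"]), 100)
  expect_equal(unname(rose_histogram(c(10, 350))["toward"]), 100)
  uniform <- rose_histogram(seq(0.5, 359.5, by = 1))
  expect_equal(unname(uniform), rep(25, 4))
  expect_equal(sum(rose_histogram(runif(100, 0, 360))), 100)
  # rotating every bearing by 90 degrees permutes the quadrants cyclically
  set.seed(37)
  b <- runif(200, 0, 360)
  r0 <- rose_histogram(b)
  r90 <- rose_histogram(b + 90)
  expect_equal(unname(r90[c("right", "away", "left", "toward")]), unname(r0))
})

test_that("turn regression contrast favours the responsive light range", {
  x <- seq(10, 170, by = 10)
  perfect <- suppressWarnings(turn_light_regression(x, 0.5 * x + 3))
  expect_equal(unname(perfect), c(1, 1), tolerance = 1e-9)

  set.seed(39)
  noise <- turn_light_regression(runif(1000, -180, 180), runif(1000, -180, 180))
  expect_lt(noise[["r2_all"]], 0.02)

  dat <- generate_turn_dataset(tracking_params(seed = 41), n = 1000)
  r2 <- turn_light_regression(dat$light_angle_deg, dat$turn_angle_deg, split = 130)
  expect_gt(r2[["r2_below_split"]], r2[["r2_all"]])

  expect_error(turn_light_regression(c(1, 2), c(3, 4)), "at least 3")
  expect_error(turn_light_regression(rep(5, 10), rnorm(10)), "degenerate")
})

test_that("wigwag extraction detects reversals of heading change", {
  # constant heading: no events
  none <- extract_wigwag(0:10, rep(45, 11))
  expect_length(none$angles, 0)
  # monotone ramp: turning, but never reversing
  ramp <- extract_wigwag(0:20, seq(0, 100, by = 5))
  expect_length(ramp$angles, 0)
  # sawtooth swinging +/-10 about the track: every swing is a reversal
  saw <- extract_wigwag(0:20, rep(c(-10, 10), length.out = 21))
  expect_true(all(abs(saw$angles) == 20))
  expect_true(all(saw$intervals == 1))
  expect_true(all(diff(sign(saw$angles)) != 0))   # successive swings alternate
})

test_that("generated tracking round-trips through extraction and MLE fitting", {
  # large arena so no track is truncated before the full duration; the
  # deadband is set well below the swing scale because these tracks carry
  # no measurement jitter (a 1-degree deadband would censor real swings)
  params <- tracking_params(duration = 120, arena_radius = 400, seed = 43)
  trk <- generate_tracking(params, n_animals = 12)
  per <- split(as.data.frame(trk), trk$animal_id)
  ww <- lapply(per, function(d) extract_wigwag(d$t_s, d$heading_deg,
                                               deadband = 0.1))
  angles <- unlist(lapply(ww, `[[`, "angles"))
  intervals <- unlist(lapply(ww, `[[`, "intervals"))
  fit <- fit_wigwag_distributions(angles, intervals)
  n_a <- length(angles)
  expect_gt(n_a, 500)
  expect_lt(abs(fit$normal_sd_mle - 18.7), 3 * 18.7 / sqrt(2 * n_a))
  expect_lt(abs(fit$lognormal_mu_mle - (-0.15)),
            3 * 0.44 / sqrt(length(intervals)) + 0.02)
  expect_lt(abs(fit$lognormal_sigma_mle - 0.44),
            3 * 0.44 / sqrt(2 * length(intervals)) + 0.02)
})

test_that("maximum-likelihood fits match their closed forms and an independent fitter", {
  fit <- fit_wigwag_distributions(c(-10, 10), c(1, 1))
  expect_equal(fit$normal_mean_mle, 0)
  expect_equal(fit$normal_sd_mle, 10)   # 1/n MLE variance
  expect_equal(fit$lognormal_mu_mle, 0)
  expect_equal(fit$lognormal_sigma_mle, 0)

  set.seed(45)
  a <- rnorm(10000, 0, 18.7)
  k <- rlnorm(10000, -0.15, 0.44)
  fit2 <- fit_wigwag_distributions(a, k)
  expect_lt(abs(fit2$normal_sd_mle - 18.7), 3 * 18.7 / sqrt(2e4))
  expect_lt(abs(fit2$lognormal_sigma_mle - 0.44), 3 * 0.44 / sqrt(2e4))

  if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    ref_n <- fitdistrplus::fitdist(a, "norm", method = "mle")
    expect_equal(fit2$normal_sd_mle, unname(ref_n$estimate["sd"]), tolerance = 1e-4)
    ref_l <- fitdistrplus::fitdist(k, "lnorm", method = "mle")
    expect_equal(fit2$lognormal_mu_mle, unname(ref_l$estimate["meanlog"]),
                 tolerance = 1e-4)
    expect_equal(fit2$lognormal_sigma_mle, unname(ref_l$estimate["sdlog"]),
                 tolerance = 1e-4)
  }

  expect_error(fit_wigwag_distributions(c(1, 2), c(0, 1)), "strictly positive")
})
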