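test_that("relative torque implements the printed mass-normalised formula", {
  rt <- relative_torque(7, rep(100, 10), 70)
  expect_true(all(rt$series == 10))
  expect_equal(rt$peak, 10)

  expect_equal(relative_torque(7, rep(0, 10), 70)$peak, 0)

  a <- withr::with_seed(1, rnorm(50, sd = 200))
  expect_equal(relative_torque(7, a, 140)$series,
               relative_torque(7, a, 70)$series / 2)
  expect_equal(relative_torque(14, a, 70)$series,
               relative_torque(7, a, 70)$series * 2)

  expect_error(relative_torque(-1, a, 70), "positive")
  expect_error(relative_torque(7, a, 70, integer(0)), "empty phase")
})

test_that("joint power is the torque-velocity product with a bounded peak", {
  p <- joint_power(rep(10, 20), rep(50, 20))
  expect_true(all(p$series == 500))
  expect_equal(p$peak, 500)
  expect_equal(joint_power(rep(10, 5), rep(0, 5))$peak, 0)

  rt <- withr::with_seed(2, rnorm(100))
  av <- withr::with_seed(3, rnorm(100, sd = 50))
  expect_lte(joint_power(rt, av)$peak, max(abs(rt)) * max(abs(av)))
  expect_error(joint_power(rt, av[-1]), "length mismatch")
})

test_that("rate of force development divides peak force by time to peak", {
  fs <- 200
  ramp <- seq(0, 2000, length.out = 0.25 * fs + 1)   # peaks 0.25 s after onset
  fp <- forceplate_series(c(ramp, rep(1000, 20)), fs)
  r <- rate_of_force_development(fp, seq_along(fp$fz))
  expect_equal(r$peak_force, 2000)
  expect_equal(r$time_to_peak, 0.25)
  expect_equal(r$rfd, 8000)

  expect_error(rate_of_force_development(forceplate_series(rep(500, 50), fs),
                                         1:50), "undefined RFD")

  # brute-force scan oracle on a simulated propulsion phase
  sim <- quick_jump("CMJ")
  seg <- segment_jump_phases(sim$markers, sim$force, "CMJ")
  fpm <- kinegen:::fp_at_marker_rate(sim$force, sim$markers)
  idx <- seq.int(phase_frames(seg, "E")[1], max(phase_frames(seg, "C")))
  r2 <- rate_of_force_development(fpm, idx)
  fz <- fpm$fz[idx]
  ipk <- which.max(fz)
  expect_identical(r2$peak_force, fz[ipk])
  expect_equal(r2$rfd, fz[ipk] / ((ipk - 1) / fpm$frequency), tolerance = 1e-12)
})

test_that("reactive indices match their defining ratios", {
  ri <- reactive_indices(0.30, 0.25, 0.25)
  expect_equal(ri$rsi, 1.2)
  expect_equal(reactive_indices(0.30, 0.30, 0.2)$ireaf, 0)
  expect_equal(reactive_indices(0.33, 0.30, 0.2)$ireaf, 0.1, tolerance = 1e-12)
  expect_error(reactive_indices(0.3, 0, 0.2), "domain error")
  expect_error(reactive_indices(0.3, 0.3, 0), "domain error")
})

test_that("trial aggregation averages or picks the best per outcome direction", {
  df <- data.frame(jump_height_ft_m = c(0.30, 0.32, 0.28),
                   sprint_time_s = c(1.2, 1.1, 1.3))
  m <- aggregate_trials(df, "mean")
  expect_equal(m$jump_height_ft_m, 0.30)
  b <- aggregate_trials(df, "best")
  expect_equal(b$jump_height_ft_m, 0.32)
  expect_equal(b$sprint_time_s, 1.1)

  one <- aggregate_trials(df[1, ], "best")
  expect_equal(one$jump_height_ft_m, df$jump_height_ft_m[1])
  expect_identical(aggregate_trials(df[1, ], "mean")$sprint_time_s,
                   df$sprint_time_s[1])
  expect_error(aggregate_trials(df[0, ]), "no trials")
})

test_that("full-chain outcomes agree with ground-truth-side computations", {
  anthro <- anthropometry_config()
  mass <- 57
  for (type in c("CMJ", "DJ")) {
    sim <- quick_jump(type, h = 0.26)
    tr <- sim$truth
    out <- trial_outcomes(sim$markers, sim$force, type, total_mass_kg = mass)

    expect_lt(abs(out$jump_height_ft_m / tr$flight_height - 1), 0.05)
    expect_lt(abs(out$jump_height_marker_m / tr$flight_height - 1), 0.05)
    if (type == "DJ")
      expect_lt(abs(out$contact_time_s / tr$contact_time - 1), 0.05)

    # torque peak via the same operators applied to the true angle series
    f <- sim$markers$frequency
    e_i <- which(tr$time >= tr$phase_times$E[1] & tr$time <= tr$phase_times$E[2])
    for (joint in c("hip", "knee")) {
      ang_true <- if (joint == "hip") tr$hip_angle else tr$knee_angle
      aa <- central_difference(central_difference(
        smooth_lowpass(ang_true, f, 10), f), f)
      rt_true <- relative_torque(joint_segment_mass(anthro, joint, mass),
                                 aa, mass, e_i)$peak
      expect_lt(abs(out[[paste0(joint, "_rt_peak")]] / rt_true - 1), 0.05)
    }
  }
})

test_that("sprint trials flow through the outcome chain", {
  s <- simulate_sprint_trial(sprint_sim_config(v0 = 1, accel = 3))
  out <- trial_outcomes(s$markers, trial_type = "SPRINT")
  expect_lt(abs(out$sprint_time_s - s$truth$interval), 1 / 200)
  expect_true(is.na(out$jump_height_ft_m))
})
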