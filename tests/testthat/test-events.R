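test_that("flight detection finds threshold-crossing intervals with debouncing", {
  fs <- 1000
  fz <- rep(686.7, 2 * fs)
  fz[(1.0 * fs + 1):(1.4 * fs)] <- 0
  fp <- forceplate_series(fz, fs)
  fl <- detect_contact_flight(fp, threshold_n = 10)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$takeoff, 1.0, tolerance = 1.5 / fs)
  expect_equal(fl$landing, 1.4, tolerance = 1.5 / fs)

  expect_equal(nrow(detect_contact_flight(forceplate_series(rep(700, 100), fs))), 0L)

  # sub-debounce dips are ignored
  fz2 <- rep(686.7, fs)
  fz2[501:520] <- 0    # 20 ms dip
  expect_equal(nrow(detect_contact_flight(forceplate_series(fz2, fs))), 0L)
})

test_that("drop-jump contact time is recovered within one frame period", {
  for (ct in c(0.16, 0.20, 0.24)) {
    sim <- simulate_jump_trial(jump_sim_config("DJ", contact_time = ct))
    seg <- segment_jump_phases(sim$markers, sim$force, "DJ")
    expect_lt(abs(seg$contact_time - ct), 1 / sim$markers$frequency)
  }
})

test_that("segmentation produces the phase structure of each jump type", {
  sj <- quick_jump("SJ")
  seg_sj <- segment_jump_phases(sj$markers, sj$force, "SJ")
  expect_false("E" %in% names(seg_sj$phases))
  expect_true(all(c("C", "F2", "L2") %in% names(seg_sj$phases)))

  cmj <- quick_jump("CMJ")
  seg_cmj <- segment_jump_phases(cmj$markers, cmj$force, "CMJ")
  expect_lt(abs(seg_cmj$phases$E[2] - cmj$truth$phase_times$E[2]) *
              cmj$markers$frequency, 1)

  dj <- quick_jump("DJ")
  seg_dj <- segment_jump_phases(dj$markers, dj$force, "DJ")
  labs <- names(seg_dj$phases)
  expect_identical(labs, intersect(c("D", "F1", "L1", "E", "C", "F2", "L2"), labs))
  starts <- vapply(seg_dj$phases, `[`, numeric(1), 1)
  expect_true(all(diff(starts) >= 0))
})

test_that("segmentation is invariant to quiet-standing padding", {
  sim <- quick_jump("CMJ", noise = 0.001, seed = 3)
  seg <- segment_jump_phases(sim$markers, sim$force, "CMJ")

  pad_s <- 0.5
  fm <- sim$markers$frequency
  padded <- sim$markers
  padded$positions <- lapply(padded$positions, function(m)
    rbind(m[rep(1, pad_s * fm), , drop = FALSE], m))
  fpad <- sim$force
  fpad$fz <- c(rep(57 * 9.81, pad_s * fpad$frequency), fpad$fz)
  seg2 <- segment_jump_phases(padded, fpad, "CMJ")

  for (lab in c("E", "C", "F2")) {
    d1 <- diff(seg$phases[[lab]])
    d2 <- diff(seg2$phases[[lab]])
    expect_lt(abs(d1 - d2) * fm, 1.5)
    expect_lt(abs((seg2$phases[[lab]][1] - pad_s) - seg$phases[[lab]][1]) * fm, 1.5)
  }
})

test_that("jump height follows the ballistic closed form and the marker apex", {
  seg04 <- phase_segmentation(list(F2 = c(1, 1.4)), 200, flight_time = 0.4)
  expect_equal(jump_height(seg04, method = "flight_time"), 9.81 * 0.16 / 8)
  expect_equal(jump_height(seg04, method = "flight_time"), 0.1962)

  seg0 <- phase_segmentation(list(F2 = c(1, 1)), 200, flight_time = 0)
  expect_equal(jump_height(seg0, method = "flight_time"), 0)

  expect_error(jump_height(phase_segmentation(list(C = c(0, 1)), 200),
                           method = "flight_time"), "flight")

  for (type in c("CMJ", "SJ", "DJ")) {
    sim <- quick_jump(type, h = 0.28)
    seg <- segment_jump_phases(sim$markers, sim$force, type)
    kin <- linear_kinematics(sim$markers)
    h_ft <- jump_height(seg, method = "flight_time", jump_type = type)
    h_mk <- jump_height(seg, kin, method = "marker", jump_type = type)
    expect_lt(abs(h_ft / h_mk - 1), 0.02)
    expect_lt(abs(h_ft / 0.28 - 1), 0.05)
  }
})

test_that("SSC speed classification brackets 250 ms with the boundary as slow", {
  expect_identical(classify_ssc_speed(0.200), "fast")
  expect_identical(classify_ssc_speed(0.300), "slow")
  expect_identical(classify_ssc_speed(0.250), "slow")
  expect_identical(classify_ssc_speed(c(0.1, 0.3)), c("fast", "slow"))
  expect_error(classify_ssc_speed(0), "positive")
})

test_that("sprint timing interpolates plane crossings", {
  # hand-built linear track: x = 2*(t - 0.5) + 0 crossing x=0 at 0.5 s and
  # x=2.4 at 1.7 s
  fs <- 100
  t <- (0:299) / fs
  x <- 2 * (t - 0.5)
  pos <- list(F_sacrum = cbind(x = x, y = 0, z = 1))
  mk <- marker_trajectories(pos, fs)
  expect_equal(sprint_time(mk, c(0, 2.4)), 1.2, tolerance = 1e-9)

  expect_error(sprint_time(mk, c(1, 1)), "distinct")
  expect_error(sprint_time(mk, c(0, 99)), "never crossed")

  s <- simulate_sprint_trial(sprint_sim_config(v0 = 0, accel = 2, x_start = 0))
  expect_lt(abs(sprint_time(s$markers) - s$truth$interval), 1 / 200)
})
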