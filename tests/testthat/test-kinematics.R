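test_that("zero-phase low-pass has unit DC gain and the designed stopband", {
  expect_lt(max(abs(smooth_lowpass(rep(5, 200), 200, 10) - 5)), 1e-9)

  # two-tone separation: 1 Hz kept within 1%, 50 Hz cut by > 40 dB
  fs <- 200
  t <- seq(0, 5, by = 1 / fs)
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 50 * t)
  y <- smooth_lowpass(x, fs, 10, order = 4)
  amp <- function(sig, f) {
    core <- seq(fs, length(sig) - fs)   # drop the first/last second
    b <- cbind(sin(2 * pi * f * t[core]), cos(2 * pi * f * t[core]))
    sqrt(sum(stats::lm.fit(b, sig[core])$coefficients^2))
  }
  expect_equal(amp(y, 1), 1, tolerance = 0.01)
  expect_lt(amp(y, 50) / amp(x, 50), 10^(-40 / 20))

  expect_error(smooth_lowpass(x, 200, 150), "Nyquist")
  expect_error(smooth_lowpass(x, 200, 0), "parameter error")
})

test_that("central difference is exact on ramps, accurate on sinusoids", {
  f <- 100
  t <- (0:299) / f
  d <- central_difference(3 * t + 2, f)
  expect_equal(d[2:299], rep(3, 298), tolerance = 1e-10)

  expect_true(all(central_difference(rep(7, 50), f) == 0))

  fs <- 1000
  ts <- (0:2000) / fs
  th <- 30 * sin(2 * pi * ts)
  est <- central_difference(th, fs)
  truth <- 30 * 2 * pi * cos(2 * pi * ts)
  interior <- 2:2000
  expect_lt(max(abs(est[interior] - truth[interior])), 0.001 * max(abs(truth)))

  expect_error(central_difference(c(1, 2), f), "3 samples")
})

test_that("differentiate-then-integrate recovers a band-limited signal", {
  fs <- 200
  t <- (0:999) / fs
  x <- 0.3 * sin(2 * pi * 1.5 * t) + 0.1 * cos(2 * pi * 3 * t)
  v <- central_difference(x, fs)
  xi <- x[1] + c(0, cumsum((v[-1] + v[-length(v)]) / 2)) / fs
  expect_lt(max(abs(xi - x)), 0.005 * diff(range(x)))
})

test_that("joint angles follow the inner-angle convention", {
  pos <- list(P = matrix(c(0, 0, 0), 1), V = matrix(c(0, 0, 1), 1),
              D = matrix(c(0, 0, 2), 1))
  pos <- lapply(pos, function(m) m[c(1, 1, 1), , drop = FALSE])  # 3 frames
  mk <- marker_trajectories(pos, 100)
  a <- joint_angle_series(mk, c("P", "V", "D"), cutoff_hz = NULL)
  expect_equal(a$angle, rep(180, 3), tolerance = 1e-9)

  pos$D <- matrix(rep(c(1, 0, 1), each = 3), ncol = 3)
  mk <- marker_trajectories(pos, 100)
  a <- joint_angle_series(mk, c("P", "V", "D"), cutoff_hz = NULL)
  expect_equal(a$angle, rep(90, 3), tolerance = 1e-9)

  # coincident markers are a degenerate geometry, reported with the frame
  pos$D <- pos$V
  mk <- marker_trajectories(pos, 100)
  expect_error(joint_angle_series(mk, c("P", "V", "D")), "frame 1")
})

test_that("joint angles are invariant to rigid rotation and translation", {
  sim <- quick_jump("CMJ")
  base <- joint_angle_series(sim$markers, "knee", "L", cutoff_hz = NULL)$angle
  for (seed in 1:5) {
    rot <- withr::with_seed(seed, {
      th <- runif(3, 0, 2 * pi)
      Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
      Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
      Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
      Rx %*% Ry %*% Rz
    })
    shift <- withr::with_seed(seed + 100, runif(3, -5, 5))
    moved <- sim$markers
    moved$positions <- lapply(moved$positions, function(m)
      sweep(m %*% t(rot), 2, -shift))
    rotated <- joint_angle_series(moved, "knee", "L", cutoff_hz = NULL)$angle
    expect_equal(rotated, base, tolerance = 1e-8)
  }
})

test_that("marker-derived knee angle matches the simulator's ground truth", {
  for (type in c("CMJ", "DJ")) {
    sim <- quick_jump(type)
    for (side in c("L", "R")) {
      ang <- joint_angle_series(sim$markers, "knee", side, cutoff_hz = NULL)
      expect_lt(sqrt(mean((ang$angle - sim$truth$knee_angle)^2)), 1)
    }
    hip <- joint_angle_series(sim$markers, "hip", "L", cutoff_hz = NULL)
    expect_lt(sqrt(mean((hip$angle - sim$truth$hip_angle)^2)), 1)
  }
})

test_that("sacrum linear kinematics track standing, flight and takeoff truth", {
  # a genuinely static trial: constant marker positions, zero velocity
  static <- marker_trajectories(
    list(F_sacrum = matrix(rep(c(0.1, 0, 0.91), each = 200), ncol = 3)), 200)
  kin0 <- linear_kinematics(static)
  expect_lt(max(abs(kin0$velocity[, "z"])), 1e-9)

  still <- quick_jump("CMJ")
  kin <- linear_kinematics(still$markers)
  # quiet standing before the countermovement: near-zero velocity (the
  # zero-phase filter anticipates the upcoming descent slightly)
  stand <- which(still$truth$time > 0.1 & still$truth$time < 0.35)
  expect_lt(max(abs(kin$velocity[stand, "z"])), 2e-3)

  tr <- still$truth
  fl <- which(tr$time > tr$phase_times$F2[1] + 0.12 &
              tr$time < tr$phase_times$F2[2] - 0.12)
  expect_lt(max(abs(kin$acceleration[fl, "z"] + tr$g)) / tr$g, 0.02)

  vmax <- max(kin$velocity[, "z"])
  expect_lt(abs(vmax / tr$v_takeoff - 1), 0.02)

  expect_error(linear_kinematics(still$markers, "nope"), "not present")
})
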