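test_that("jump trials are dynamically consistent with their ground truth", {
  for (type in c("CMJ", "SJ", "DJ")) {
    sim <- quick_jump(type)
    tr <- sim$truth
    fp <- sim$force
    tt <- (seq_along(fp$fz) - 1L) / fp$frequency

    # flight frames carry exactly zero force
    f2 <- tt > tr$phase_times$F2[1] + 2e-3 & tt < tr$phase_times$F2[2] - 2e-3
    expect_true(all(fp$fz[f2] == 0))

    # apex height above the takeoff position equals the configured target
    apex <- max(tr$z)
    expect_equal(apex - tr$takeoff_z, 0.25, tolerance = 1e-3)

    # trapezoid impulse over the propulsion phase matches momentum at takeoff
    imp <- trapz_impulse(fp, tr$phase_times$C[1], tr$phase_times$C[2], 57)
    expect_lt(abs(imp / (57 * tr$v_takeoff) - 1), 0.01)

    # flight height consistency h = v^2 / 2g
    expect_equal(tr$flight_height, tr$v_takeoff^2 / (2 * tr$g), tolerance = 1e-9)

    # phase boundaries are ordered
    b <- do.call(rbind, tr$phase_times)
    expect_true(all(diff(as.vector(t(b))) >= -1e-9))
  }
})

test_that("standing force integrates to body weight and simulation is seed-deterministic", {
  sim <- quick_jump("CMJ", noise = 0.001, seed = 7)
  fp <- sim$force
  tt <- (seq_along(fp$fz) - 1L) / fp$frequency
  idx <- which(tt <= 0.45)
  area <- sum((fp$fz[idx][-1] + fp$fz[idx][-length(idx)]) / 2) / fp$frequency
  expect_lt(abs(area / (57 * 9.81 * tt[max(idx)]) - 1), 0.005)

  sim2 <- quick_jump("CMJ", noise = 0.001, seed = 7)
  expect_identical(sim$markers$positions, sim2$markers$positions)
  expect_identical(sim$force$fz, sim2$force$fz)
  sim3 <- quick_jump("CMJ", noise = 0.001, seed = 8)
  expect_false(identical(sim$markers$positions, sim3$markers$positions))
})

test_that("degenerate jump configurations are rejected", {
  expect_error(jump_sim_config("CMJ", target_flight_height = -0.1), "config error")
  expect_error(simulate_jump_trial(jump_sim_config("CMJ", countermovement_depth = 0.8)),
               "config error")
  expect_error(simulate_jump_trial(
    jump_sim_config("CMJ", countermovement_depth = 0.35, ecc_time = 0.2)),
    "config error")
  expect_error(jump_sim_config("DJ", contact_time = 0), "config error")
})

test_that("sprint trials hit the closed-form gate times", {
  s <- simulate_sprint_trial(sprint_sim_config(v0 = 5, accel = 0, x_start = 0))
  expect_equal(s$truth$interval, 1.0, tolerance = 1e-12)
  expect_equal(sprint_time(s$markers), 1.0, tolerance = 1e-3)

  s2 <- simulate_sprint_trial(sprint_sim_config(v0 = 0, accel = 2, x_start = 0))
  expect_equal(s2$truth$interval, sqrt(2 * 5 / 2), tolerance = 1e-12)
  expect_equal(sprint_time(s2$markers), sqrt(5), tolerance = 1 / 200)

  for (seed in 1:10) {
    s3 <- simulate_sprint_trial(sprint_sim_config(v0 = 1, accel = 3,
                                                  noise_sd = 0.002, seed = seed))
    expect_lt(abs(sprint_time(s3$markers) - s3$truth$interval), 1 / 200)
  }

  expect_error(sprint_sim_config(v0 = 0, accel = 0), "config error")
})

test_that("cohort genotypes follow Hardy-Weinberg sampling with recoverable effects", {
  coh <- simulate_cohort(cohort_sim_config(n = 1e4, maf_ace = 0.5, seed = 3))
  se3 <- 3 * sqrt(0.5 * 0.5 / (2 * 1e4))
  expect_lt(abs(coh$truth$realized_allele_freq[["ace_d"]] - 0.5), se3)

  # null architecture: no group separation beyond chance
  null <- simulate_cohort(cohort_sim_config(n = 600, effect_locus = "none", seed = 4))
  an <- genotype_anova(null$outcomes[[2]], null$genotypes$ace)
  expect_gt(an$p_value, 0.01)

  # additive shift: regression on the 0/0.5/1 code recovers the full
  # homozygote-to-homozygote difference
  eff <- simulate_cohort(cohort_sim_config(n = 1000, effect_locus = "ace",
                                           model = "additive", effect_size = 1,
                                           outcome_sd = 1, seed = 5))
  code <- code_genetic_model(eff$genotypes$ace, genetic_model_coding("additive", "ace"))
  fit <- lm(eff$outcomes[[2]] ~ code)
  ci <- confint(fit)["code", ]
  expect_gt(1, ci[1])
  expect_lt(1, ci[2])
})

test_that("simulated cohorts pass the HWE test in nearly all seeds", {
  ok <- vapply(1:100, function(s) {
    coh <- simulate_cohort(cohort_sim_config(n = 300, maf_ace = 0.4, seed = s))
    cnt <- as.integer(table(factor(coh$genotypes$ace, levels = c("II", "ID", "DD"))))
    hwe_chi_square(cnt)$p_value >= 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.98)
})

test_that("cohort Cohen's f parameterisation produces the requested separation", {
  coh <- simulate_cohort(cohort_sim_config(n = 5e4, effect_locus = "ace",
                                           model = "additive", cohens_f = 0.25,
                                           outcome_sd = 2, seed = 9))
  g <- coh$genotypes$ace
  y <- coh$outcomes[[2]]
  gm <- tapply(y, g, mean)
  wt <- table(g) / length(g)
  sd_b <- sqrt(sum(wt * (gm - sum(wt * gm))^2))
  f_hat <- sd_b / 2
  expect_equal(f_hat, 0.25, tolerance = 0.03)
})
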