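# shared fixture builders: everything is generated in code at test time

quick_jump <- function(type = "CMJ", h = 0.25, noise = 0, seed = 1L, ...) {
  simulate_jump_trial(jump_sim_config(
    type, target_flight_height = h,
    countermovement_depth = if (type == "SJ") NULL else 0.30,
    noise_sd = noise, seed = seed, ...))
}

# random-but-reproducible trial drawn from the study conditions: jump type,
# flight height 0.15-0.35 m, marker noise up to 2 mm
draw_trial <- function(rep, noise_every_other = TRUE) {
  set.seed(9000 + rep)
  type <- sample(c("CMJ", "SJ", "DJ"), 1)
  h <- runif(1, 0.15, 0.35)
  ns <- if (noise_every_other && rep %% 2 == 0) runif(1, 5e-4, 2e-3) else 0
  cfg <- jump_sim_config(type, target_flight_height = h,
                         countermovement_depth = if (type == "SJ") NULL
                                                 else runif(1, 0.25, 0.35),
                         noise_sd = ns, seed = rep)
  list(sim = simulate_jump_trial(cfg), type = type, h = h, noise = ns)
}

trapz_impulse <- function(fp, t0, t1, mass, g = 9.81) {
  tt <- (seq_along(fp$fz) - 1L) / fp$frequency
  idx <- which(tt >= t0 & tt <= t1)
  sum((fp$fz[idx][-1] + fp$fz[idx][-length(idx)]) / 2 - mass * g) / fp$frequency
}

phase_frame_errors <- function(seg, truth, frequency) {
  errs <- c()
  for (lab in names(truth$phase_times)) {
    if (!lab %in% names(seg$phases)) next
    errs[lab] <- max(abs(seg$phases[[lab]] - truth$phase_times[[lab]])) * frequency
  }
  errs
}

random_marker_set <- function(n_frames = 5, n_markers = 3, seed = 1) {
  withr::with_seed(seed, {
    pos <- lapply(seq_len(n_markers), function(i)
      matrix(rnorm(n_frames * 3), ncol = 3))
    names(pos) <- paste0("M", seq_len(n_markers))
    marker_trajectories(pos, frequency = 150)
  })
}
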