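# Physics-based generators for jump trials, sprint trials and genotyped
# cohorts. Every generated trial carries a ground-truth record so downstream
# detection/estimation stages can be tested against known answers.

#' Jump-trial simulation configuration
#'
#' Defaults describe a moderately trained adult female (body mass 57 kg,
#' BMI ~ 23) performing ballistic vertical jumps captured at 200 Hz.
#'
#' @param jump_type "SJ", "CMJ" or "DJ".
#' @param target_flight_height flight height of the jump apex above the
#'   takeoff position (m).
#' @param countermovement_depth CMJ descent depth / SJ held-squat depth (m).
#'   `NULL` for SJ picks the depth at which the knee is at 90 degrees.
#'   Ignored for DJ (the eccentric depth follows from box height and contact
#'   time).
#' @param contact_time DJ ground-contact duration (s).
#' @param box_height DJ box height (m, default 0.20).
#' @param segment_lengths named list: trunk, thigh, shank, foot (m).
#' @param body_mass total body mass (kg).
#' @param frequency camera sampling rate (Hz).
#' @param force_frequency force-plate sampling rate (Hz); plates typically
#'   run several times faster than the cameras.
#' @param noise_sd isotropic Gaussian marker jitter (m); 0 = noise-free.
#' @param seed integer seed for the marker noise; `NULL` uses the current RNG
#'   state.
#' @param stand_time,ecc_time,landing_time,tail_time phase durations (s) for
#'   the initial hold, CMJ eccentric descent, landing cushioning, and final
#'   hold.
#' @param g gravitational acceleration (m s^-2).
#' @return a `jump_sim_config` list.
#' @export
jump_sim_config <- function(jump_type = c("CMJ", "SJ", "DJ"),
                            target_flight_height = 0.25,
                            countermovement_depth = 0.30,
                            contact_time = 0.18,
                            box_height = 0.20,
                            segment_lengths = list(trunk = 0.50, thigh = 0.41,
                                                   shank = 0.42, foot = 0.24),
                            body_mass = 57,
                            frequency = 200,
                            force_frequency = 1000,
                            noise_sd = 0,
                            seed = NULL,
                            stand_time = 0.5,
                            ecc_time = 0.5,
                            landing_time = 0.15,
                            tail_time = 0.3,
                            g = 9.81) {
  jump_type <- match.arg(jump_type)
  sl <- segment_lengths
  if (any(unlist(sl) <= 0) || body_mass <= 0 || frequency <= 0 ||
      target_flight_height <= 0 || g <= 0)
    stop("config error: lengths, masses, frequency, flight height and g must be positive",
         call. = FALSE)
  if (jump_type == "DJ" && (is.null(contact_time) || contact_time <= 0))
    stop("config error: DJ requires contact_time > 0", call. = FALSE)
  if (box_height < 0) stop("config error: box_height must be >= 0", call. = FALSE)
  if (jump_type == "SJ" && is.null(countermovement_depth)) {
    # held 90-degree squat: hip-ankle distance sqrt(thigh^2 + shank^2)
    countermovement_depth <- (sl$thigh + sl$shank) - sqrt(sl$thigh^2 + sl$shank^2)
  }
  cfg <- list(
    jump_type = jump_type, target_flight_height = target_flight_height,
    countermovement_depth = countermovement_depth, contact_time = contact_time,
    box_height = box_height, segment_lengths = sl, body_mass = body_mass,
    frequency = frequency, force_frequency = force_frequency,
    noise_sd = noise_sd, seed = seed,
    stand_time = stand_time, ecc_time = ecc_time, landing_time = landing_time,
    tail_time = tail_time, g = g,
    ankle_height = 0.08, pelvic_half_width = 0.12,
    sacrum_offset = c(-0.10, 0), asis_offset = c(0.10, 0.10)
  )
  class(cfg) <- "jump_sim_config"
  cfg
}

# piecewise segment descriptor: closed-form z(t), vz(t), az(t) on [0, dur)
seg_piece <- function(dur, zf, vf, af, contact, surface = 0) {
  list(dur = dur, zf = zf, vf = vf, af = af, contact = contact, surface = surface)
}

piece_const <- function(dur, z0, contact, surface = 0) {
  force(z0)
  seg_piece(dur,
            function(s) rep(z0, length(s)),
            function(s) rep(0, length(s)),
            function(s) rep(0, length(s)),
            contact, surface)
}

# cosine descent: z0 -> z0 - depth over te, v = 0 at both ends
piece_descent <- function(te, z0, depth) {
  seg_piece(te,
            function(s) z0 - depth / 2 * (1 - cos(pi * s / te)),
            function(s) -depth * pi / (2 * te) * sin(pi * s / te),
            function(s) -depth * pi^2 / (2 * te^2) * cos(pi * s / te),
            contact = TRUE)
}

# quarter-sine velocity ramp 0 -> v_to over tc, rising 2*v_to*tc/pi;
# acceleration starts at its peak v_to*pi/(2*tc) (force rises through the
# eccentric/concentric transition) and reaches 0 at takeoff
piece_push <- function(tc, z0, v_to) {
  seg_piece(tc,
            function(s) z0 + v_to * 2 * tc / pi * (1 - cos(pi * s / (2 * tc))),
            function(s) v_to * sin(pi * s / (2 * tc)),
            function(s) v_to * pi / (2 * tc) * cos(pi * s / (2 * tc)),
            contact = TRUE)
}

# ballistic flight from z0 with initial vertical velocity v0
piece_flight <- function(dur, z0, v0, g) {
  seg_piece(dur,
            function(s) z0 + v0 * s - g * s^2 / 2,
            function(s) v0 - g * s,
            function(s) rep(-g, length(s)),
            contact = FALSE)
}

# landing cushion: velocity -v_in -> 0 over tl (quarter-cosine), descending
# 2*v_in*tl/pi; deceleration peaks at the end, so the height minimum that
# closes the cushion is sharply defined
piece_cushion <- function(tl, z0, v_in) {
  seg_piece(tl,
            function(s) z0 - v_in * 2 * tl / pi * sin(pi * s / (2 * tl)),
            function(s) -v_in * cos(pi * s / (2 * tl)),
            function(s) v_in * pi / (2 * tl) * sin(pi * s / (2 * tl)),
            contact = TRUE)
}

#' Simulate one ballistic jump trial
#'
#' Builds a piecewise-smooth sacrum/pelvis trajectory for the requested jump
#' type, poses a planar two-link (shank + thigh) leg chain under it by inverse
#' kinematics (foot fixed during ground contact, chain frozen and translating
#' during flight), mirrors the chain across a fixed pelvic width, and
#' synthesises the vertical ground-reaction force as
#' `fz = body_mass * (g + az)` during contact (0 in flight), with `az` the
#' closed-form second derivative of the simulated centre-of-mass trajectory
#' (proxied by the sacrum). Optional isotropic Gaussian jitter is added to
#' every marker coordinate.
#'
#' @param config a [jump_sim_config()].
#' @return list with elements `markers` ([marker_trajectories()]), `force`
#'   ([forceplate_series()]) and `truth` (a `sim_ground_truth` list holding
#'   phase boundary times, takeoff velocity, flight height and time, DJ
#'   contact time, true sacrum z/vz/az and hip/knee angle series, standing and
#'   takeoff heights, and `g`).
#' @export
simulate_jump_trial <- function(config) {
  stopifnot(inherits(config, "jump_sim_config"))
  cf <- config
  sl <- cf$segment_lengths
  g <- cf$g
  v_to <- sqrt(2 * g * cf$target_flight_height)
  z0 <- cf$ankle_height + sl$thigh + sl$shank      # standing pelvis height
  z_min_geom <- cf$ankle_height + abs(sl$thigh - sl$shank) + 0.02

  pieces <- list()
  phases <- list()   # label -> c(start, end) seconds
  t_cursor <- 0
  add <- function(piece, label = NULL) {
    pieces[[length(pieces) + 1L]] <<- piece
    if (!is.null(label)) phases[[label]] <<- c(t_cursor, t_cursor + piece$dur)
    t_cursor <<- t_cursor + piece$dur
  }

  tf <- 2 * v_to / g
  contact_time <- NA_real_
  if (cf$jump_type == "CMJ") {
    d <- cf$countermovement_depth
    if (z0 - d < z_min_geom)
      stop("config error: countermovement_depth incompatible with segment lengths",
           call. = FALSE)
    # the descent's peak deceleration d*pi^2/(2*te^2) must stay below g or
    # the athlete would leave the plate (fz < 0) while "unweighting"
    if (d * pi^2 / (2 * cf$ecc_time^2) > 0.95 * g)
      stop("config error: eccentric descent too violent (increase ecc_time or reduce depth)",
           call. = FALSE)
    tc <- pi * d / (2 * v_to)
    add(piece_const(cf$stand_time, z0, contact = TRUE), "L1")
    add(piece_descent(cf$ecc_time, z0, d), "E")
    add(piece_push(tc, z0 - d, v_to), "C")
    add(piece_flight(tf, z0, v_to, g), "F2")
    add(piece_cushion(cf$landing_time, z0, v_to), "L2")
    add(piece_const(cf$tail_time, z0 - 2 * v_to * cf$landing_time / pi, contact = TRUE))
    z_to <- z0
  } else if (cf$jump_type == "SJ") {
    d <- cf$countermovement_depth
    if (z0 - d < z_min_geom)
      stop("config error: squat depth incompatible with segment lengths",
           call. = FALSE)
    tc <- pi * d / (2 * v_to)
    add(piece_const(cf$stand_time, z0 - d, contact = TRUE))
    add(piece_push(tc, z0 - d, v_to), "C")
    add(piece_flight(tf, z0, v_to, g), "F2")
    add(piece_cushion(cf$landing_time, z0, v_to), "L2")
    add(piece_const(cf$tail_time, z0 - 2 * v_to * cf$landing_time / pi, contact = TRUE))
    z_to <- z0
  } else { # DJ
    bh <- cf$box_height
    v_td <- sqrt(2 * g * bh)
    tE <- cf$contact_time / 2
    tC <- cf$contact_time / 2
    z_lo <- z0 - 2 * v_td * tE / pi
    if (z_lo < z_min_geom)
      stop("config error: contact_time/box_height drive the pelvis below the geometric minimum",
           call. = FALSE)
    z_to <- z_lo + 2 * v_to * tC / pi
    contact_time <- cf$contact_time
    add(piece_const(cf$stand_time, z0 + bh, contact = FALSE, surface = bh), "D")
    add(piece_flight(v_td / g, z0 + bh, 0, g), "F1")
    add(piece_cushion(tE, z0, v_td), "E")
    add(piece_push(tC, z_lo, v_to), "C")
    add(piece_flight(tf, z_to, v_to, g), "F2")
    add(piece_cushion(cf$landing_time, z_to, v_to), "L2")
    add(piece_const(cf$tail_time, z_to - 2 * v_to * cf$landing_time / pi, contact = TRUE))
  }
  # DJ: L1 is the landing instant opening ground contact (start of E)
  if (cf$jump_type == "DJ") {
    phases <- c(phases[c("D", "F1")],
                list(L1 = c(phases$E[1], phases$E[1])),
                phases[c("E", "C", "F2", "L2")])
  }

  # sample the piecewise trajectory on an arbitrary clock
  starts <- cumsum(c(0, vapply(pieces, `[[`, numeric(1), "dur")))
  sample_profile <- function(freq) {
    dt <- 1 / freq
    n <- floor(t_cursor / dt) + 1L
    t <- (seq_len(n) - 1L) * dt
    z <- vz <- az <- numeric(n)
    contact <- logical(n)
    surface <- numeric(n)
    for (k in seq_along(pieces)) {
      sel <- t >= starts[k] & (if (k == length(pieces)) t <= starts[k + 1] + 1e-12
                               else t < starts[k + 1])
      if (!any(sel)) next
      s <- t[sel] - starts[k]
      p <- pieces[[k]]
      z[sel] <- p$zf(s); vz[sel] <- p$vf(s); az[sel] <- p$af(s)
      contact[sel] <- p$contact
      surface[sel] <- p$surface
    }
    list(t = t, n = n, z = z, vz = vz, az = az, contact = contact,
         surface = surface)
  }
  mp <- sample_profile(cf$frequency)
  t <- mp$t; n <- mp$n; z <- mp$z; vz <- mp$vz; az <- mp$az
  contact <- mp$contact; surface <- mp$surface

  # force plate on its own (faster) clock; it sees only floor contact
  # (box standing happens off-plate)
  fp_prof <- sample_profile(cf$force_frequency)
  fz <- ifelse(fp_prof$contact & fp_prof$surface == 0,
               cf$body_mass * (g + fp_prof$az), 0)
  on_plate <- contact & surface == 0
  phases$L2[2] <- t[n]   # landing phase runs to the end of the recording

  # leg-chain pose: hip-to-ankle distance per frame
  Lt <- sl$thigh; Ls <- sl$shank
  ankle_z <- numeric(n)
  ankle_z[contact] <- surface[contact] + cf$ankle_height
  if (any(!contact)) {
    # frozen chain in flight: keep the hip-ankle distance from the contact
    # frame preceding each flight run (standing extension before the first)
    d_frozen <- z0 - cf$ankle_height
    for (i in which(!contact)) {
      if (i > 1L && contact[i - 1L]) d_frozen <- z[i - 1L] - ankle_z[i - 1L]
      ankle_z[i] <- z[i] - d_frozen
    }
  }
  d_ha <- pmin(z - ankle_z, Lt + Ls)          # hip-ankle distance
  a_along <- (d_ha^2 + Lt^2 - Ls^2) / (2 * d_ha)
  e_perp <- sqrt(pmax(Lt^2 - a_along^2, 0))   # anterior knee offset
  knee_x <- e_perp
  knee_z <- z - a_along

  knee_deg <- acos(pmin(pmax((Lt^2 + Ls^2 - d_ha^2) / (2 * Lt * Ls), -1), 1)) * 180 / pi
  # hip inner angle at the trochanter between ASIS and condyle directions
  hip_deg <- vapply(seq_len(n), function(i) {
    u <- c(cf$asis_offset[1], cf$asis_offset[2])
    v <- c(knee_x[i], knee_z[i] - z[i])
    ang <- acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
    ang * 180 / pi
  }, numeric(1))

  w <- cf$pelvic_half_width
  mk <- function(x, y, zz) cbind(x = rep_len(x, n), y = rep_len(y, n), z = zz)
  foot_x <- 0.7 * sl$foot
  positions <- list(
    A5thMet_L = mk(foot_x, -w, ankle_z - cf$ankle_height + 0.02),
    A5thMet_R = mk(foot_x, w, ankle_z - cf$ankle_height + 0.02),
    Bmalleolus_L = mk(0, -w, ankle_z),
    Bmalleolus_R = mk(0, w, ankle_z),
    Ccondyle_L = cbind(x = knee_x, y = rep(-w, n), z = knee_z),
    Ccondyle_R = cbind(x = knee_x, y = rep(w, n), z = knee_z),
    Dtrochanter_L = mk(0, -w, z),
    Dtrochanter_R = mk(0, w, z),
    E_ASIS_L = mk(cf$asis_offset[1], -w, z + cf$asis_offset[2]),
    E_ASIS_R = mk(cf$asis_offset[1], w, z + cf$asis_offset[2]),
    F_sacrum = mk(cf$sacrum_offset[1], 0, z)
  )
  if (cf$noise_sd > 0) {
    add_noise <- function() {
      for (m in names(positions))
        positions[[m]] <<- positions[[m]] +
          matrix(stats::rnorm(3L * n, sd = cf$noise_sd), ncol = 3)
    }
    if (is.null(cf$seed)) add_noise() else withr::with_seed(cf$seed, add_noise())
  }

  markers <- marker_trajectories(positions, cf$frequency,
                                 meta = list(trial_type = cf$jump_type))
  force <- forceplate_series(fz, cf$force_frequency)
  truth <- structure(list(
    jump_type = cf$jump_type,
    phase_times = phases,
    flight_height = cf$target_flight_height,
    v_takeoff = v_to,
    flight_time = tf,
    contact_time = contact_time,
    standing_z = z0,
    takeoff_z = z_to,
    time = t, z = z, vz = vz, az = az,
    hip_angle = hip_deg, knee_angle = knee_deg,
    contact = on_plate,
    g = g
  ), class = "sim_ground_truth")
  list(markers = markers, force = force, truth = truth)
}

#' Sprint-trial simulation configuration
#'
#' Constant-acceleration horizontal profile `x(t) = x_start + v0 t + a t^2/2`
#' for a short sprint through two timing planes.
#'
#' @param v0 initial horizontal speed (m s^-1).
#' @param accel constant acceleration (m s^-2).
#' @param x_start sacrum x at t = 0 (m); gates sit at `gates` (m).
#' @param gates positions of the two timing planes (m).
#' @param frequency sampling rate (Hz).
#' @param noise_sd marker jitter sd (m).
#' @param seed RNG seed for the jitter.
#' @param overshoot distance run past the far gate (m).
#' @export
sprint_sim_config <- function(v0 = 0, accel = 4, x_start = -0.5,
                              gates = c(0, 5), frequency = 200,
                              noise_sd = 0, seed = NULL, overshoot = 0.5) {
  if (frequency <= 0) stop("config error: frequency must be positive", call. = FALSE)
  if (v0 < 0) stop("config error: v0 must be non-negative", call. = FALSE)
  if (v0 <= 0 && accel <= 0)
    stop("config error: trial cannot cover the gates with no speed and no acceleration",
         call. = FALSE)
  if (x_start > min(gates))
    stop("config error: start must lie before the first gate", call. = FALSE)
  structure(list(v0 = v0, accel = accel, x_start = x_start, gates = sort(gates),
                 frequency = frequency, noise_sd = noise_sd, seed = seed,
                 overshoot = overshoot),
            class = "sprint_sim_config")
}

#' Simulate one short-sprint trial
#'
#' The whole standing marker chain translates along x with the configured
#' constant-acceleration profile; ground-truth gate crossing times are solved
#' in closed form.
#'
#' @param config a [sprint_sim_config()].
#' @return list with `markers` and `truth` (crossing times per gate and the
#'   gate interval).
#' @export
simulate_sprint_trial <- function(config) {
  stopifnot(inherits(config, "sprint_sim_config"))
  cf <- config
  cross_time <- function(xg) {
    dx <- xg - cf$x_start
    if (dx <= 0) return(0)
    if (cf$accel == 0) return(dx / cf$v0)
    (-cf$v0 + sqrt(cf$v0^2 + 2 * cf$accel * dx)) / cf$accel
  }
  t_gates <- vapply(cf$gates, cross_time, numeric(1))
  t_end <- cross_time(max(cf$gates) + cf$overshoot)
  dt <- 1 / cf$frequency
  n <- floor(t_end / dt) + 2L
  t <- (seq_len(n) - 1L) * dt
  x <- cf$x_start + cf$v0 * t + cf$accel * t^2 / 2

  sl <- list(thigh = 0.41, shank = 0.42)
  ankle_h <- 0.08
  z0 <- ankle_h + sl$thigh + sl$shank
  w <- 0.12
  mk <- function(dx, y, zz) cbind(x = x + dx, y = rep(y, n), z = rep(zz, n))
  positions <- list(
    A5thMet_L = mk(0.17, -w, 0.02), A5thMet_R = mk(0.17, w, 0.02),
    Bmalleolus_L = mk(0, -w, ankle_h), Bmalleolus_R = mk(0, w, ankle_h),
    Ccondyle_L = mk(0, -w, ankle_h + sl$shank),
    Ccondyle_R = mk(0, w, ankle_h + sl$shank),
    Dtrochanter_L = mk(0, -w, z0), Dtrochanter_R = mk(0, w, z0),
    E_ASIS_L = mk(0.10, -w, z0 + 0.10), E_ASIS_R = mk(0.10, w, z0 + 0.10),
    # the sacrum is the gate-timing reference: keep it at the chain origin
    # along the running direction
    F_sacrum = mk(0, 0, z0)
  )
  if (cf$noise_sd > 0) {
    add_noise <- function() {
      for (m in names(positions))
        positions[[m]] <<- positions[[m]] +
          matrix(stats::rnorm(3L * n, sd = cf$noise_sd), ncol = 3)
    }
    if (is.null(cf$seed)) add_noise() else withr::with_seed(cf$seed, add_noise())
  }
  markers <- marker_trajectories(positions, cf$frequency,
                                 meta = list(trial_type = "SPRINT"))
  truth <- structure(list(
    gates = cf$gates, gate_times = t_gates,
    interval = diff(t_gates), time = t, x = x
  ), class = "sim_ground_truth")
  list(markers = markers, truth = truth)
}

#' Cohort simulation configuration
#'
#' Genotypes are drawn allele-wise so Hardy-Weinberg proportions hold by
#' construction; a configurable genetic architecture shifts one outcome.
#'
#' @param n number of participants (>= 2).
#' @param maf_actn3 frequency of the ACTN3 X allele.
#' @param maf_ace frequency of the ACE D allele.
#' @param effect_locus locus carrying the effect ("ace", "actn3" or "none").
#' @param model genetic architecture: "additive", "I_dominant" or
#'   "D_dominant" (for ACTN3 read I as R and D as X).
#' @param effect_size mean difference between the two extreme homozygote
#'   groups, in outcome units.
#' @param cohens_f alternative effect parameterisation: if non-`NULL`,
#'   `effect_size` is chosen so the expected between-genotype standard
#'   deviation (Hardy-Weinberg weights) is `cohens_f * outcome_sd`.
#' @param outcome_name name of the shifted outcome column.
#' @param outcome_mean,outcome_sd baseline outcome mean and residual sd.
#' @param seed RNG seed.
#' @export
cohort_sim_config <- function(n = 283, maf_actn3 = 0.5, maf_ace = 0.5,
                              effect_locus = c("ace", "actn3", "none"),
                              model = c("additive", "I_dominant", "D_dominant"),
                              effect_size = 0, cohens_f = NULL,
                              outcome_name = "hip_rt_peak_ecc",
                              outcome_mean = 10, outcome_sd = 2,
                              seed = 1L) {
  effect_locus <- match.arg(effect_locus)
  model <- match.arg(model)
  if (n < 2) stop("config error: n must be >= 2", call. = FALSE)
  for (p in c(maf_actn3, maf_ace))
    if (p <= 0 || p >= 1)
      stop("config error: allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  if (outcome_sd <= 0) stop("config error: outcome_sd must be positive", call. = FALSE)
  structure(list(n = as.integer(n), maf_actn3 = maf_actn3, maf_ace = maf_ace,
                 effect_locus = effect_locus, model = model,
                 effect_size = effect_size, cohens_f = cohens_f,
                 outcome_name = outcome_name, outcome_mean = outcome_mean,
                 outcome_sd = outcome_sd, seed = seed),
            class = "cohort_sim_config")
}

#' Simulate a genotyped cohort with a known embedded effect
#'
#' Draws two alleles per participant per locus (hence genotype frequencies
#' p^2, 2pq, q^2 in expectation), generates covariates, and builds the target
#' outcome as `baseline + effect_size * model_code(genotype) + N(0, sd)`.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `genotypes` (a `genotype_table`), `outcomes` (data frame
#'   id + outcome column) and `truth` (realised allele frequencies,
#'   per-genotype shifts, the effect coding used).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cf <- config
  run <- function() {
    n <- cf$n
    draw_geno <- function(q, labels) {
      # q = frequency of the second (variant) allele; labels ordered
      # (ref hom, het, variant hom)
      k <- stats::rbinom(n, 2, q)
      factor(labels[k + 1L], levels = labels)
    }
    actn3 <- draw_geno(cf$maf_actn3, c("RR", "RX", "XX"))
    ace <- draw_geno(cf$maf_ace, c("II", "ID", "DD"))
    body_mass <- stats::rnorm(n, 57, 6)
    body_mass[body_mass < 40] <- 40
    height <- stats::rnorm(n, 1.60, 0.05)
    age <- round(stats::runif(n, 18, 45))
    geno <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      actn3 = as.character(actn3), ace = as.character(ace),
      body_mass_kg = round(body_mass, 1),
      height_m = round(height, 2),
      bmi = round(body_mass / height^2, 1),
      age = age, sex = "F",
      parq_positive = FALSE, power_sport = FALSE,
      stringsAsFactors = FALSE
    )
    eff_geno <- switch(cf$effect_locus,
                       ace = as.character(ace), actn3 = as.character(actn3),
                       none = NULL)
    shifts <- setNames(numeric(n), NULL)
    code <- numeric(n)
    effect_size <- cf$effect_size
    if (!is.null(eff_geno)) {
      coding <- genetic_model_coding(cf$model,
                                     locus = if (cf$effect_locus == "ace") "ace" else "actn3")
      code <- code_genetic_model(eff_geno, coding)
      if (!is.null(cf$cohens_f)) {
        q <- if (cf$effect_locus == "ace") cf$maf_ace else cf$maf_actn3
        wts <- c((1 - q)^2, 2 * q * (1 - q), q^2)
        cd <- unname(unlist(coding$code_map))
        mu <- sum(wts * cd)
        sd_code <- sqrt(sum(wts * (cd - mu)^2))
        effect_size <- cf$cohens_f * cf$outcome_sd / sd_code
      }
      shifts <- effect_size * code
    }
    outcome <- cf$outcome_mean + shifts + stats::rnorm(n, 0, cf$outcome_sd)
    outcomes <- data.frame(id = geno$id, value = outcome, stringsAsFactors = FALSE)
    names(outcomes)[2] <- cf$outcome_name
    realized_freq <- c(
      actn3_x = mean(c(RR = 0, RX = 0.5, XX = 1)[geno$actn3]),
      ace_d = mean(c(II = 0, ID = 0.5, DD = 1)[geno$ace])
    )
    list(
      genotypes = validate_genotype_table(geno),
      outcomes = outcomes,
      truth = list(realized_allele_freq = realized_freq,
                   effect_locus = cf$effect_locus, model = cf$model,
                   effect_size = effect_size,
                   genotype_shift = if (!is.null(eff_geno))
                     effect_size * unlist(genetic_model_coding(
                       cf$model,
                       locus = if (cf$effect_locus == "ace") "ace" else "actn3")$code_map)
                   else NULL)
    )
  }
  if (is.null(cf$seed)) run() else withr::with_seed(cf$seed, run())
}
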