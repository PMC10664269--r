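# Per-trial performance outcomes and their aggregation across a participant's
# trials: relative torque and power at hip and knee, rate of force
# development, reactive indices, jump heights and timing.
#
# Relative torque is implemented literally as printed in jump-testing
# practice: segmental mass (kg) x angular acceleration (deg s^-2) / total
# body mass (kg). Angles stay in degrees end to end; the quantity is a
# mass-normalised angular measure, not an SI newton-metre (see the methods
# vignette for the unit discussion).

#' Segment-mass fraction table
#'
#' Fractions of total body mass per body segment, defaults from standard
#' adult-female anthropometry (de Leva's adjusted Zatsiorsky fractions,
#' one side): thigh 0.1478, shank 0.0481, foot 0.0129, trunk 0.4257.
#' The hip torque computation uses the extensor-chain mass
#' (thigh + shank + foot), the knee the shank + foot mass.
#'
#' @param fractions named numeric vector of mass fractions in (0, 1).
#' @param source_tag free-text provenance tag stored with results.
#' @export
anthropometry_config <- function(fractions = c(thigh = 0.1478, shank = 0.0481,
                                               foot = 0.0129, trunk = 0.4257),
                                 source_tag = "deLeva1996_female") {
  if (any(fractions <= 0) || any(fractions >= 1))
    stop("mass fractions must lie strictly in (0, 1)", call. = FALSE)
  structure(list(fractions = fractions, source_tag = source_tag),
            class = "anthropometry_config")
}

#' Segment mass driving a joint's torque
#' @param anthro an [anthropometry_config()].
#' @param joint "hip" or "knee".
#' @param total_mass_kg total body mass (kg).
#' @export
joint_segment_mass <- function(anthro, joint = c("hip", "knee"), total_mass_kg) {
  joint <- match.arg(joint)
  fr <- anthro$fractions
  fsum <- switch(joint,
                 hip = fr[["thigh"]] + fr[["shank"]] + fr[["foot"]],
                 knee = fr[["shank"]] + fr[["foot"]])
  fsum * total_mass_kg
}

#' Relative torque series and phase peak
#'
#' `RT(t) = segment_mass * angular_acceleration(t) / total_mass`; the peak is
#' the maximum absolute value over the requested frame interval.
#'
#' @param segment_mass_kg mass of the segment chain driven by the joint (kg).
#' @param angular_acc angular acceleration series (deg s^-2) or an
#'   `angle_series` object.
#' @param total_mass_kg total body mass (kg).
#' @param phase_idx frame indices defining the phase of interest (default:
#'   whole series).
#' @return list `series` and `peak`.
#' @export
relative_torque <- function(segment_mass_kg, angular_acc, total_mass_kg,
                            phase_idx = NULL) {
  if (segment_mass_kg <= 0 || total_mass_kg <= 0)
    stop("masses must be positive", call. = FALSE)
  aa <- if (inherits(angular_acc, "angle_series")) angular_acc$angular_acceleration
        else as.numeric(angular_acc)
  rt <- segment_mass_kg * aa / total_mass_kg
  if (is.null(phase_idx)) phase_idx <- seq_along(rt)
  if (length(phase_idx) == 0L) stop("empty phase interval", call. = FALSE)
  list(series = rt, peak = max(abs(rt[phase_idx])))
}

#' Joint power series and phase peak
#'
#' Pointwise product of the relative-torque series and the angular-velocity
#' series (deg s^-1).
#'
#' @param rt_series relative torque series.
#' @param angular_velocity_series angular velocity series, same length.
#' @param phase_idx frame indices for the peak (default: whole series).
#' @return list `series` and `peak` (max absolute value over the phase).
#' @export
joint_power <- function(rt_series, angular_velocity_series, phase_idx = NULL) {
  if (length(rt_series) != length(angular_velocity_series))
    stop("length mismatch between torque and angular-velocity series", call. = FALSE)
  p <- rt_series * angular_velocity_series
  if (is.null(phase_idx)) phase_idx <- seq_along(p)
  if (length(phase_idx) == 0L) stop("empty phase interval", call. = FALSE)
  list(series = p, peak = max(abs(p[phase_idx])))
}

#' Rate of force development over a phase
#'
#' Peak vertical force within the interval divided by the time from the
#' interval start (force onset) to that peak: `RFD = peak_force /
#' time_to_peak`.
#'
#' @param fp a [forceplate_series()].
#' @param phase_idx frame indices of the phase (onset = first index).
#' @return list `rfd` (N s^-1), `peak_force` (N), `time_to_peak` (s).
#' @export
rate_of_force_development <- function(fp, phase_idx) {
  stopifnot(inherits(fp, "forceplate_series"))
  if (length(phase_idx) == 0L) stop("empty phase interval", call. = FALSE)
  fz <- fp$fz[phase_idx]
  ipk <- which.max(fz)
  t_pk <- (ipk - 1L) / fp$frequency
  if (t_pk <= 0)
    stop("undefined RFD: peak force at the interval start", call. = FALSE)
  list(rfd = fz[ipk] / t_pk, peak_force = fz[ipk], time_to_peak = t_pk)
}

#' Reactive strength index and index of reactive force
#'
#' `RSI = DJ_height / contact_time`; `IReaF = (DJ_height - SJ_height) /
#' SJ_height`, the relative height gain attributable to the
#' stretch-shortening cycle.
#'
#' @param dj_height_m drop-jump height (m).
#' @param sj_height_m squat-jump height (m, > 0).
#' @param contact_time_s drop-jump ground contact time (s, > 0).
#' @return list `rsi`, `ireaf`.
#' @export
reactive_indices <- function(dj_height_m, sj_height_m, contact_time_s) {
  if (sj_height_m <= 0) stop("domain error: SJ height must be positive", call. = FALSE)
  if (contact_time_s <= 0) stop("domain error: contact time must be positive", call. = FALSE)
  list(rsi = dj_height_m / contact_time_s,
       ireaf = (dj_height_m - sj_height_m) / sj_height_m)
}

# outcome columns where "best" means the smallest value
MINIMIZED_OUTCOMES <- c("sprint_time_s", "contact_time_s")

#' Aggregate per-trial outcomes for one participant
#'
#' @param per_trial data frame of per-trial outcome rows (numeric outcome
#'   columns plus any id columns listed in `by`).
#' @param method "mean", or "best" (maximum for heights, torque, power, RFD,
#'   RSI; minimum for sprint and contact times).
#' @param by grouping columns kept in the output (default none: one row).
#' @return aggregated data frame with an `aggregation` tag column.
#' @export
aggregate_trials <- function(per_trial, method = c("mean", "best"), by = NULL) {
  method <- match.arg(method)
  if (!is.data.frame(per_trial) || nrow(per_trial) == 0L)
    stop("no trials to aggregate", call. = FALSE)
  num_cols <- setdiff(names(per_trial)[vapply(per_trial, is.numeric, logical(1))],
                      by)
  agg_one <- function(df) {
    out <- lapply(num_cols, function(cn) {
      v <- df[[cn]][is.finite(df[[cn]])]
      if (!length(v)) return(NA_real_)
      if (method == "mean") mean(v)
      else if (cn %in% MINIMIZED_OUTCOMES) min(v) else max(v)
    })
    names(out) <- num_cols
    as.data.frame(out)
  }
  if (is.null(by)) {
    res <- agg_one(per_trial)
  } else {
    pieces <- split(per_trial, per_trial[by], drop = TRUE)
    res <- do.call(rbind, lapply(pieces, function(df) {
      cbind(df[1, by, drop = FALSE], agg_one(df))
    }))
    rownames(res) <- NULL
  }
  res$aggregation <- method
  res
}

#' All outcomes for a single jump or sprint trial
#'
#' Runs the full chain — sacrum kinematics, phase segmentation, joint angles,
#' torque/power, force outcomes — and returns one row of outcomes. Torque and
#' power peaks are reported for the eccentric phase (falling back to the
#' concentric phase for squat jumps, which have no eccentric phase), averaged
#' over the left and right sides.
#'
#' @param markers a [marker_trajectories()] trial.
#' @param fp matching [forceplate_series()]; `NULL` for sprints.
#' @param trial_type "SJ", "CMJ", "DJ" or "SPRINT" (default: from metadata).
#' @param total_mass_kg participant total body mass (kg).
#' @param anthro an [anthropometry_config()].
#' @param cutoff_hz smoothing cutoff (Hz).
#' @param threshold_n flight-detection threshold (N).
#' @param gate_positions sprint gate planes (m).
#' @param g gravitational acceleration.
#' @return one-row data frame of outcomes (NA where not applicable).
#' @export
trial_outcomes <- function(markers, fp = NULL, trial_type = NULL,
                           total_mass_kg = 57,
                           anthro = anthropometry_config(),
                           cutoff_hz = 10, threshold_n = 10,
                           gate_positions = c(0, 5), g = 9.81) {
  if (is.null(trial_type)) trial_type <- markers$meta$trial_type
  if (is.null(trial_type)) stop("trial type unknown", call. = FALSE)
  row <- data.frame(
    trial_type = trial_type,
    jump_height_ft_m = NA_real_, jump_height_marker_m = NA_real_,
    contact_time_s = NA_real_, flight_time_s = NA_real_,
    rfd_n_per_s = NA_real_, peak_force_n = NA_real_, time_to_peak_s = NA_real_,
    hip_rt_peak = NA_real_, knee_rt_peak = NA_real_,
    hip_power_peak = NA_real_, knee_power_peak = NA_real_,
    torque_phase = NA_character_,
    sprint_time_s = NA_real_,
    stringsAsFactors = FALSE
  )
  if (trial_type == "SPRINT") {
    row$sprint_time_s <- sprint_time(markers, gate_positions)
    return(row)
  }
  if (is.null(fp)) stop("jump trials need a force-plate series", call. = FALSE)
  seg <- segment_jump_phases(markers, fp, trial_type,
                             threshold_n = threshold_n, cutoff_hz = cutoff_hz)
  kin <- linear_kinematics(markers, "F_sacrum", cutoff_hz = cutoff_hz)
  row$flight_time_s <- seg$flight_time
  row$contact_time_s <- seg$contact_time
  row$jump_height_ft_m <- jump_height(seg, method = "flight_time",
                                      jump_type = trial_type, g = g)
  row$jump_height_marker_m <- jump_height(seg, kin, method = "marker",
                                          jump_type = trial_type, g = g)

  # force phase: whole ground-contact push (E + C, or C for SJ)
  push_phase <- if ("E" %in% names(seg$phases)) "E" else "C"
  push_idx <- seq.int(phase_frames(seg, push_phase)[1],
                      max(phase_frames(seg, "C")))
  rfd <- tryCatch(rate_of_force_development(fp_at_marker_rate(fp, markers), push_idx),
                  error = function(e) NULL)
  if (!is.null(rfd)) {
    row$rfd_n_per_s <- rfd$rfd
    row$peak_force_n <- rfd$peak_force
    row$time_to_peak_s <- rfd$time_to_peak
  }

  torque_phase <- if ("E" %in% names(seg$phases)) "E" else "C"
  idx <- phase_frames(seg, torque_phase)
  row$torque_phase <- torque_phase
  for (joint in c("hip", "knee")) {
    seg_mass <- joint_segment_mass(anthro, joint, total_mass_kg)
    rt_pk <- pw_pk <- numeric(0)
    for (side in c("L", "R")) {
      ang <- joint_angle_series(markers, joint, side, cutoff_hz = cutoff_hz)
      rt <- relative_torque(seg_mass, ang, total_mass_kg, idx)
      pw <- joint_power(rt$series, ang$angular_velocity, idx)
      rt_pk <- c(rt_pk, rt$peak)
      pw_pk <- c(pw_pk, pw$peak)
    }
    row[[paste0(joint, "_rt_peak")]] <- mean(rt_pk)
    row[[paste0(joint, "_power_peak")]] <- mean(pw_pk)
  }
  row
}

# force plate and cameras often run on different clocks; index arithmetic in
# trial_outcomes assumes marker-rate indices, so resample when they differ
fp_at_marker_rate <- function(fp, markers) {
  if (fp$frequency == markers$frequency) return(fp)
  t_fp <- (seq_along(fp$fz) - 1L) / fp$frequency
  t_mk <- (seq_len(n_frames(markers)) - 1L) / markers$frequency
  forceplate_series(stats::approx(t_fp, fp$fz, xout = t_mk, rule = 2)$y,
                    markers$frequency)
}
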