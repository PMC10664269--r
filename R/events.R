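# Trial segmentation into jump phases, flight/contact detection from the
# force plate, and the timing outcomes built on them.
#
# Phase labels follow the D / F1 / L1 / E / C / F2 / L2 scheme used in
# rebound-jump testing: D on-box standing, F1 box-to-ground fall, L1 landing
# (instant opening ground contact in a drop jump; quiet standing in a
# countermovement jump), E eccentric descent, C concentric propulsion, F2 the
# jump flight, L2 the final landing.

PHASE_ORDER <- c("D", "F1", "L1", "E", "C", "F2", "L2")

#' Phase segmentation container
#'
#' @param phases named list label -> c(start_time, end_time) in seconds;
#'   labels from D, F1, L1, E, C, F2, L2. Present labels must be ordered and
#'   non-overlapping.
#' @param frequency sampling rate (Hz) of the segmented trial.
#' @param contact_time drop-jump ground-contact duration (s), if applicable.
#' @param flight_time duration of the jump flight F2 (s).
#' @export
phase_segmentation <- function(phases, frequency, contact_time = NA_real_,
                               flight_time = NA_real_) {
  lab <- names(phases)
  if (!all(lab %in% PHASE_ORDER))
    stop("unknown phase label(s): ",
         paste(setdiff(lab, PHASE_ORDER), collapse = ", "), call. = FALSE)
  ord <- PHASE_ORDER[PHASE_ORDER %in% lab]
  phases <- phases[ord]
  bounds <- do.call(rbind, phases)
  if (any(bounds[, 2] < bounds[, 1]))
    stop("phase with negative duration", call. = FALSE)
  if (length(ord) > 1L) {
    for (k in 2:length(ord))
      if (phases[[k]][1] < phases[[k - 1]][2] - 1e-9)
        stop(sprintf("phases %s and %s overlap or are out of order",
                     ord[k - 1], ord[k]), call. = FALSE)
  }
  structure(list(phases = phases, frequency = frequency,
                 contact_time = contact_time, flight_time = flight_time),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation>\n")
  for (lab in names(x$phases))
    cat(sprintf("  %-3s %7.3f - %7.3f s\n", lab, x$phases[[lab]][1], x$phases[[lab]][2]))
  if (!is.na(x$contact_time)) cat(sprintf("  contact_time %.3f s\n", x$contact_time))
  if (!is.na(x$flight_time)) cat(sprintf("  flight_time  %.3f s\n", x$flight_time))
  invisible(x)
}

#' Frame indices of a phase
#' @param seg a `phase_segmentation`.
#' @param label phase label.
#' @export
phase_frames <- function(seg, label) {
  if (!label %in% names(seg$phases))
    stop("phase ", label, " not present in segmentation", call. = FALSE)
  b <- seg$phases[[label]]
  i0 <- max(1L, floor(b[1] * seg$frequency) + 1L)
  i1 <- floor(b[2] * seg$frequency) + 1L
  seq.int(i0, max(i0, i1))
}

#' Detect flight and contact intervals from vertical force
#'
#' Flight = maximal runs with `fz < threshold_n` lasting at least
#' `min_flight_s` (debouncing against landing ringing); interval end points
#' are placed at the linear-interpolated threshold crossings.
#'
#' @param fp a [forceplate_series()] (zero-offset-corrected).
#' @param threshold_n force threshold in newtons (default 10).
#' @param min_flight_s minimum flight duration retained (default 0.05 s).
#' @return data frame with columns `takeoff`, `landing` (s); zero rows when
#'   the force never drops below threshold.
#' @export
detect_contact_flight <- function(fp, threshold_n = 10, min_flight_s = 0.05) {
  stopifnot(inherits(fp, "forceplate_series"))
  fz <- fp$fz
  if (length(fz) == 0L) stop("input error: no samples", call. = FALSE)
  below <- fz < threshold_n
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  dt <- 1 / fp$frequency
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    # crossing times by linear interpolation on the bracketing samples
    t_off <- if (i0 == 1L) 0 else {
      (i0 - 2L) * dt + dt * (fz[i0 - 1L] - threshold_n) / (fz[i0 - 1L] - fz[i0])
    }
    t_on <- if (i1 == length(fz)) (i1 - 1L) * dt else {
      (i1 - 1L) * dt + dt * (threshold_n - fz[i1]) / (fz[i1 + 1L] - fz[i1])
    }
    if (t_on - t_off >= min_flight_s)
      out[[length(out) + 1L]] <- c(takeoff = t_off, landing = t_on)
  }
  if (!length(out))
    return(data.frame(takeoff = numeric(0), landing = numeric(0)))
  as.data.frame(do.call(rbind, out))
}

# coarse onset time (s) of sustained motion: first index where sign*v
# exceeds v_thresh for `sustain_s`, backtracked to the quiet-phase noise
# floor; refine with refine_onset_changepoint() for sub-frame accuracy
motion_onset <- function(v, frequency, sign = -1, v_thresh = 0.30,
                         sustain_s = 0.025, from = 1L, to = length(v)) {
  # skip the first 0.1 s: filtering transients at the series edge masquerade
  # as motion
  from <- max(from, round(0.1 * frequency) + 1L)
  idx <- from:to
  vv <- sign * v[idx]
  sustain <- max(1L, round(sustain_s * frequency))
  hit <- NA_integer_
  run <- 0L
  for (i in seq_along(vv)) {
    run <- if (vv[i] > v_thresh) run + 1L else 0L
    if (run >= sustain) { hit <- i - sustain + 1L; break }
  }
  if (is.na(hit)) return(NA_real_)
  quiet <- seq_len(max(2L, hit - round(0.25 * frequency)))
  floor_v <- max(0.01, 1.5 * stats::sd(vv[quiet]))
  j <- hit
  while (j > 1L && vv[j - 1L] > floor_v) j <- j - 1L
  t_local <- (idx - 1L) / frequency
  t_local[j]
}

# sub-frame refinement of a rest-to-motion onset by a changepoint fit on the
# RAW position signal: motion from rest is locally quadratic in time
# (constant initial acceleration), so z(t) = b0 + b1 * ((t - t0)+)^2 is
# fitted by least squares for candidate onsets t0 on a quarter-frame grid,
# and the residual-minimising t0 wins. Working on unfiltered samples avoids
# the anticipation bias that zero-phase smoothing introduces at a kink.
refine_onset_changepoint <- function(z_raw, frequency, t_coarse, sign = -1,
                                     span_before = 0.20, span_after = 0.12,
                                     search = 0.08) {
  dt <- 1 / frequency
  tt <- (seq_along(z_raw) - 1L) * dt
  win <- which(tt >= t_coarse - span_before & tt <= t_coarse + span_after)
  if (length(win) < 12L) return(t_coarse)
  y <- sign * z_raw[win]   # increasing after onset
  tw <- tt[win]
  cands <- t_coarse + seq(-search, search, by = dt / 4)
  cands <- cands[cands > tw[2] & cands < tw[length(tw) - 2L]]
  if (!length(cands)) return(t_coarse)
  rss <- vapply(cands, function(t0) {
    xr <- pmax(tw - t0, 0)^2
    fit <- stats::lm.fit(cbind(1, xr), y)
    if (fit$coefficients[2] < 0) return(Inf)
    sum(fit$residuals^2)
  }, numeric(1))
  if (!any(is.finite(rss))) return(t_coarse)
  cands[which.min(rss)]
}

# movement onset (s) from the force record: first sustained deviation of fz
# from the quiet-standing body weight, backtracked to the last near-quiet
# sample. The plate is the cleanest onset sensor available: any change of
# centre-of-mass acceleration registers immediately as a force deviation.
force_onset <- function(dev, frequency, sign = -1, to_time = Inf,
                        sustain_s = 0.01) {
  n <- length(dev)
  to <- min(n, floor(to_time * frequency) + 1L)
  from <- max(1L, round(0.05 * frequency))
  quiet <- dev[seq.int(from, max(from + 1L, round(0.25 * frequency)))]
  thr_hit <- max(20, 6 * stats::sd(quiet))
  thr_back <- max(5, 4 * stats::sd(quiet))
  vv <- sign * dev
  sustain <- max(1L, round(sustain_s * frequency))
  run <- 0L
  hit <- NA_integer_
  for (i in from:to) {
    run <- if (vv[i] > thr_hit) run + 1L else 0L
    if (run >= sustain) { hit <- i - sustain + 1L; break }
  }
  if (is.na(hit)) return(NA_real_)
  j <- hit
  while (j > 1L && vv[j - 1L] > thr_back) j <- j - 1L
  (j - 1L) / frequency
}

# time of zero vertical centre-of-mass velocity inside a contact interval by
# the impulse-momentum theorem: v(t) = v_start + integral of (fz - mg)/m.
# This locates the eccentric/concentric boundary without touching the (far
# noisier) marker signal.
impulse_zero_velocity <- function(fp, body_weight_n, t0, t1, v_start = 0) {
  ff <- fp$frequency
  ftt <- (seq_along(fp$fz) - 1L) / ff
  idx <- which(ftt >= t0 & ftt <= t1)
  if (length(idx) < 3L || body_weight_n <= 0) return(NA_real_)
  acc <- (fp$fz[idx] - body_weight_n) / (body_weight_n / 9.81)
  v <- v_start + cumsum(acc) / ff
  neg <- which(v < 0)
  if (!length(neg) || max(neg) >= length(v)) return(NA_real_)
  i0 <- max(neg)
  ftt[idx[1]] + (i0 - 1L) / ff + (0 - v[i0]) / (v[i0 + 1L] - v[i0]) / ff
}

# sub-frame time of the height minimum: coarse argmin on the smoothed
# series, then a changepoint fit on the RAW samples. The eccentric and
# concentric sides of the minimum have different curvatures, so a single
# parabola's vertex is biased toward the flatter side; instead fit
# z = b0 + b1*((t-t0)-)^2 + b2*((t-t0)+)^2 (a two-sided quadratic with a
# shared vertex) for candidate t0 on a quarter-frame grid and keep the
# residual-minimising breakpoint.
refine_min_time <- function(z_smooth, z_raw, frequency, window,
                            half_window_s = 0.04, search_s = 0.02) {
  im <- window[which.min(z_smooth[window])]
  dt <- 1 / frequency
  t_im <- (im - 1L) * dt
  hw <- max(3L, round(half_window_s * frequency))
  wi <- max(1L, im - hw):min(length(z_raw), im + hw)
  if (length(wi) < 7L) return(t_im)
  tw <- (wi - 1L) * dt
  y <- z_raw[wi]
  cands <- t_im + seq(-search_s, search_s, by = dt / 4)
  cands <- cands[cands > tw[2] & cands < tw[length(tw) - 1L]]
  if (!length(cands)) return(t_im)
  rss <- vapply(cands, function(t0) {
    xl <- pmin(tw - t0, 0)^2
    xr <- pmax(tw - t0, 0)^2
    fit <- stats::lm.fit(cbind(1, xl, xr), y)
    if (any(fit$coefficients[2:3] < 0)) return(Inf)
    sum(fit$residuals^2)
  }, numeric(1))
  if (!any(is.finite(rss))) return(t_im)
  cands[which.min(rss)]
}

#' Segment a jump trial into its phases
#'
#' Combines the force plate (flight detection, [detect_contact_flight()])
#' with the sacrum vertical trajectory (movement onsets, eccentric/concentric
#' split at minimum height) to produce the phase map of the trial:
#'
#' * CMJ: L1 quiet standing, E from downward-movement onset to minimum sacrum
#'   height, C from that minimum to takeoff, F2 flight, L2 landing.
#' * DJ: D on-box standing, F1 fall from step-off to first ground contact
#'   (L1, the touchdown instant), E/C splitting ground contact at minimum
#'   sacrum height, F2 flight, L2 landing; `contact_time` = touchdown to
#'   takeoff.
#' * SJ: no E phase; C from the first sustained upward sacrum velocity to
#'   takeoff.
#'
#' @param markers a [marker_trajectories()] trial.
#' @param fp the matching [forceplate_series()].
#' @param jump_type "SJ", "CMJ" or "DJ".
#' @param threshold_n flight-detection force threshold (N).
#' @param cutoff_hz smoothing cutoff for the sacrum signal (Hz).
#' @return a [phase_segmentation()].
#' @export
segment_jump_phases <- function(markers, fp, jump_type = c("CMJ", "SJ", "DJ"),
                                threshold_n = 10, cutoff_hz = 10) {
  jump_type <- match.arg(jump_type)
  stopifnot(inherits(markers, "marker_trajectories"), inherits(fp, "forceplate_series"))
  f <- markers$frequency
  dt <- 1 / f
  kin <- linear_kinematics(markers, "F_sacrum", cutoff_hz = cutoff_hz)
  z <- kin$position_smoothed[, "z"]
  z_raw <- markers$positions[["F_sacrum"]][, "z"]
  vz <- kin$velocity[, "z"]
  n <- length(z)
  t_end <- (n - 1L) * dt
  flights <- detect_contact_flight(fp, threshold_n)

  # the jump flight is the longest force-free run (robust against brief
  # unweighting dips below threshold during a vigorous countermovement)
  need_flight <- function(label) {
    if (nrow(flights) == 0L)
      stop("segmentation error: phase ", label, " not found (no flight detected)",
           call. = FALSE)
    flights[which.max(flights$landing - flights$takeoff), ]
  }
  ti <- function(tm) min(n, max(1L, round(tm / dt) + 1L))

  ff <- fp$frequency
  ftt <- (seq_along(fp$fz) - 1L) / ff

  if (jump_type == "CMJ") {
    fl <- need_flight("F2")
    fw <- mean(fp$fz[ftt <= 0.3])             # quiet-standing body weight (N)
    e_on_t <- force_onset(fp$fz - fw, ff, sign = -1, to_time = fl$takeoff)
    if (is.na(e_on_t)) {                      # marker fallback
      e_on_t <- motion_onset(vz, f, sign = -1, to = ti(fl$takeoff))
      if (is.na(e_on_t))
        stop("segmentation error: phase E not found (no downward movement onset)",
             call. = FALSE)
      e_on_t <- refine_onset_changepoint(z_raw, f, e_on_t, sign = -1)
    }
    min_t <- impulse_zero_velocity(fp, fw, e_on_t, fl$takeoff, v_start = 0)
    if (is.na(min_t)) {
      contact_i <- seq.int(min(ti(fl$takeoff), ceiling(e_on_t * f) + 1L),
                           ti(fl$takeoff))
      min_t <- refine_min_time(z, z_raw, f, contact_i)
    }
    min_t <- max(min_t, e_on_t)
    phases <- list(
      L1 = c(0, e_on_t),
      E = c(e_on_t, min_t),
      C = c(min_t, fl$takeoff),
      F2 = c(fl$takeoff, fl$landing),
      L2 = c(fl$landing, t_end)
    )
    return(phase_segmentation(phases, f, flight_time = fl$landing - fl$takeoff))
  }

  if (jump_type == "SJ") {
    fl <- need_flight("F2")
    fw <- mean(fp$fz[ftt <= 0.3])
    c_on_t <- force_onset(fp$fz - fw, ff, sign = +1, to_time = fl$takeoff)
    if (is.na(c_on_t)) {
      c_on_t <- motion_onset(vz, f, sign = +1, to = ti(fl$takeoff))
      if (is.na(c_on_t))
        stop("segmentation error: phase C not found (no upward movement onset)",
             call. = FALSE)
      c_on_t <- refine_onset_changepoint(z_raw, f, c_on_t, sign = +1)
    }
    phases <- list(
      C = c(c_on_t, fl$takeoff),
      F2 = c(fl$takeoff, fl$landing),
      L2 = c(fl$landing, t_end)
    )
    return(phase_segmentation(phases, f, flight_time = fl$landing - fl$takeoff))
  }

  # DJ: plate reads zero while the athlete stands on the box, so the first
  # contact run on the plate IS the rebound contact; the jump flight follows it
  contacts_above <- fp$fz >= threshold_n
  if (!any(contacts_above))
    stop("segmentation error: phase L1 not found (no ground contact on the plate)",
         call. = FALSE)
  fl_rows <- detect_contact_flight(fp, threshold_n)
  dtf <- 1 / ff
  first_contact_i <- which(contacts_above)[1]
  touchdown <- if (first_contact_i == 1L) 0 else {
    (first_contact_i - 2L) * dtf +
      dtf * (threshold_n - fp$fz[first_contact_i - 1L]) /
        (fp$fz[first_contact_i] - fp$fz[first_contact_i - 1L])
  }
  after <- fl_rows[fl_rows$takeoff > touchdown, , drop = FALSE]
  if (nrow(after) == 0L)
    stop("segmentation error: phase F2 not found (no flight after ground contact)",
         call. = FALSE)
  fl <- after[1, ]
  d_end_t <- motion_onset(vz, f, sign = -1, to = ti(touchdown))
  if (is.na(d_end_t))
    stop("segmentation error: phase F1 not found (no step-off onset)", call. = FALSE)
  d_end_t <- refine_onset_changepoint(z_raw, f, d_end_t, sign = -1)
  # body weight from the final stance; touchdown velocity from the
  # whole-contact impulse balance with the flight-time takeoff velocity
  fw <- mean(fp$fz[ftt >= max(ftt) - 0.2])
  ci <- which(ftt >= touchdown & ftt <= fl$takeoff)
  imp <- sum(fp$fz[ci] - fw) / (fw / 9.81) / ff     # v_takeoff + v_touchdown
  v_to_est <- 9.81 * (fl$landing - fl$takeoff) / 2
  min_t <- impulse_zero_velocity(fp, fw, touchdown, fl$takeoff,
                                 v_start = -(imp - v_to_est))
  if (is.na(min_t)) {
    contact_i <- seq.int(ti(touchdown), ti(fl$takeoff))
    min_t <- refine_min_time(z, z_raw, f, contact_i)
  }
  min_t <- max(min_t, touchdown)
  phases <- list(
    D = c(0, d_end_t),
    F1 = c(d_end_t, touchdown),
    L1 = c(touchdown, touchdown),
    E = c(touchdown, min_t),
    C = c(min_t, fl$takeoff),
    F2 = c(fl$takeoff, fl$landing),
    L2 = c(fl$landing, t_end)
  )
  phase_segmentation(phases, f,
                     contact_time = fl$takeoff - touchdown,
                     flight_time = fl$landing - fl$takeoff)
}

#' Jump height from a segmented trial
#'
#' Two estimators are available:
#' * `"flight_time"`: ballistic closed form `h = g * t_f^2 / 8` from the F2
#'   flight duration (assumes landing at takeoff height).
#' * `"marker"`: apex of the sacrum during F2 minus a reference height — the
#'   mean sacrum height during quiet standing (L1) for a CMJ, or the sacrum
#'   height at takeoff for SJ/DJ, where no uncontaminated standing reference
#'   exists on the ground.
#'
#' @param seg a [phase_segmentation()] with an F2 phase.
#' @param kin the trial's sacrum [linear_kinematics()] (needed for the marker
#'   method).
#' @param method "flight_time" or "marker".
#' @param jump_type used by the marker method to pick the reference.
#' @param g gravitational acceleration (m s^-2).
#' @return height in metres.
#' @export
jump_height <- function(seg, kin = NULL, method = c("flight_time", "marker"),
                        jump_type = c("CMJ", "SJ", "DJ"), g = 9.81) {
  method <- match.arg(method)
  jump_type <- match.arg(jump_type)
  if (method == "flight_time") {
    tf <- seg$flight_time
    if (is.na(tf)) stop("missing flight phase", call. = FALSE)
    return(g * tf^2 / 8)
  }
  if (is.null(kin)) stop("marker method needs the sacrum linear series", call. = FALSE)
  if (!"F2" %in% names(seg$phases)) stop("missing flight phase", call. = FALSE)
  z <- kin$position_smoothed[, "z"]
  tt <- (seq_along(z) - 1L) / kin$frequency
  fl_i <- phase_frames(seg, "F2")
  # parabolic apex through the three samples around the maximum (the frame
  # grid rarely hits the true apex)
  im <- fl_i[which.max(z[fl_i])]
  apex <- if (im > 1L && im < length(z)) {
    zm <- z[(im - 1L):(im + 1L)]
    den <- zm[1] - 2 * zm[2] + zm[3]
    if (den < 0) zm[2] - (zm[3] - zm[1])^2 / (8 * den) else zm[2]
  } else z[im]
  ref <- if (jump_type == "CMJ" && "L1" %in% names(seg$phases)) {
    mean(z[phase_frames(seg, "L1")])
  } else {
    # sacrum height at the (sub-frame) takeoff instant from the force plate
    stats::approx(tt, z, xout = seg$phases[["F2"]][1], rule = 2)$y
  }
  apex - ref
}

#' Classify stretch-shortening-cycle speed from ground-contact time
#'
#' Rebound actions with ground contact shorter than 250 ms are classed as
#' fast SSC (typical of drop jumps), longer ones as slow SSC (typical of
#' countermovement jumps). The boundary value 0.250 s is assigned to "slow".
#'
#' @param contact_time_s ground contact time in seconds (> 0).
#' @return "fast" or "slow" (vectorised).
#' @export
classify_ssc_speed <- function(contact_time_s) {
  if (any(!is.finite(contact_time_s)) || any(contact_time_s <= 0))
    stop("contact time must be positive", call. = FALSE)
  ifelse(contact_time_s < 0.250, "fast", "slow")
}

#' Sprint time between two virtual timing planes
#'
#' Time between the linear-interpolated crossings of the sacrum x-trajectory
#' through the planes `x = gate_positions[1]` and `x = gate_positions[2]`.
#'
#' @param markers a [marker_trajectories()] sprint trial.
#' @param gate_positions numeric length-2, distinct gate x positions (m).
#' @param marker_id marker whose x-trajectory is timed.
#' @param cutoff_hz smoothing cutoff applied before crossing detection
#'   (`NULL` = none).
#' @return interval in seconds.
#' @export
sprint_time <- function(markers, gate_positions = c(0, 5),
                        marker_id = "F_sacrum", cutoff_hz = NULL) {
  stopifnot(inherits(markers, "marker_trajectories"))
  if (length(gate_positions) != 2L || gate_positions[1] == gate_positions[2])
    stop("parameter error: gates must be two distinct positions", call. = FALSE)
  x <- markers$positions[[marker_id]][, "x"]
  if (!is.null(cutoff_hz)) x <- smooth_lowpass(x, markers$frequency, cutoff_hz)
  dt <- 1 / markers$frequency
  cross <- function(gate) {
    i <- which(x >= gate)[1]
    if (is.na(i)) stop(sprintf("gate plane x = %g never crossed", gate), call. = FALSE)
    if (i == 1L) {
      if (abs(x[1] - gate) > 1e-9)
        stop(sprintf("gate plane x = %g already passed at trial start", gate),
             call. = FALSE)
      return(0)
    }
    (i - 2L) * dt + dt * (gate - x[i - 1L]) / (x[i] - x[i - 1L])
  }
  g <- sort(gate_positions)
  cross(g[2]) - cross(g[1])
}
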