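# Marker signals -> smoothed linear and angular kinematics. All angles in
# degrees, angular rates in deg/s and deg/s^2 to match how jump-testing
# outcomes are conventionally reported.

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward filtering with a Butterworth design
#' ([signal::butter()]), odd-reflection edge padding and steady-state initial
#' filter conditions, so the output has zero phase lag, unit DC gain and no
#' edge transients (a constant series passes through unchanged to machine
#' precision).
#'
#' @param x numeric series.
#' @param frequency sampling rate (Hz).
#' @param cutoff_hz low-pass cutoff; must be below the Nyquist frequency.
#' @param order filter order of each pass (default 4).
#' @return filtered series, same length as `x`.
#' @export
smooth_lowpass <- function(x, frequency, cutoff_hz = 10, order = 4) {
  if (cutoff_hz <= 0)
    stop("parameter error: cutoff must be positive", call. = FALSE)
  if (cutoff_hz >= frequency / 2)
    stop(sprintf("parameter error: cutoff %g Hz >= Nyquist %g Hz",
                 cutoff_hz, frequency / 2), call. = FALSE)
  if (anyNA(x)) stop("input error: series contains NA (fill gaps first)", call. = FALSE)
  bt <- signal::butter(order, cutoff_hz / (frequency / 2), type = "low")
  b <- bt$b; a <- bt$a
  npad <- min(length(x) - 1L, max(3L * (max(length(a), length(b)) - 1L), 12L))
  if (npad < 1L) return(x)
  # odd reflection about the end points kills edge discontinuities
  xe <- c(2 * x[1] - rev(x[2:(npad + 1L)]), x,
          2 * x[length(x)] - x[length(x) - 1:npad])
  onepass <- function(v) {
    # steady-state initial conditions for a step of height v[1]
    signal::filter(b, a, v, init.x = rep(v[1], length(b) - 1L),
                   init.y = rep(v[1], length(a) - 1L))
  }
  y <- onepass(xe)
  y <- rev(onepass(rev(y)))
  as.numeric(y[(npad + 1L):(npad + length(x))])
}

#' Central-difference differentiation
#'
#' Interior points by the symmetric difference `(x[i+1] - x[i-1]) * f / 2`,
#' endpoints by one-sided differences. Exact for polynomials up to degree 2
#' at interior points; apply twice for acceleration.
#'
#' @param x numeric series (>= 3 samples).
#' @param frequency sampling rate (Hz).
#' @return derivative series, same length as `x`.
#' @export
central_difference <- function(x, frequency) {
  n <- length(x)
  if (n < 3L) stop("input error: need at least 3 samples", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * frequency / 2
  d[1] <- (x[2] - x[1]) * frequency
  d[n] <- (x[n] - x[n - 1L]) * frequency
  d
}

#' Inner joint angle from a marker triplet
#'
#' Per frame, the angle at the vertex marker between the vectors to the
#' proximal and distal markers: `acos` of their normalised dot product, in
#' degrees. With this convention an extended knee reads ~180 degrees and a
#' parallel squat ~90 degrees. Angular velocity and acceleration are obtained
#' by low-pass filtering the angle then differentiating twice with
#' [central_difference()].
#'
#' @param markers a [marker_trajectories()] object.
#' @param joint "hip" (triplet ASIS-trochanter-condyle, E/D/C) or "knee"
#'   (trochanter-condyle-malleolus, D/C/B), or a custom character triplet
#'   `c(proximal, vertex, distal)` of marker names.
#' @param side "L" or "R"; ignored for a custom triplet.
#' @param cutoff_hz,order smoothing parameters forwarded to
#'   [smooth_lowpass()]; `cutoff_hz = NULL` skips smoothing.
#' @return list of class `angle_series`: `joint`, `side`, `angle` (deg),
#'   `angular_velocity` (deg/s), `angular_acceleration` (deg/s^2),
#'   `frequency`.
#' @export
joint_angle_series <- function(markers, joint = c("hip", "knee"), side = c("L", "R"),
                               cutoff_hz = 10, order = 4) {
  stopifnot(inherits(markers, "marker_trajectories"))
  if (length(joint) == 3L && all(joint %in% names(markers$positions))) {
    triplet <- joint
    joint_name <- paste(joint, collapse = "-")
    side <- NA_character_
  } else {
    joint <- match.arg(joint)
    side <- match.arg(side)
    triplet <- switch(joint,
      hip = paste0(c("E_ASIS_", "Dtrochanter_", "Ccondyle_"), side),
      knee = paste0(c("Dtrochanter_", "Ccondyle_", "Bmalleolus_"), side)
    )
    joint_name <- joint
  }
  miss <- setdiff(triplet, names(markers$positions))
  if (length(miss))
    stop("input error: missing marker(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  P <- markers$positions[[triplet[1]]]
  V <- markers$positions[[triplet[2]]]
  D <- markers$positions[[triplet[3]]]
  u <- P - V
  v <- D - V
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  degen <- which(nu < 1e-6 | nv < 1e-6)
  if (length(degen))
    stop(sprintf("degenerate geometry: coincident markers at frame %d", degen[1]),
         call. = FALSE)
  cosang <- pmin(pmax(rowSums(u * v) / (nu * nv), -1), 1)
  ang <- acos(cosang) * 180 / pi
  sm <- if (is.null(cutoff_hz)) ang
        else smooth_lowpass(ang, markers$frequency, cutoff_hz, order)
  av <- central_difference(sm, markers$frequency)
  aa <- central_difference(av, markers$frequency)
  structure(list(joint = joint_name, side = side, angle = ang,
                 angle_smoothed = sm, angular_velocity = av,
                 angular_acceleration = aa, frequency = markers$frequency),
            class = "angle_series")
}

#' Linear kinematics of a single marker
#'
#' Position plus smoothed first and second derivatives along each lab axis.
#' Defaults to the sacrum marker, the conventional whole-body proxy for jump
#' height, peak velocity and sprint position.
#'
#' @param markers a [marker_trajectories()] object.
#' @param marker_id marker to track (default "F_sacrum").
#' @param cutoff_hz,order smoothing parameters; `cutoff_hz = NULL` skips
#'   smoothing before differentiation.
#' @return list of class `linear_series`: `position` (n x 3), `velocity`,
#'   `acceleration` (same shape), `frequency`, `marker_id`.
#' @export
linear_kinematics <- function(markers, marker_id = "F_sacrum",
                              cutoff_hz = 10, order = 4) {
  stopifnot(inherits(markers, "marker_trajectories"))
  if (!marker_id %in% names(markers$positions))
    stop("input error: marker ", marker_id, " not present", call. = FALSE)
  pos <- markers$positions[[marker_id]]
  f <- markers$frequency
  sm <- apply(pos, 2, function(col) {
    if (is.null(cutoff_hz)) col else smooth_lowpass(col, f, cutoff_hz, order)
  })
  vel <- apply(sm, 2, central_difference, frequency = f)
  acc <- apply(vel, 2, central_difference, frequency = f)
  colnames(vel) <- colnames(acc) <- c("x", "y", "z")
  structure(list(position = pos, position_smoothed = sm, velocity = vel,
                 acceleration = acc, frequency = f, marker_id = marker_id),
            class = "linear_series")
}
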