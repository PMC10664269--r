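#' @importFrom stats approx rnorm runif rbinom sd var cor pchisq pf qf pt qtukey
#'   ptukey aov anova TukeyHSD t.test ks.test lm logLik coef setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

#' Canonical eleven-marker set
#'
#' Marker labels for the lower-limb model: fifth metatarsal (A), lateral
#' malleolus (B), lateral femoral condyle (C), greater trochanter (D),
#' anterior superior iliac spine (E) on each side, plus the sacrum (F).
#'
#' @export
CANONICAL_MARKERS <- c(
  "A5thMet_L", "A5thMet_R",
  "Bmalleolus_L", "Bmalleolus_R",
  "Ccondyle_L", "Ccondyle_R",
  "Dtrochanter_L", "Dtrochanter_R",
  "E_ASIS_L", "E_ASIS_R",
  "F_sacrum"
)

TRIAL_TYPES <- c("SJ", "CMJ", "DJ", "SPRINT")
ACTN3_GENOTYPES <- c("RR", "RX", "XX")
ACE_GENOTYPES <- c("II", "ID", "DD")

#' Marker-trajectory container
#'
#' Time-indexed 3D positions (metres, lab frame, vertical axis = z) for a set
#' of reflective markers sharing one sampling clock.
#'
#' @param positions named list of n-by-3 numeric matrices (columns x, y, z),
#'   one per marker; all must have the same number of rows. `NA` rows mark
#'   occlusion gaps.
#' @param frequency sampling rate in Hz (> 0).
#' @param meta list with optional fields `participant_id`, `trial_type`
#'   (one of SJ, CMJ, DJ, SPRINT), `trial_number`.
#' @return object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(positions, frequency, meta = list()) {
  if (!is.list(positions) || is.null(names(positions)) || any(names(positions) == ""))
    stop("`positions` must be a named list of n-by-3 matrices", call. = FALSE)
  nf <- vapply(positions, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    stop("all markers must share the same frame count", call. = FALSE)
  if (!all(vapply(positions, ncol, integer(1)) == 3L))
    stop("marker matrices must have exactly 3 columns (x, y, z)", call. = FALSE)
  if (!is.numeric(frequency) || length(frequency) != 1L || !is.finite(frequency) || frequency <= 0)
    stop("`frequency` must be a single positive number (Hz)", call. = FALSE)
  if (!is.null(meta$trial_type) && !meta$trial_type %in% TRIAL_TYPES)
    stop("trial_type must be one of ", paste(TRIAL_TYPES, collapse = ", "), call. = FALSE)
  positions <- lapply(positions, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  structure(
    list(positions = positions, frequency = as.numeric(frequency), meta = meta),
    class = "marker_trajectories"
  )
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf(
    "<marker_trajectories> %d markers x %d frames @ %g Hz (%.2f s)\n",
    length(x$positions), n_frames(x), x$frequency, (n_frames(x) - 1) / x$frequency
  ))
  if (!is.null(x$meta$trial_type))
    cat("  trial:", x$meta$trial_type,
        if (!is.null(x$meta$participant_id)) paste0("participant ", x$meta$participant_id) else "",
        "\n")
  invisible(x)
}

#' Number of frames in a marker-trajectory object
#' @param x a `marker_trajectories` object.
#' @export
n_frames <- function(x) nrow(x$positions[[1]])

#' Force-plate series container
#'
#' Ground-reaction force channels sampled on one clock. `fz` is the vertical
#' component (N, positive upward); `fx`/`fy` shear components are optional.
#'
#' @param fz numeric vector of vertical force (N).
#' @param frequency sampling rate in Hz.
#' @param fx,fy optional shear channels, same length as `fz`.
#' @param plate_dims plate side lengths in metres (default 0.9 x 0.9).
#' @return object of class `forceplate_series`.
#' @export
forceplate_series <- function(fz, frequency, fx = NULL, fy = NULL,
                              plate_dims = c(0.9, 0.9)) {
  if (!is.numeric(fz) || length(fz) < 1L)
    stop("`fz` must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("`frequency` must be a single positive number (Hz)", call. = FALSE)
  for (ch in list(fx = fx, fy = fy)) {
    if (!is.null(ch) && length(ch) != length(fz))
      stop("all force channels must share one length", call. = FALSE)
  }
  if (any(fz < -50, na.rm = TRUE))
    warning("fz below -50 N: check zero-offset correction")
  structure(
    list(fz = as.numeric(fz), fx = if (!is.null(fx)) as.numeric(fx),
         fy = if (!is.null(fy)) as.numeric(fy),
         frequency = as.numeric(frequency), plate_dims = plate_dims),
    class = "forceplate_series"
  )
}

#' @export
print.forceplate_series <- function(x, ...) {
  cat(sprintf("<forceplate_series> %d samples @ %g Hz, peak fz %.1f N\n",
              length(x$fz), x$frequency, max(x$fz, na.rm = TRUE)))
  invisible(x)
}

# ---- marker TSV dialect -----------------------------------------------------
#
# Pinned QTM-like text dialect so fixtures are bit-exact:
#   line 1..k  header records "KEY<TAB>value", keys FREQUENCY (Hz, required),
#              UNITS (m|mm, default m), GAP_SENTINEL (zero|none, default none),
#              MARKER_NAMES (tab-separated labels, required, last header line)
#   then one row per frame, 3 tab-separated columns per marker (x y z).
# Empty cells, or an all-zero triple when GAP_SENTINEL is "zero", mark gaps.

#' Read a marker trajectory TSV export
#'
#' Parses the package's pinned motion-capture TSV dialect (see Details) into a
#' [marker_trajectories()] object, normalising coordinates to metres and
#' optionally interpolating short occlusion gaps.
#'
#' @details The dialect has header lines `FREQUENCY`, optional `UNITS`
#'   (`m` or `mm`) and `GAP_SENTINEL` (`zero` or `none`), then `MARKER_NAMES`,
#'   followed by one row per frame with three tab-separated columns per
#'   marker. When `GAP_SENTINEL` is `zero`, an exactly-zero coordinate triple
#'   is treated as an occlusion gap (a common optical-capture convention);
#'   empty cells always are. Gaps are linearly interpolated per coordinate up
#'   to `max_gap_run` consecutive frames; a longer run aborts the read.
#'
#' @param source path to the TSV file.
#' @param fill_gaps interpolate gap frames (default TRUE).
#' @param max_gap_run longest gap run (frames) eligible for interpolation.
#' @param meta optional trial metadata list passed to [marker_trajectories()].
#' @return a `marker_trajectories` object.
#' @export
read_marker_tsv <- function(source, fill_gaps = TRUE, max_gap_run = 10L,
                            meta = list()) {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) == 0L) stop("format error: empty marker file", call. = FALSE)
  hdr <- list(UNITS = "m", GAP_SENTINEL = "none")
  i <- 1L
  repeat {
    if (i > length(lines)) break
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    key <- parts[1]
    if (!key %in% c("FREQUENCY", "UNITS", "GAP_SENTINEL", "MARKER_NAMES")) break
    hdr[[key]] <- if (key == "MARKER_NAMES") parts[-1] else parts[2]
    i <- i + 1L
    if (key == "MARKER_NAMES") break
  }
  if (is.null(hdr$FREQUENCY))
    stop("format error: missing FREQUENCY header", call. = FALSE)
  if (is.null(hdr$MARKER_NAMES))
    stop("format error: missing MARKER_NAMES header", call. = FALSE)
  freq <- suppressWarnings(as.numeric(hdr$FREQUENCY))
  if (is.na(freq) || freq <= 0)
    stop("format error: FREQUENCY must be a positive number", call. = FALSE)
  if (!hdr$UNITS %in% c("m", "mm"))
    stop("format error: UNITS must be 'm' or 'mm'", call. = FALSE)
  markers <- hdr$MARKER_NAMES
  ncols <- 3L * length(markers)
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("format error: no data rows", call. = FALSE)

  cells <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != ncols)
  if (length(bad))
    stop(sprintf("format error: line %d has %d columns, expected %d",
                 i + bad[1] - 1L, lengths(cells)[bad[1]], ncols), call. = FALSE)
  flat <- unlist(cells, use.names = FALSE)
  num <- suppressWarnings(as.numeric(flat))
  blank <- !nzchar(flat)
  if (any(is.na(num) & !blank)) {
    j <- which(is.na(num) & !blank)[1]
    stop(sprintf("format error: non-numeric cell '%s' at line %d",
                 flat[j], i + (j - 1L) %/% ncols), call. = FALSE)
  }
  mat <- matrix(num, nrow = length(body), ncol = ncols, byrow = TRUE)
  scale <- if (hdr$UNITS == "mm") 1e-3 else 1
  positions <- vector("list", length(markers))
  names(positions) <- markers
  for (k in seq_along(markers)) {
    block <- mat[, (3L * k - 2L):(3L * k), drop = FALSE] * scale
    if (identical(hdr$GAP_SENTINEL, "zero")) {
      zero_row <- rowSums(block == 0) == 3L
      block[zero_row, ] <- NA_real_
    }
    block[!stats::complete.cases(block), ] <- NA_real_
    positions[[k]] <- block
  }
  traj <- marker_trajectories(positions, freq, meta)
  if (fill_gaps) traj <- fill_marker_gaps(traj, max_gap_run = max_gap_run)
  traj
}

#' Interpolate occlusion gaps in marker trajectories
#'
#' Linear interpolation per marker and coordinate across `NA` runs of at most
#' `max_gap_run` frames. Longer runs, or gaps touching the first/last frame,
#' reject the trial (an error), because extrapolated marker data would corrupt
#' derivatives downstream.
#'
#' @param traj a `marker_trajectories` object.
#' @param max_gap_run maximum interpolable run length (frames).
#' @export
fill_marker_gaps <- function(traj, max_gap_run = 10L) {
  for (m in names(traj$positions)) {
    blk <- traj$positions[[m]]
    gap <- is.na(blk[, 1])
    if (!any(gap)) next
    r <- rle(gap)
    runs <- r$lengths[r$values]
    if (any(runs > max_gap_run))
      stop(sprintf("trial rejected: marker %s has a gap of %d frames (max %d)",
                   m, max(runs), max_gap_run), call. = FALSE)
    if (gap[1] || gap[length(gap)])
      stop(sprintf("trial rejected: marker %s has a gap at the trial boundary", m),
           call. = FALSE)
    idx <- seq_len(nrow(blk))
    for (j in 1:3)
      blk[gap, j] <- stats::approx(idx[!gap], blk[!gap, j], xout = idx[gap])$y
    traj$positions[[m]] <- blk
  }
  traj
}

#' Write marker trajectories in the pinned TSV dialect
#'
#' Inverse of [read_marker_tsv()]; values are written in metres with 12
#' significant digits, so write-then-read is an identity for gap-free data and
#' repeated writes are byte-identical.
#'
#' @param traj a `marker_trajectories` object.
#' @param dest output path.
#' @export
write_marker_tsv <- function(traj, dest) {
  stopifnot(inherits(traj, "marker_trajectories"))
  mat <- do.call(cbind, traj$positions)
  rows <- apply(mat, 1, function(v) {
    paste(ifelse(is.na(v), "", sprintf("%.12g", v)), collapse = "\t")
  })
  lines <- c(
    paste0("FREQUENCY\t", sprintf("%.12g", traj$frequency)),
    "UNITS\tm",
    "GAP_SENTINEL\tnone",
    paste(c("MARKER_NAMES", names(traj$positions)), collapse = "\t"),
    rows
  )
  writeLines(lines, dest)
  invisible(dest)
}

# ---- force-plate TSV --------------------------------------------------------

#' Read a force-plate TSV export
#'
#' Header lines `FREQUENCY` (Hz) and `CHANNELS` (subset of fz, fx, fy; fz
#' required), then one row per sample.
#'
#' @param source path to the TSV file.
#' @return a `forceplate_series` object.
#' @export
read_forceplate_tsv <- function(source) {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) == 0L) stop("format error: empty force file", call. = FALSE)
  hdr <- list()
  i <- 1L
  repeat {
    if (i > length(lines)) break
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (!parts[1] %in% c("FREQUENCY", "CHANNELS")) break
    hdr[[parts[1]]] <- if (parts[1] == "CHANNELS") parts[-1] else parts[2]
    i <- i + 1L
    if (parts[1] == "CHANNELS") break
  }
  if (is.null(hdr$FREQUENCY)) stop("format error: missing FREQUENCY header", call. = FALSE)
  if (is.null(hdr$CHANNELS)) stop("format error: missing CHANNELS header", call. = FALSE)
  freq <- suppressWarnings(as.numeric(hdr$FREQUENCY))
  if (is.na(freq) || freq <= 0)
    stop("format error: FREQUENCY must be a positive number", call. = FALSE)
  chans <- hdr$CHANNELS
  if (!"fz" %in% chans) stop("format error: fz channel required", call. = FALSE)
  if (!all(chans %in% c("fz", "fx", "fy")))
    stop("format error: unknown channel in CHANNELS", call. = FALSE)
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("format error: no data rows", call. = FALSE)
  cells <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(chans))
  if (length(bad))
    stop(sprintf("format error: line %d has %d columns, expected %d",
                 i + bad[1] - 1L, lengths(cells)[bad[1]], length(chans)),
         call. = FALSE)
  flat <- unlist(cells, use.names = FALSE)
  num <- suppressWarnings(as.numeric(flat))
  if (anyNA(num)) {
    j <- which(is.na(num))[1]
    stop(sprintf("format error: non-numeric cell '%s' at line %d",
                 flat[j], i + (j - 1L) %/% length(chans)), call. = FALSE)
  }
  mat <- matrix(num, nrow = length(body), ncol = length(chans), byrow = TRUE)
  colnames(mat) <- chans
  forceplate_series(
    fz = mat[, "fz"],
    fx = if ("fx" %in% chans) mat[, "fx"],
    fy = if ("fy" %in% chans) mat[, "fy"],
    frequency = freq
  )
}

#' Write a force-plate series in the pinned TSV dialect
#' @param fp a `forceplate_series` object.
#' @param dest output path.
#' @export
write_forceplate_tsv <- function(fp, dest) {
  stopifnot(inherits(fp, "forceplate_series"))
  chans <- c("fz", if (!is.null(fp$fx)) "fx", if (!is.null(fp$fy)) "fy")
  mat <- do.call(cbind, fp[chans])
  rows <- apply(mat, 1, function(v) paste(sprintf("%.12g", v), collapse = "\t"))
  lines <- c(
    paste0("FREQUENCY\t", sprintf("%.12g", fp$frequency)),
    paste(c("CHANNELS", chans), collapse = "\t"),
    rows
  )
  writeLines(lines, dest)
  invisible(dest)
}

# ---- genotype table ---------------------------------------------------------

#' Read and validate a cohort genotype/covariate table
#'
#' CSV with header; required columns `id`, `actn3` (RR/RX/XX), `ace`
#' (II/ID/DD). Additional covariate columns (e.g. `body_mass_kg`, `age`,
#' `sex`, exclusion flags) pass through unchanged.
#'
#' @param source path to the CSV file.
#' @return a `data.frame` with class `genotype_table`.
#' @export
read_genotype_table <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  validate_genotype_table(df)
}

#' Validate a genotype/covariate data frame
#' @param df data frame with columns `id`, `actn3`, `ace` at minimum.
#' @export
validate_genotype_table <- function(df) {
  need <- c("id", "actn3", "ace")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("validation error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$id)) {
    dup <- df$id[duplicated(df$id)][1]
    stop(sprintf("validation error: duplicate participant id '%s'", dup),
         call. = FALSE)
  }
  check_vocab <- function(col, vocab, name) {
    bad <- which(!col %in% vocab)
    if (length(bad))
      stop(sprintf("validation error: row %d has %s genotype '%s' (allowed: %s)",
                   bad[1], name, col[bad[1]], paste(vocab, collapse = "/")),
           call. = FALSE)
  }
  check_vocab(df$actn3, ACTN3_GENOTYPES, "ACTN3")
  check_vocab(df$ace, ACE_GENOTYPES, "ACE")
  # a bare F/T in an unquoted CSV sex column comes back logical
  if ("sex" %in% names(df) && is.logical(df$sex))
    df$sex <- ifelse(df$sex, "T", "F")
  if ("body_mass_kg" %in% names(df) && any(df$body_mass_kg <= 0, na.rm = TRUE))
    stop("validation error: body_mass_kg must be positive", call. = FALSE)
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Write a genotype table as CSV
#' @param df a genotype table (or plain data frame).
#' @param dest output path.
#' @export
write_genotype_table <- function(df, dest) {
  utils::write.csv(df, dest, row.names = FALSE, quote = FALSE)
  invisible(dest)
}

# ---- results tables ---------------------------------------------------------

#' Write a results table with a deterministic layout
#'
#' Columns are written in their existing order, numeric values with 12
#' significant digits, no quoting, no row names: two writes of the same input
#' are byte-identical and a read-back reproduces values to 12 significant
#' digits. An empty collection yields a header-only file.
#'
#' @param results data frame of outcomes or association statistics.
#' @param dest output path.
#' @export
write_results_table <- function(results, dest) {
  if (!is.data.frame(results))
    stop("`results` must be a data frame", call. = FALSE)
  fmt <- as.data.frame(
    lapply(results, function(col) {
      if (is.numeric(col)) ifelse(is.na(col), "", sprintf("%.12g", col))
      else as.character(col)
    }),
    stringsAsFactors = FALSE, optional = TRUE
  )
  if (nrow(results) == 0L) {
    writeLines(paste(names(results), collapse = ","), dest)
    return(invisible(dest))
  }
  names(fmt) <- names(results)
  utils::write.csv(fmt, dest, row.names = FALSE, quote = FALSE)
  invisible(dest)
}

#' Read back a results table written by [write_results_table()]
#' @param source path to the CSV file.
#' @export
read_results_table <- function(source) {
  utils::read.csv(source, stringsAsFactors = FALSE)
}
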