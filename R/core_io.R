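#' Tri-axial acceleration signal
#'
#' Container for a uniformly sampled tri-axial acceleration record. Channels
#' follow the waist-worn device convention: `x` vertical, `y`
#' antero-posterior, `z` medio-lateral. Samples are always stored in m/s^2;
#' readers convert from g on load.
#'
#' @param x,y,z Numeric vectors of equal length, acceleration in m/s^2.
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Session time of the first sample, seconds (default 0).
#' @return An object of class `accel_signal`: a list with elements `x`, `y`,
#'   `z`, `fs`, `t0`.
#' @export
accel_signal <- function(x, y, z, fs, t0 = 0) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (length(y) != length(x) || length(z) != length(x))
    stop("channels x, y, z must have the same length")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("acceleration channels must not contain missing values")
  structure(list(x = x, y = y, z = z, fs = fs, t0 = as.numeric(t0)),
            class = "accel_signal")
}

#' @export
print.accel_signal <- function(x, ...) {
  cat(sprintf("<accel_signal> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              n_samples(x), x$fs, n_samples(x) / x$fs, x$t0))
  invisible(x)
}

#' Number of samples in an acceleration signal
#' @param signal An [accel_signal()].
#' @export
n_samples <- function(signal) length(signal$x)

#' Sample times of an acceleration signal
#' @param signal An [accel_signal()].
#' @return Numeric vector of session times (s), one per sample.
#' @export
accel_time <- function(signal) {
  signal$t0 + (seq_len(n_samples(signal)) - 1L) / signal$fs
}

#' Extract a time slice from an acceleration signal
#'
#' @param signal An [accel_signal()].
#' @param start_s,end_s Slice boundaries in session time, half-open
#'   `[start_s, end_s)`.
#' @return An [accel_signal()] with `t0` set to the slice start.
#' @export
slice_accel <- function(signal, start_s, end_s) {
  if (end_s <= start_s) stop("empty slice: end_s must exceed start_s")
  tt <- accel_time(signal)
  keep <- tt >= start_s - 1e-9 & tt < end_s - 1e-9
  if (!any(keep)) stop("slice contains no samples")
  accel_signal(signal$x[keep], signal$y[keep], signal$z[keep],
               fs = signal$fs, t0 = tt[which(keep)[1L]])
}

#' Reference speed trace
#'
#' 1 Hz speed series from the mobile gold standard (or the simulator's
#' ground truth).
#'
#' @param time Timestamps in seconds, spaced exactly 1 s apart (tolerance
#'   1e-9).
#' @param speed Speeds in m/s, all non-negative.
#' @return An object of class `speed_trace`: a data.frame with columns
#'   `time` and `speed`.
#' @export
speed_trace <- function(time, speed) {
  time <- as.numeric(time); speed <- as.numeric(speed)
  if (length(time) != length(speed)) stop("`time` and `speed` lengths differ")
  if (length(time) > 1L && any(abs(diff(time) - 1) > 1e-9))
    stop("speed trace must be sampled at exactly 1 Hz")
  if (any(speed < 0)) stop("speeds must be non-negative")
  structure(data.frame(time = time, speed = speed),
            class = c("speed_trace", "data.frame"))
}

#' Subject metadata
#'
#' Anthropometric and calibration parameters used by the step-length and
#' walk-ratio speed models and by the gait simulator.
#'
#' @param id Subject identifier (character).
#' @param leg_length Leg length in m, in (0.5, 1.5).
#' @param walk_step_length Walking step length in m (used by the default and
#'   walk/run step-length models), or `NA`.
#' @param run_step_length Running step length in m, or `NA`.
#' @param calibration_step_length,calibration_cadence Optional calibration
#'   measurements (m; steps/min).
#' @param walk_ratio Individual walk ratio in m per (step/min), or `NA`
#'   (used by the simulator to emulate inter-subject variability).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(id, leg_length,
                            walk_step_length = NA_real_,
                            run_step_length = NA_real_,
                            calibration_step_length = NA_real_,
                            calibration_cadence = NA_real_,
                            walk_ratio = NA_real_) {
  if (!(leg_length > 0.5 && leg_length < 1.5))
    stop("leg_length must be in (0.5, 1.5) m")
  for (sl in c(walk_step_length, run_step_length, calibration_step_length)) {
    if (!is.na(sl) && !(sl > 0.1 && sl < 3.0))
      stop("step lengths must be in (0.1, 3.0) m when present")
  }
  structure(list(id = as.character(id), leg_length = leg_length,
                 walk_step_length = walk_step_length,
                 run_step_length = run_step_length,
                 calibration_step_length = calibration_step_length,
                 calibration_cadence = calibration_cadence,
                 walk_ratio = walk_ratio),
            class = "subject_profile")
}

#' Session annotation
#'
#' Ordered, non-overlapping labelled intervals describing the protocol
#' structure of a recording session (activity levels and rest gaps).
#'
#' @param label Character labels, one per interval.
#' @param start_s,end_s Interval boundaries in session time (s), half-open.
#' @param kind `"activity"` or `"rest"` per interval.
#' @return An object of class `session_annotation` (a data.frame).
#' @export
session_annotation <- function(label, start_s, end_s, kind) {
  df <- data.frame(label = as.character(label), start_s = start_s,
                   end_s = end_s, kind = as.character(kind))
  if (any(df$end_s <= df$start_s)) stop("intervals must have positive length")
  if (!all(df$kind %in% c("activity", "rest")))
    stop('kind must be "activity" or "rest"')
  o <- order(df$start_s)
  df <- df[o, , drop = FALSE]
  if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)] - 1e-9))
    stop("annotation intervals must not overlap")
  rownames(df) <- NULL
  structure(df, class = c("session_annotation", "data.frame"))
}

G_PER_MS2 <- 9.81

#' Read a tri-axial acceleration CSV
#'
#' Expects a header `time,x,y,z` with a monotone time column at a fixed
#' sampling rate. Non-uniform sampling is rejected with the index of the
#' first offending gap.
#'
#' @param path CSV file path.
#' @param unit Unit of the stored samples: `"m/s2"` (default, loaded as-is)
#'   or `"g"` (multiplied by 9.81 on load).
#' @return An [accel_signal()] in m/s^2.
#' @export
read_accel_csv <- function(path, unit = c("m/s2", "g")) {
  unit <- match.arg(unit)
  df <- read.csv(path)
  need <- c("time", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (nrow(df) < 2L) stop("need at least 2 samples to infer sampling rate")
  dt <- diff(df$time)
  bad <- which(abs(dt - dt[1L]) > 1e-6 * max(1, abs(dt[1L])))
  if (length(bad))
    stop(sprintf("non-uniform sampling: time step changes at row %d", bad[1L]))
  if (dt[1L] <= 0) stop("time column must be strictly increasing")
  fac <- if (unit == "g") G_PER_MS2 else 1
  accel_signal(df$x * fac, df$y * fac, df$z * fac,
               fs = 1 / dt[1L], t0 = df$time[1L])
}

#' Write a tri-axial acceleration CSV
#' @param signal An [accel_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(signal, path) {
  df <- data.frame(time = accel_time(signal), x = signal$x, y = signal$y,
                   z = signal$z)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a 1 Hz speed CSV
#' @param path CSV file with header `time,speed`.
#' @return A [speed_trace()].
#' @export
read_speed_csv <- function(path) {
  df <- read.csv(path)
  miss <- setdiff(c("time", "speed"), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  speed_trace(df$time, df$speed)
}

#' Write a 1 Hz speed CSV
#' @param trace A [speed_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_speed_csv <- function(trace, path) {
  write.csv(as.data.frame(unclass(trace))[c("time", "speed")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read/write subject metadata as JSON
#' @param subject A [subject_profile()].
#' @param path JSON file path.
#' @return `read_subject_json` returns a [subject_profile()];
#'   `write_subject_json` returns `path` invisibly.
#' @export
write_subject_json <- function(subject, path) {
  jsonlite::write_json(unclass(subject), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_subject_json
#' @export
read_subject_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  subject_profile(lst$id, num(lst$leg_length),
                  walk_step_length = num(lst$walk_step_length),
                  run_step_length = num(lst$run_step_length),
                  calibration_step_length = num(lst$calibration_step_length),
                  calibration_cadence = num(lst$calibration_cadence),
                  walk_ratio = num(lst$walk_ratio))
}

#' Read/write a session annotation as JSON
#' @param annotation A [session_annotation()].
#' @param path JSON file path.
#' @export
write_annotation_json <- function(annotation, path) {
  jsonlite::write_json(as.data.frame(unclass(annotation)), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  session_annotation(df$label, df$start_s, df$end_s, df$kind)
}
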