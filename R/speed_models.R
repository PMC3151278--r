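#' Walk ratio
#'
#' The ratio between step length (m) and step frequency (steps/min),
#' approximately constant across walking speeds within a person. The
#' default 0.0065 m/(steps/min) is the conventional population value.
#'
#' @param ratio Walk ratio in m per (step/min), in (0.002, 0.02).
#' @param source `"default"` or `"calibrated"`.
#' @return An object of class `walk_ratio`.
#' @export
walk_ratio <- function(ratio = 0.0065, source = c("default", "calibrated")) {
  source <- match.arg(source)
  if (!(ratio > 0.002 && ratio < 0.02))
    stop("walk ratio must be in (0.002, 0.02) m/(steps/min)")
  structure(list(ratio = ratio, source = source), class = "walk_ratio")
}

#' Step-length (default) speed model
#'
#' Distance = step count x walking step length; speed = distance / duration.
#'
#' @param steps A `step_intervals` object from [detect_steps()].
#' @param subject A [subject_profile()] with `walk_step_length` set.
#' @param duration_s Interval duration (s).
#' @return Estimated speed (m/s).
#' @export
predict_steplength_default <- function(steps, subject, duration_s) {
  if (is.na(subject$walk_step_length))
    stop("subject walk_step_length is not configured")
  if (duration_s <= 0) stop("duration must be positive")
  n_steps(steps) * subject$walk_step_length / duration_s
}

#' Step-length (walk/run) speed model
#'
#' As the default model, but running steps contribute the running step
#' length: distance = n_walk x walk length + n_run x run length.
#'
#' @inheritParams predict_steplength_default
#' @export
predict_steplength_walkrun <- function(steps, subject, duration_s) {
  if (is.na(subject$walk_step_length) || is.na(subject$run_step_length))
    stop("subject walk and run step lengths must both be configured")
  if (duration_s <= 0) stop("duration must be positive")
  n <- n_steps(steps)
  cls <- attr(steps, "gait_class") %||% "walk"
  n_run <- if (identical(cls, "run")) n else 0L
  n_walk <- n - n_run
  (n_walk * subject$walk_step_length + n_run * subject$run_step_length) /
    duration_s
}

#' Step-length (inverted pendulum) speed model
#'
#' Per step, the vertical centre-of-mass excursion `h` is recovered by
#' double integration of the (drift-corrected) vertical acceleration over
#' the step; the step length follows from the pendulum geometry
#' `d = k * 2 * sqrt(2*L*h - h^2)` with leg length `L` and correction
#' factor `k`. The interval speed is the duration-weighted mean of the
#' per-step speeds `d / step_duration`.
#'
#' Steps whose recovered excursion is degenerate (`h <= 0` or `h >= L`) are
#' skipped and counted in the `"n_skipped"` attribute.
#'
#' @param signal The segment [accel_signal()].
#' @param steps A `step_intervals` object from [detect_steps()].
#' @param subject A [subject_profile()] with `leg_length` set.
#' @param k Step-length correction factor (default 1; ~1.25 in parts of the
#'   literature).
#' @param cutoff_hz Drift-removal low-pass cut-off (Hz).
#' @return Estimated interval speed (m/s), with per-step speeds as
#'   attribute `"per_step"` and the skip count as `"n_skipped"`.
#' @export
predict_steplength_pendulum <- function(signal, steps, subject, k = 1,
                                        cutoff_hz = 0.1) {
  L <- subject$leg_length
  fs <- signal$fs
  if (nrow(steps) == 0L) {
    out <- 0
    attr(out, "per_step") <- numeric(0)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  xd <- detrend_lowfreq(signal$x, fs, cutoff_hz = cutoff_hz)
  d_j <- rep(NA_real_, nrow(steps))
  T_j <- (steps$end - steps$start) / fs
  for (i in seq_len(nrow(steps))) {
    idx <- steps$start[i]:(steps$end[i] - 1L)
    t <- (seq_along(idx) - 1L) / fs
    v1 <- pracma::cumtrapz(t, xd[idx])
    p <- as.numeric(pracma::cumtrapz(t, as.numeric(v1)))
    # the unknown initial velocity at the step boundary shows up as a
    # linear ramp in the displacement; remove it before reading off the
    # excursion
    beta <- cov(t, p) / var(t)
    p <- p - beta * t
    h <- max(p) - min(p)
    if (h <= 0 || h >= L) next
    d_j[i] <- k * 2 * sqrt(2 * L * h - h^2)
  }
  ok <- !is.na(d_j)
  speed <- if (any(ok)) sum(d_j[ok]) / sum(T_j[ok]) else 0
  attr(speed, "per_step") <- d_j / T_j
  attr(speed, "n_skipped") <- sum(!ok)
  speed
}

#' Walk-ratio speed model
#'
#' Cadence `C` (steps/min) is measured over the interval; step length is
#' `wr * C`, hence speed `= wr * C^2 / 60`.
#'
#' @param steps A `step_intervals` object from [detect_steps()].
#' @param duration_s Interval duration (s).
#' @param wr A [walk_ratio()].
#' @return Estimated speed (m/s); 0 when no steps were detected.
#' @export
predict_walkratio <- function(steps, duration_s, wr = walk_ratio()) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- n_steps(steps)
  if (n == 0L) return(0)
  cadence <- n / duration_s * 60
  wr$ratio * cadence^2 / 60
}

#' Calibrate an individual walk ratio
#'
#' From a calibration bout with measured cadence and known speed: step
#' length = speed / (cadence / 60), ratio = step length / cadence.
#' Alternatively pass an explicit step length instead of a speed.
#'
#' @param cadence Cadence in steps/min (> 0).
#' @param speed Known speed (m/s); ignored if `step_length` is given.
#' @param step_length Optional explicit step length (m).
#' @return A [walk_ratio()] with `source = "calibrated"`.
#' @export
calibrate_walkratio <- function(cadence, speed = NULL, step_length = NULL) {
  if (cadence <= 0) stop("cadence must be positive")
  if (is.null(step_length)) {
    if (is.null(speed)) stop("provide either speed or step_length")
    step_length <- speed / (cadence / 60)
  }
  walk_ratio(step_length / cadence, source = "calibrated")
}

#' Direct-integration speed model
#'
#' The antero-posterior channel is drift-corrected by subtracting its
#' low-pass (0.1 Hz, zero-phase Butterworth) component, integrated to
#' velocity by cumulative trapezoids, and the residual integration drift is
#' removed from the velocity with the same low-pass subtraction. The speed
#' of each 1 s bin is estimated as the amplitude of the velocity
#' oscillation (`sqrt(2)` x RMS); the interval estimate is the median over
#' bins, which is robust to the filter's boundary transients (the 0.1 Hz
#' low-pass settles over roughly 10 s at each segment end). The forward
#' velocity oscillates about the mean walking speed with amplitude equal
#' to that speed, which makes the amplitude estimator invariant to the
#' (arbitrary) gait phase at the segment start.
#'
#' @param signal The segment [accel_signal()] (at least 2 s).
#' @param cutoff_hz Drift-removal cut-off (Hz).
#' @param detrend If `FALSE`, skip both drift corrections (testing hook for
#'   closed-form checks).
#' @param return_velocity If `TRUE`, return the velocity series (m/s)
#'   instead of the speed estimate.
#' @return Estimated speed (m/s), or the velocity series if
#'   `return_velocity`.
#' @export
predict_integration <- function(signal, cutoff_hz = 0.1, detrend = TRUE,
                                return_velocity = FALSE) {
  fs <- signal$fs
  n <- n_samples(signal)
  if (n < 2 * fs) stop("interval must be at least 2 s for integration")
  a <- signal$y
  if (detrend) a <- detrend_lowfreq(a, fs, cutoff_hz = cutoff_hz)
  t <- (seq_len(n) - 1L) / fs
  v <- as.numeric(pracma::cumtrapz(t, a))
  if (return_velocity && !detrend) return(v)
  if (detrend) v <- detrend_lowfreq(v, fs, cutoff_hz = cutoff_hz)
  if (return_velocity) return(v)
  nsec <- floor(n / fs)
  amp <- vapply(seq_len(nsec), function(s) {
    idx <- (round((s - 1L) * fs) + 1L):round(s * fs)
    sqrt(2) * sqrt(mean(v[idx]^2))
  }, numeric(1))
  max(0, median(amp))
}
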