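#' Energy channel
#'
#' Per-sample Euclidean norm of the three acceleration components:
#' `e_i = sqrt(x_i^2 + y_i^2 + z_i^2)`.
#'
#' @param signal An [accel_signal()].
#' @return Numeric vector of per-sample energies (m/s^2).
#' @export
energy_channel <- function(signal) {
  sqrt(signal$x^2 + signal$y^2 + signal$z^2)
}

#' Step-detection parameters
#'
#' Peak detection on the vertical channel with gait-class-specific
#' thresholds and refractory delays. A bout is classified as running when
#' the RMS of its demeaned vertical channel exceeds `run_rms_threshold`.
#'
#' @param walk_threshold,run_threshold Peak height above the bout mean
#'   (m/s^2).
#' @param walk_delay_s,run_delay_s Refractory delay before the next peak (s).
#' @param run_rms_threshold Vertical-RMS walk/run classification boundary
#'   (m/s^2).
#' @param smooth_window_s Moving-average smoothing applied to the vertical
#'   channel before peak picking (s); reduces spurious noise peaks.
#' @return A list of class `step_detect_params`.
#' @export
step_detect_params <- function(walk_threshold = 0.5, walk_delay_s = 0.30,
                               run_threshold = 2.5, run_delay_s = 0.20,
                               run_rms_threshold = 3.5,
                               smooth_window_s = 0.10) {
  structure(list(walk_threshold = walk_threshold,
                 walk_delay_s = walk_delay_s,
                 run_threshold = run_threshold, run_delay_s = run_delay_s,
                 run_rms_threshold = run_rms_threshold,
                 smooth_window_s = smooth_window_s),
            class = "step_detect_params")
}

# Centered moving average with edge truncation.
moving_avg <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(0L, i - 1L - half)
  hi <- pmin(n, i - 1L + (w - half))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Detect steps in a gait bout
#'
#' The input is treated as one contiguous bout: it is first classified as
#' walking or running from the vertical-channel RMS, then peaks exceeding
#' the class threshold (above the bout mean) are picked with the class
#' refractory delay. Each detected peak is one step; the returned intervals
#' partition the span between consecutive peaks (half-open, 1-based
#' `[start, end)` sample indices).
#'
#' @param signal An [accel_signal()] of at least 1 s.
#' @param params A [step_detect_params()].
#' @return A data.frame of class `step_intervals` with columns `start`,
#'   `end`, `gait_class` (one row per inter-peak interval; `n_peaks - 1`
#'   rows). Attributes: `"peaks"` (sample indices of the detected peaks),
#'   `"n_steps"` (number of peaks = step count), `"gait_class"` (bout
#'   class), `"fs"`.
#' @export
detect_steps <- function(signal, params = step_detect_params()) {
  fs <- signal$fs
  if (n_samples(signal) < fs) stop("signal must be at least 1 s long")
  x <- signal$x - mean(signal$x)
  xs <- moving_avg(x, max(1L, round(params$smooth_window_s * fs)))
  bout_rms <- sqrt(mean(x^2))
  gait_class <- if (bout_rms > params$run_rms_threshold) "run" else "walk"
  thr <- if (gait_class == "run") params$run_threshold else
    params$walk_threshold
  delay <- if (gait_class == "run") params$run_delay_s else
    params$walk_delay_s
  # zero = "+" accepts plateau peaks (exactly symmetric sampling around a
  # waveform maximum yields two equal samples at the top)
  pk <- pracma::findpeaks(xs, minpeakheight = thr, zero = "+",
                          minpeakdistance = max(1L, round(delay * fs)))
  peaks <- if (is.null(pk)) integer(0) else sort(pk[, 2L])
  if (length(peaks) >= 2L) {
    ivs <- data.frame(start = peaks[-length(peaks)], end = peaks[-1L],
                      gait_class = gait_class)
  } else {
    ivs <- data.frame(start = integer(0), end = integer(0),
                      gait_class = character(0))
  }
  structure(ivs, class = c("step_intervals", "data.frame"),
            peaks = peaks, n_steps = length(peaks), gait_class = gait_class,
            fs = fs)
}

#' Step count of a detection result
#'
#' The number of detected steps equals the number of vertical-channel peaks
#' (one more than the number of inter-peak intervals).
#'
#' @param steps A `step_intervals` object from [detect_steps()].
#' @export
n_steps <- function(steps) {
  n <- attr(steps, "n_steps")
  if (is.null(n)) nrow(steps) + (nrow(steps) > 0L) else n
}

# Canonical feature order: Table-style feature set per channel, channels
# x, y, z, e, plus the step duration once (41 names).
FEATURE_BASE <- c("min", "max", "mean", "sum", "sum_abs", "range", "rms",
                  "max_minus_mean", "step_amplitude",
                  "minmax_amplitude_duration")
FEATURE_CHANNELS <- c("x", "y", "z", "e")

#' Canonical per-step feature names
#'
#' Ten features per channel (`x`, `y`, `z`, `e`) plus `step_duration`:
#' 41 names in the fixed column order used by [feature_matrix()].
#'
#' @return Character vector of length 41.
#' @export
feature_names <- function() {
  c(as.vector(vapply(FEATURE_CHANNELS,
                     function(ch) paste(FEATURE_BASE, ch, sep = "_"),
                     character(length(FEATURE_BASE)))),
    "step_duration")
}

# Ten features of one channel slice.
channel_features <- function(v, fs) {
  mn <- min(v); mx <- max(v); me <- mean(v)
  imax <- which.max(v); imin <- which.min(v)
  c(min = mn, max = mx, mean = me, sum = sum(v), sum_abs = sum(abs(v)),
    range = mx - mn, rms = sqrt(mean(v^2)), max_minus_mean = mx - me,
    step_amplitude = v[imax] - min(v[seq_len(imax)]),
    minmax_amplitude_duration = (imax - imin) / fs)
}

#' Extract the 41 per-step features
#'
#' For each channel (`x`, `y`, `z` and the energy `e`): minimum, maximum,
#' mean, sum, sum of absolute values, range, RMS, maximum minus mean, step
#' amplitude (peak value minus the preceding trough within the step), and
#' the signed time from the channel minimum to its maximum; plus the step
#' duration.
#'
#' @param signal An [accel_signal()].
#' @param start,end Step interval, 1-based half-open `[start, end)` sample
#'   indices; at least 2 samples.
#' @param e Optional precomputed energy channel (avoids recomputation).
#' @return Named numeric vector of length 41 in [feature_names()] order.
#' @export
extract_features <- function(signal, start, end, e = NULL) {
  n <- n_samples(signal)
  if (start < 1L || end > n + 1L || end - start < 2L)
    stop("step interval out of bounds or shorter than 2 samples")
  idx <- start:(end - 1L)
  if (is.null(e)) e <- energy_channel(signal)
  fs <- signal$fs
  out <- c(channel_features(signal$x[idx], fs),
           channel_features(signal$y[idx], fs),
           channel_features(signal$z[idx], fs),
           channel_features(e[idx], fs),
           length(idx) / fs)
  names(out) <- feature_names()
  out
}

#' Per-step feature matrix
#'
#' @param signal An [accel_signal()].
#' @param steps A `step_intervals` object (or any data.frame with `start`
#'   and `end` columns).
#' @return A data.frame with one row per step and the 41 columns of
#'   [feature_names()], in that order.
#' @export
feature_matrix <- function(signal, steps) {
  nms <- feature_names()
  if (nrow(steps) == 0L) {
    df <- as.data.frame(matrix(numeric(0), 0L, length(nms)))
    names(df) <- nms
    return(df)
  }
  e <- energy_channel(signal)
  m <- vapply(seq_len(nrow(steps)), function(i) {
    extract_features(signal, steps$start[i], steps$end[i], e = e)
  }, numeric(length(nms)))
  df <- as.data.frame(t(m))
  names(df) <- nms
  df
}
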