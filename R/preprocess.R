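#' Centered moving RMS
#'
#' @param x Numeric vector.
#' @param fs Sampling frequency (Hz).
#' @param window_s Window width (s); windows are truncated at the edges.
#' @return Numeric vector, same length as `x`.
#' @export
moving_rms <- function(x, fs, window_s = 1) {
  n <- length(x)
  w <- max(1L, round(window_s * fs))
  half <- w %/% 2L
  cs <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(0L, i - 1L - half)
  hi <- pmin(n, i - 1L + (w - half))
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

# Energy channel with a robust (median) per-channel offset removal, so the
# detector behaves identically whether or not the vertical channel carries
# the constant gravity component.
dynamic_energy <- function(signal) {
  sqrt((signal$x - median(signal$x))^2 +
       (signal$y - median(signal$y))^2 +
       (signal$z - median(signal$z))^2)
}

#' Detect inactivity (rest) intervals
#'
#' Finds maximal intervals where the moving RMS of the gravity-free energy
#' channel stays below a threshold for at least `min_duration_s`.
#'
#' @param signal An [accel_signal()].
#' @param min_duration_s Minimum rest duration (s).
#' @param energy_threshold RMS threshold (m/s^2).
#' @param window_s Moving-RMS window (s).
#' @return A data.frame with columns `start_s`, `end_s`, `start`, `end`
#'   (sample indices, half-open), possibly empty; sorted, non-overlapping.
#' @export
detect_inactivity <- function(signal, min_duration_s = 5,
                              energy_threshold = 0.5, window_s = 1) {
  fs <- signal$fs
  if (n_samples(signal) < min_duration_s * fs)
    stop("signal shorter than min_duration_s")
  rms <- moving_rms(dynamic_energy(signal), fs, window_s)
  below <- rms < energy_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration_s * fs
  if (!any(keep))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      start = integer(0), end = integer(0)))
  data.frame(start_s = signal$t0 + (starts[keep] - 1L) / fs,
             end_s = signal$t0 + ends[keep] / fs,
             start = starts[keep], end = ends[keep] + 1L)
}

#' Activity intervals (complement of detected rests)
#'
#' @param signal An [accel_signal()].
#' @param rests Rest intervals from [detect_inactivity()]; computed if
#'   missing.
#' @param min_duration_s Discard activity intervals shorter than this (s).
#' @param ... Passed to [detect_inactivity()].
#' @return A data.frame with columns `start_s`, `end_s`.
#' @export
activity_intervals <- function(signal, rests = NULL, min_duration_s = 10,
                               ...) {
  if (is.null(rests)) rests <- detect_inactivity(signal, ...)
  t_end <- signal$t0 + n_samples(signal) / signal$fs
  edges_start <- c(signal$t0, rests$end_s)
  edges_end <- c(rests$start_s, t_end)
  df <- data.frame(start_s = edges_start, end_s = edges_end)
  df <- df[df$end_s - df$start_s >= min_duration_s, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Synchronize accelerometer and reference speed streams
#'
#' Both streams are reduced to binary activity profiles on a 1 s grid (the
#' accelerometer via the moving-RMS energy criterion, the trace via
#' `speed > speed_threshold`); the returned lag maximizes their agreement.
#' The lag is the number of seconds by which the trace clock leads the
#' accelerometer clock: subtract it from the trace timestamps to align
#' (see [apply_lag()]).
#'
#' @param signal An [accel_signal()].
#' @param trace A [speed_trace()].
#' @param max_lag_s Search range (s); lags in `-max_lag_s:max_lag_s`.
#' @param energy_threshold RMS threshold for the accelerometer profile
#'   (m/s^2).
#' @param speed_threshold Speed threshold for the trace profile (m/s).
#' @return Integer lag in seconds.
#' @export
synchronize <- function(signal, trace, max_lag_s = 60,
                        energy_threshold = 0.5, speed_threshold = 0.05) {
  fs <- signal$fs
  e <- dynamic_energy(signal)
  nsec <- floor(n_samples(signal) / fs)
  if (nsec < 2L) stop("signal too short to synchronize")
  sec_rms <- vapply(seq_len(nsec), function(s) {
    idx <- ((s - 1L) * fs + 1L):(s * fs)
    sqrt(mean(e[idx]^2))
  }, numeric(1))
  a_bin <- sec_rms > energy_threshold
  a_time <- floor(signal$t0) + seq_len(nsec) - 1L
  t_bin <- trace$speed > speed_threshold
  t_time <- round(trace$time)
  if (length(unique(a_bin)) < 2L || length(unique(t_bin)) < 2L)
    stop("cannot synchronize: no activity/rest transitions in one of the streams")
  lags <- seq.int(-max_lag_s, max_lag_s)
  score <- vapply(lags, function(l) {
    idx <- match(a_time + l, t_time)
    ok <- !is.na(idx)
    if (sum(ok) < 10L) return(-Inf)
    mean(a_bin[ok] == t_bin[idx[ok]])
  }, numeric(1))
  best <- which(score == max(score))
  lags[best[which.min(abs(lags[best]))]]
}

#' Shift a speed trace onto the accelerometer clock
#' @param trace A [speed_trace()].
#' @param lag Lag in seconds, as returned by [synchronize()].
#' @return A [speed_trace()] with `time - lag`.
#' @export
apply_lag <- function(trace, lag) speed_trace(trace$time - lag, trace$speed)

#' Aligned segment
#'
#' One activity interval with matched accelerometer and reference-speed
#' slices on a common clock.
#'
#' @param accel [accel_signal()] slice.
#' @param speed [speed_trace()] slice.
#' @param label Interval label.
#' @param lag Lag (s) that was applied to the trace.
#' @return An object of class `aligned_segment`.
#' @export
aligned_segment <- function(accel, speed, label, lag = 0) {
  structure(list(accel = accel, speed = speed, label = label, lag = lag),
            class = "aligned_segment")
}

#' Segment and align a session
#'
#' Detects rest gaps in the accelerometer stream, synchronizes the reference
#' trace, and returns one [aligned_segment()] per activity interval.
#'
#' @param accel An [accel_signal()].
#' @param trace A [speed_trace()].
#' @param labels Optional labels for the activity intervals in order;
#'   defaults to `level_1, level_2, ...`.
#' @param max_lag_s,energy_threshold Passed to [synchronize()] /
#'   [detect_inactivity()].
#' @param min_rest_s,min_activity_s Minimum rest / activity durations (s).
#' @return A list of [aligned_segment()]s with the applied lag as attribute
#'   `"lag"`.
#' @export
align_session <- function(accel, trace, labels = NULL, max_lag_s = 60,
                          energy_threshold = 0.5, min_rest_s = 5,
                          min_activity_s = 10) {
  rests <- detect_inactivity(accel, min_duration_s = min_rest_s,
                             energy_threshold = energy_threshold)
  acts <- activity_intervals(accel, rests, min_duration_s = min_activity_s)
  if (nrow(acts) == 0L) stop("no activity intervals found")
  lag <- synchronize(accel, trace, max_lag_s = max_lag_s,
                     energy_threshold = energy_threshold)
  trace_al <- apply_lag(trace, lag)
  if (is.null(labels)) labels <- paste0("level_", seq_len(nrow(acts)))
  if (length(labels) < nrow(acts))
    stop("fewer labels than detected activity intervals")
  segs <- lapply(seq_len(nrow(acts)), function(i) {
    a <- slice_accel(accel, acts$start_s[i], acts$end_s[i])
    keep <- trace_al$time >= acts$start_s[i] - 1e-9 &
      trace_al$time < acts$end_s[i] - 1e-9
    aligned_segment(a, speed_trace(trace_al$time[keep],
                                   trace_al$speed[keep]),
                    label = labels[i], lag = lag)
  })
  attr(segs, "lag") <- lag
  segs
}

#' Trim segment boundaries
#'
#' Cuts `trim_s` seconds from both ends of an aligned segment, discarding
#' the unreliable gait-initiation/termination phases.
#'
#' @param segment An [aligned_segment()].
#' @param trim_s Seconds to cut at each end (default 5).
#' @return The trimmed [aligned_segment()].
#' @export
trim_boundaries <- function(segment, trim_s = 5) {
  dur <- n_samples(segment$accel) / segment$accel$fs
  if (dur <= 2 * trim_s)
    stop(sprintf("segment '%s' too short to trim (%.1f s <= %.1f s)",
                 segment$label, dur, 2 * trim_s))
  a <- segment$accel
  new_start <- a$t0 + trim_s
  new_end <- a$t0 + dur - trim_s
  a2 <- slice_accel(a, new_start, new_end)
  keep <- segment$speed$time >= new_start - 1e-9 &
    segment$speed$time < new_end - 1e-9
  aligned_segment(a2, speed_trace(segment$speed$time[keep],
                                  segment$speed$speed[keep]),
                  label = segment$label, lag = segment$lag)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Designs a digital Butterworth low-pass (via [signal::butter()]) and
#' applies it forward-backward (zero phase, squared magnitude response).
#' The input is demeaned and extended by odd reflection over `3 / cutoff_hz`
#' seconds at both ends before filtering, so edge transients decay inside
#' the padding and the DC gain is exactly 1.
#'
#' @param x Numeric vector.
#' @param fs Sampling frequency (Hz).
#' @param order Filter order (default 4).
#' @param cutoff_hz Cut-off frequency (Hz, default 0.1); must be below the
#'   Nyquist frequency.
#' @return Filtered vector, same length as `x`.
#' @export
butterworth_lowpass <- function(x, fs, order = 4, cutoff_hz = 0.1) {
  if (cutoff_hz >= fs / 2) stop("cutoff_hz must be below the Nyquist frequency")
  n <- length(x)
  if (n < 4L) stop("signal too short to filter")
  mu <- mean(x)
  xc <- x - mu
  P <- min(n - 1L, as.integer(ceiling(3 * fs / cutoff_hz)))
  ext <- c(2 * xc[1L] - xc[(P + 1L):2L], xc, 2 * xc[n] - xc[(n - 1L):(n - P)])
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, ext)
  y[(P + 1L):(P + n)] + mu
}

#' Remove slow drift by subtracting the low-pass component
#'
#' High-pass detrending used before and after integration: the 0.1 Hz
#' low-pass component (the drift) is estimated with
#' [butterworth_lowpass()] and subtracted.
#'
#' @inheritParams butterworth_lowpass
#' @return Detrended vector.
#' @export
detrend_lowfreq <- function(x, fs, order = 4, cutoff_hz = 0.1) {
  x - butterworth_lowpass(x, fs, order = order, cutoff_hz = cutoff_hz)
}
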