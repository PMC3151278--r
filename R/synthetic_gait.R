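#' Parameters of the single-step waveform
#'
#' The simulator builds gait bouts from per-step waveform blocks that satisfy
#' the inverted-pendulum geometry: a subject with leg length `L` taking steps
#' of length `d` vaults over the stance leg, so the vertical centre-of-mass
#' excursion is `h = L - sqrt(L^2 - d^2/4)` (peak to peak).
#'
#' @param step_frequency Step frequency f in steps/s, in (0.3, 5).
#' @param step_length Step length d in m, in (0.1, 3); must satisfy `d < 2L`.
#' @param leg_length Leg length L in m.
#' @param noise_sd Additive white Gaussian noise per channel, m/s^2.
#' @param harmonic_weights Optional numeric weights of higher vertical
#'   harmonics (k = 2, 3, ...) relative to the fundamental; they add
#'   waveform realism at the cost of perturbing the exact pendulum geometry.
#' @return An object of class `gait_waveform_params` with the derived
#'   excursion `h` attached.
#' @export
gait_waveform_params <- function(step_frequency, step_length, leg_length,
                                 noise_sd = 0, harmonic_weights = numeric(0)) {
  f <- step_frequency; d <- step_length; L <- leg_length
  if (!(f > 0.3 && f < 5)) stop("step_frequency must be in (0.3, 5) steps/s")
  if (!(d > 0 && d < 3)) stop("step_length must be in (0, 3) m")
  if (d >= 2 * L)
    stop(sprintf("pendulum geometry requires d < 2*L (d = %.3f, L = %.3f)",
                 d, L))
  h <- L - sqrt(L^2 - d^2 / 4)
  structure(list(step_frequency = f, step_length = d, leg_length = L,
                 noise_sd = noise_sd, harmonic_weights = harmonic_weights,
                 h = h),
            class = "gait_waveform_params")
}

#' Synthesize one step of tri-axial acceleration
#'
#' Vertical channel: exact second derivative of a centre-of-mass path with
#' peak-to-peak excursion `h`, with its single dominant peak at mid-step so
#' peak detection finds exactly one peak per step and bout edges are troughs.
#' Antero-posterior channel: zero-mean oscillation at the step frequency with
#' amplitude `2*pi*f*(f*d)`, chosen so that its time integral oscillates with
#' amplitude equal to the true speed `f*d`. Medio-lateral channel: half-cycle
#' arch at the stride frequency `f/2`, sign alternating with `stride_phase`.
#'
#' @param params A [gait_waveform_params()].
#' @param fs Sampling frequency (Hz); must be at least `20 * f`.
#' @param stride_phase 0 or 1; alternate between consecutive steps to make
#'   the medio-lateral channel a continuous stride-frequency oscillation.
#' @return A numeric matrix with `round(fs / f)` rows and columns
#'   `x`, `y`, `z`; the vertical excursion is attached as attribute `"h"`.
#' @export
make_step_waveform <- function(params, fs, stride_phase = 0L) {
  stopifnot(inherits(params, "gait_waveform_params"))
  f <- params$step_frequency; d <- params$step_length
  h <- params$h
  if (fs < 20 * f) stop("fs must be at least 20 * step_frequency")
  n <- round(fs / f)
  t <- (seq_len(n) - 1L) / fs
  omega <- 2 * pi * f
  v <- f * d
  x <- -(h / 2) * omega^2 * cos(omega * t)
  if (length(params$harmonic_weights)) {
    for (k in seq_along(params$harmonic_weights)) {
      w <- params$harmonic_weights[k]
      x <- x - w * (h / 2) * omega^2 * cos((k + 1) * omega * t)
    }
  }
  y <- omega * v * sin(omega * t)
  z <- 1.5 * v * cos(pi * f * t) * if (stride_phase %% 2 == 0) 1 else -1
  m <- cbind(x = x, y = y, z = z)
  if (params$noise_sd > 0)
    m <- m + matrix(rnorm(length(m), 0, params$noise_sd), nrow = n)
  attr(m, "h") <- h
  m
}

#' Protocol specification for simulated sessions
#'
#' @param speeds Ordered target speeds (m/s), one per activity level.
#' @param level_duration_s Duration of each activity level (s); default 90
#'   (1.5 min). Either a single value or one per level.
#' @param rest_duration_s Duration of the inactivity gaps between levels (s);
#'   default 15. A lead-in and lead-out rest of the same duration is added.
#' @param mode `"indoor_levels"` or `"outdoor_ramp"`.
#' @param labels Optional labels, one per level; defaults to
#'   `level_1, level_2, ...`.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(speeds, level_duration_s = 90, rest_duration_s = 15,
                          mode = c("indoor_levels", "outdoor_ramp"),
                          labels = NULL) {
  mode <- match.arg(mode)
  if (any(level_duration_s <= 0) || rest_duration_s <= 0)
    stop("durations must be positive")
  level_duration_s <- rep_len(level_duration_s, length(speeds))
  if (is.null(labels)) labels <- paste0("level_", seq_along(speeds))
  if (length(labels) != length(speeds))
    stop("labels must match speeds in length")
  structure(list(speeds = speeds, level_duration_s = level_duration_s,
                 rest_duration_s = rest_duration_s, mode = mode,
                 labels = labels),
            class = "protocol_spec")
}

#' The five-level indoor protocol
#'
#' Five self-selected gait speeds from slow walking to running, 1.5 min per
#' level, separated by 15 s inactivity gaps. The default speeds are the
#' study-condition level means (m/s).
#'
#' @param speeds Level mean speeds (m/s).
#' @param level_duration_s,rest_duration_s Durations in seconds.
#' @return A [protocol_spec()] with the standard level labels.
#' @export
indoor_protocol <- function(speeds = c(0.65, 1.11, 1.47, 1.83, 2.70),
                            level_duration_s = 90, rest_duration_s = 15) {
  std <- c("slow_walking", "normal_walking", "fast_walking",
           "even_faster_walking", "running")
  labels <- if (length(speeds) == 5L) std else paste0("level_",
                                                      seq_along(speeds))
  protocol_spec(speeds, level_duration_s, rest_duration_s,
                mode = "indoor_levels", labels = labels)
}

# Split a target speed into (step frequency, step length) via the walk-ratio
# prior; cap the step length for running. Gait class is "run" when the cap
# engages or the speed exceeds the walk-run transition speed.
speed_to_gait <- function(speed, walk_ratio = 0.0065, step_length_cap = 1.0,
                          leg_length = 0.9, run_transition_speed = 2.3) {
  if (speed <= 0) stop("speed must be positive")
  cadence <- sqrt(60 * speed / walk_ratio)        # steps/min
  d <- walk_ratio * cadence
  capped <- d > step_length_cap
  if (capped) d <- step_length_cap
  f <- speed / d
  if (d >= 2 * leg_length)
    stop(sprintf("speed %.2f m/s unachievable: step length %.2f >= 2*leg length",
                 speed, d))
  list(f = f, d = d,
       gait_class = if (capped || speed >= run_transition_speed) "run" else "walk")
}

# Generate the jittered step schedule for one constant-speed bout.
# Step durations are quantized to whole samples; the per-step length is then
# d_j = speed * n_j / fs so every step's true speed is exactly `speed`.
bout_step_schedule <- function(speed, f, d, duration_s, fs, jitter_sd) {
  steps <- list(); t_used <- 0; i <- 0L
  n_level <- round(duration_s * fs)
  while (TRUE) {
    eps <- if (jitter_sd > 0) max(-3 * jitter_sd,
                                  min(3 * jitter_sd, rnorm(1, 0, jitter_sd)))
           else 0
    d_j <- d * (1 + eps)
    n_j <- max(2L, round(fs * d_j / speed))
    if (t_used + n_j > n_level) break
    d_j <- speed * n_j / fs
    i <- i + 1L
    steps[[i]] <- c(n = n_j, d = d_j)
    t_used <- t_used + n_j
  }
  do.call(rbind, steps)
}

#' Simulate a constant-speed gait bout
#'
#' Convenience generator for a single bout at a fixed step frequency and
#' length, with known true step count. Used for step-detection and pendulum
#' round-trip checks.
#'
#' @param f Step frequency (steps/s).
#' @param d Step length (m).
#' @param L Leg length (m).
#' @param duration_s Bout duration (s); the bout holds `floor(duration_s*f)`
#'   whole steps, the remainder is padded with noise.
#' @param fs Sampling frequency (Hz).
#' @param noise_sd Additive white noise per channel (m/s^2).
#' @param seed Optional integer seed.
#' @return A list with elements `accel` (an [accel_signal()]), `steps` (truth
#'   table with one row per step), and `n_steps`.
#' @export
simulate_bout <- function(f, d, L = 0.9, duration_s = 60, fs = 100,
                          noise_sd = 0, seed = NULL) {
  # snap f to a whole number of samples per step so consecutive waveform
  # blocks are phase-continuous (no spurious drift under integration)
  f <- fs / round(fs / f)
  gen <- function() {
    par <- gait_waveform_params(f, d, L)
    n_steps <- floor(duration_s * f)
    blocks <- lapply(seq_len(n_steps) - 1L,
                     function(j) make_step_waveform(par, fs, stride_phase = j))
    m <- do.call(rbind, blocks)
    n_total <- round(duration_s * fs)
    if (nrow(m) < n_total)
      m <- rbind(m, matrix(0, n_total - nrow(m), 3L))
    if (noise_sd > 0)
      m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow = nrow(m))
    per <- round(fs / f)
    start <- (seq_len(n_steps) - 1L) * per + 1L
    truth <- data.frame(start = start, end = start + per,
                        start_s = (start - 1L) / fs,
                        end_s = (start - 1L + per) / fs,
                        step_length = d, speed = f * d,
                        gait_class = "walk", label = "bout")
    list(accel = accel_signal(m[, 1L], m[, 2L], m[, 3L], fs = fs),
         steps = truth, n_steps = as.integer(n_steps))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a full protocol session with ground truth
#'
#' Builds a paired (acceleration, reference speed, annotation, per-step
#' truth) session: for each protocol level the target speed is split into
#' step frequency and length via the subject's walk-ratio prior, per-step
#' lengths are jittered, and levels are separated by low-noise inactivity
#' gaps. The 1 Hz reference trace carries the exact level speed.
#'
#' @param protocol A [protocol_spec()]; default [indoor_protocol()].
#' @param subject A [subject_profile()]; `walk_ratio` (default 0.0065) and
#'   `run_step_length` (default 1.0 m, the running step-length cap) are used
#'   when present.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param fs Sampling frequency (Hz).
#' @param noise_sd White noise during activity (m/s^2).
#' @param rest_noise_sd White noise during rests (m/s^2).
#' @param step_jitter_sd Per-step step-length jitter, as a fraction of the
#'   level step length.
#' @param include_gravity If `TRUE`, add a constant 9.81 m/s^2 to the
#'   vertical channel (device conventions differ on whether the gravity
#'   component is present).
#' @return An object of class `gait_session`: list with `accel`
#'   ([accel_signal()]), `speed` ([speed_trace()]), `annotation`
#'   ([session_annotation()]), `steps` (per-step truth table), `subject`,
#'   `protocol`.
#' @export
simulate_session <- function(protocol = indoor_protocol(), subject = NULL,
                             seed = 1, fs = 100, noise_sd = 0.3,
                             rest_noise_sd = 0.05, step_jitter_sd = 0.03,
                             include_gravity = FALSE) {
  if (is.null(subject))
    subject <- subject_profile("S00", leg_length = 0.9,
                               walk_step_length = 0.66,
                               run_step_length = 1.0, walk_ratio = 0.0065)
  wr <- if (is.na(subject$walk_ratio)) 0.0065 else subject$walk_ratio
  cap <- if (is.na(subject$run_step_length)) 1.0 else subject$run_step_length
  L <- subject$leg_length
  with_seed(seed, {
    rest_n <- round(protocol$rest_duration_s * fs)
    level_ns <- round(rep_len(protocol$level_duration_s,
                              length(protocol$speeds)) * fs)
    blocks <- list(); ann <- list(); truth <- list()
    cursor <- 0L  # samples emitted so far
    emit_rest <- function(lab) {
      blocks[[length(blocks) + 1L]] <<-
        matrix(rnorm(rest_n * 3L, 0, rest_noise_sd), rest_n, 3L)
      ann[[length(ann) + 1L]] <<- data.frame(
        label = lab, start_s = cursor / fs, end_s = (cursor + rest_n) / fs,
        kind = "rest")
      cursor <<- cursor + rest_n
    }
    emit_rest("rest_0")
    for (i in seq_along(protocol$speeds)) {
      v <- protocol$speeds[i]
      level_n <- level_ns[i]
      g <- tryCatch(speed_to_gait(v, wr, cap, L),
                    error = function(e)
                      stop(sprintf("level %d (%s): %s", i, protocol$labels[i],
                                   conditionMessage(e))))
      sched <- bout_step_schedule(v, g$f, g$d, level_n / fs, fs,
                                  step_jitter_sd)
      level_start <- cursor
      step_blocks <- vector("list", nrow(sched))
      pos <- cursor
      for (j in seq_len(nrow(sched))) {
        n_j <- sched[j, "n"]; d_j <- sched[j, "d"]
        f_j <- fs / n_j
        par <- gait_waveform_params(f_j, d_j, L)
        step_blocks[[j]] <- make_step_waveform(par, fs, stride_phase = j)
        truth[[length(truth) + 1L]] <- data.frame(
          start = pos + 1L, end = pos + n_j + 1L,
          start_s = pos / fs, end_s = (pos + n_j) / fs,
          step_length = d_j, speed = v, gait_class = g$gait_class,
          label = protocol$labels[i])
        pos <- pos + n_j
      }
      m <- do.call(rbind, step_blocks)
      if (nrow(m) < level_n) m <- rbind(m, matrix(0, level_n - nrow(m), 3L))
      if (noise_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow = nrow(m))
      blocks[[length(blocks) + 1L]] <- m
      ann[[length(ann) + 1L]] <- data.frame(
        label = protocol$labels[i], start_s = level_start / fs,
        end_s = (level_start + level_n) / fs, kind = "activity")
      cursor <- level_start + level_n
      emit_rest(if (i < length(protocol$speeds)) paste0("rest_", i)
                else "rest_end")
    }
    m <- do.call(rbind, blocks)
    if (include_gravity) m[, 1L] <- m[, 1L] + G_PER_MS2
    accel <- accel_signal(m[, 1L], m[, 2L], m[, 3L], fs = fs)
    anndf <- do.call(rbind, ann)
    annotation <- session_annotation(anndf$label, anndf$start_s, anndf$end_s,
                                     anndf$kind)
    total_s <- cursor / fs
    tt <- seq(0, floor(total_s) - 1)
    sp <- numeric(length(tt))
    act <- anndf[anndf$kind == "activity", , drop = FALSE]
    for (i in seq_len(nrow(act))) {
      inside <- tt >= act$start_s[i] & tt + 1 <= act$end_s[i]
      sp[inside] <- protocol$speeds[match(act$label[i], protocol$labels)]
    }
    structure(list(accel = accel, speed = speed_trace(tt, sp),
                   annotation = annotation,
                   steps = do.call(rbind, truth),
                   subject = subject, protocol = protocol),
              class = "gait_session")
  })
}

#' Simulate an outdoor ramp session
#'
#' Speed increases piecewise-linearly from `speed_start` to `speed_peak`,
#' peaking after half the total distance, then decreases symmetrically; no
#' rest gaps within the walk (a lead-in/lead-out rest frames the bout so the
#' streams can be synchronized).
#'
#' @param subject A [subject_profile()] (default as in [simulate_session()]).
#' @param seed Integer seed.
#' @param total_distance_m Total distance covered (m); default 812.
#' @param speed_start,speed_peak Ramp endpoints (m/s).
#' @param fs,noise_sd,rest_noise_sd,step_jitter_sd As in
#'   [simulate_session()].
#' @param rest_s Lead-in/lead-out rest duration (s).
#' @return A `gait_session` (see [simulate_session()]); the activity
#'   interval is labelled `"outdoor_ramp"`.
#' @export
simulate_outdoor_ramp <- function(subject = NULL, seed = 1,
                                  total_distance_m = 812,
                                  speed_start = 0.8, speed_peak = 2.0,
                                  fs = 100, noise_sd = 0.3,
                                  rest_noise_sd = 0.05,
                                  step_jitter_sd = 0.03, rest_s = 15) {
  if (is.null(subject))
    subject <- subject_profile("S00", leg_length = 0.9,
                               walk_step_length = 0.66,
                               run_step_length = 1.0, walk_ratio = 0.0065)
  wr <- if (is.na(subject$walk_ratio)) 0.0065 else subject$walk_ratio
  cap <- if (is.na(subject$run_step_length)) 1.0 else subject$run_step_length
  L <- subject$leg_length
  D <- total_distance_m
  profile_speed <- function(s) {
    half <- D / 2
    if (s <= half) speed_start + (speed_peak - speed_start) * s / half
    else speed_start + (speed_peak - speed_start) * (D - s) / half
  }
  with_seed(seed, {
    rest_n <- round(rest_s * fs)
    rest1 <- matrix(rnorm(rest_n * 3L, 0, rest_noise_sd), rest_n, 3L)
    dist <- 0; pos <- rest_n; j <- 0L
    step_blocks <- list(); truth <- list()
    while (dist < D) {
      v_j <- profile_speed(dist)
      g <- speed_to_gait(v_j, wr, cap, L)
      eps <- if (step_jitter_sd > 0)
        max(-3 * step_jitter_sd,
            min(3 * step_jitter_sd, rnorm(1, 0, step_jitter_sd))) else 0
      d_j <- g$d * (1 + eps)
      n_j <- max(2L, round(fs * d_j / v_j))
      d_j <- v_j * n_j / fs
      f_j <- fs / n_j
      j <- j + 1L
      par <- gait_waveform_params(f_j, d_j, L)
      step_blocks[[j]] <- make_step_waveform(par, fs, stride_phase = j)
      truth[[j]] <- data.frame(
        start = pos + 1L, end = pos + n_j + 1L,
        start_s = pos / fs, end_s = (pos + n_j) / fs,
        step_length = d_j, speed = v_j, gait_class = g$gait_class,
        label = "outdoor_ramp")
      pos <- pos + n_j
      dist <- dist + d_j
    }
    walk <- do.call(rbind, step_blocks)
    if (noise_sd > 0)
      walk <- walk + matrix(rnorm(length(walk), 0, noise_sd),
                            nrow = nrow(walk))
    rest2 <- matrix(rnorm(rest_n * 3L, 0, rest_noise_sd), rest_n, 3L)
    m <- rbind(rest1, walk, rest2)
    accel <- accel_signal(m[, 1L], m[, 2L], m[, 3L], fs = fs)
    steps <- do.call(rbind, truth)
    annotation <- session_annotation(
      c("rest_0", "outdoor_ramp", "rest_end"),
      c(0, rest_n / fs, (rest_n + nrow(walk)) / fs),
      c(rest_n / fs, (rest_n + nrow(walk)) / fs, nrow(m) / fs),
      c("rest", "activity", "rest"))
    total_s <- floor(nrow(m) / fs)
    tt <- seq(0, total_s - 1)
    sp <- numeric(length(tt))
    act_sec <- tt + 0.5
    inside <- act_sec >= min(steps$start_s) & act_sec < max(steps$end_s)
    idx <- findInterval(act_sec[inside], steps$start_s)
    sp[inside] <- steps$speed[pmax(1L, idx)]
    structure(list(accel = accel, speed = speed_trace(tt, sp),
                   annotation = annotation, steps = steps,
                   subject = subject,
                   protocol = protocol_spec(c(speed_start, speed_peak),
                                            level_duration_s = 1,
                                            rest_duration_s = rest_s,
                                            mode = "outdoor_ramp",
                                            labels = c("ramp_up", "ramp_down"))),
              class = "gait_session")
  })
}

#' Draw a synthetic subject cohort
#'
#' Emulates inter-subject variability: walk ratio uniform in
#' \[0.0055, 0.0075\] m/(steps/min), leg length uniform in \[0.8, 1.05\] m,
#' running step-length cap uniform in \[0.95, 1.10\] m. The subject's
#' nominal walking step length is their step length at 1.11 m/s (normal
#' walking) under their own walk ratio.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param id_prefix Prefix for subject ids.
#' @return A list of [subject_profile()] objects.
#' @export
simulate_cohort <- function(n, seed = 1, id_prefix = "S") {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      wr <- runif(1, 0.0055, 0.0075)
      L <- runif(1, 0.8, 1.05)
      cap <- runif(1, 0.95, 1.10)
      wsl <- sqrt(60 * 1.11 * wr)  # d at normal walking speed under this WR
      subject_profile(sprintf("%s%02d", id_prefix, i), leg_length = L,
                      walk_step_length = wsl, run_step_length = cap,
                      walk_ratio = wr)
    })
  })
}

#' Write a simulated session to a directory
#'
#' Emits the CSV/JSON formats of the I/O layer: `accel.csv`, `speed.csv`,
#' `annotation.json`, `subject.json`, `steps.csv` (truth table).
#'
#' @param session A `gait_session` from [simulate_session()] or
#'   [simulate_outdoor_ramp()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_accel_csv(session$accel, file.path(dir, "accel.csv"))
  write_speed_csv(session$speed, file.path(dir, "speed.csv"))
  write_annotation_json(session$annotation, file.path(dir, "annotation.json"))
  write_subject_json(session$subject, file.path(dir, "subject.json"))
  write.csv(session$steps, file.path(dir, "steps.csv"), row.names = FALSE)
  invisible(dir)
}
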