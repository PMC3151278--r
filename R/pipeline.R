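#' The twelve candidate algorithm labels
#'
#' Row set of the ranking report, in no particular order: five
#' step-length/walk-ratio methods, three linear-regression and three
#' support-vector-regression models, and direct integration.
#'
#' @return Character vector of length 12.
#' @export
algorithm_ids <- function() {
  c("Step length (default)", "Step length (walk/run)",
    "Step length (pendulum)", "Walk ratio (default)",
    "Walk ratio (calibrated)", "LR (MA-model)", "LR (C-model)",
    "LR (RBWE-model)", "SVR (MA-model)", "SVR (C-model)",
    "SVR (energy-model)", "Integration")
}

# Map an algorithm label to its regression model key, or NA.
regression_key <- function(algorithm) {
  switch(algorithm,
         "LR (MA-model)" = "LR.MA", "LR (C-model)" = "LR.C",
         "LR (RBWE-model)" = "LR.RBWE", "SVR (MA-model)" = "SVR.MA",
         "SVR (C-model)" = "SVR.C", "SVR (energy-model)" = "SVR.Energy",
         NA_character_)
}

#' Train the six regression speed models
#'
#' Simulates a training cohort, segments each session with the known
#' protocol annotation, trims boundaries, detects steps, extracts the
#' per-step features and reference speeds, and fits LR (MA, C, RBWE) and
#' SVR (MA, C, Energy) models. SVR hyperparameters default to the shipped
#' values of [svr_defaults()].
#'
#' @param n_subjects Training cohort size (default 15).
#' @param protocol Training protocol (default [indoor_protocol()]).
#' @param seed Integer seed (cohort draw and session noise).
#' @param step_params [step_detect_params()].
#' @param trim_s Boundary trim (s).
#' @param max_steps Optional cap on the pooled training-step count
#'   (stratified thinning keeps every k-th step); `Inf` to disable.
#' @param ... Passed to [simulate_session()].
#' @return Named list of `gait_speed_model`s keyed `LR.MA`, `LR.C`,
#'   `LR.RBWE`, `SVR.MA`, `SVR.C`, `SVR.Energy`, with the pooled training
#'   size as attribute `"n_steps"`.
#' @export
train_speed_models <- function(n_subjects = 15, protocol = indoor_protocol(),
                               seed = 1, step_params = step_detect_params(),
                               trim_s = 5, max_steps = 6000, ...) {
  cohort <- simulate_cohort(n_subjects, seed = seed)
  feats <- list(); targs <- list()
  for (i in seq_along(cohort)) {
    sess <- simulate_session(protocol, cohort[[i]], seed = seed + i, ...)
    act <- sess$annotation[sess$annotation$kind == "activity", , drop = FALSE]
    for (j in seq_len(nrow(act))) {
      a <- slice_accel(sess$accel, act$start_s[j] + trim_s,
                       act$end_s[j] - trim_s)
      st <- detect_steps(a, step_params)
      if (nrow(st) == 0L) next
      fm <- feature_matrix(a, st)
      tg <- step_target_speeds(st, a$fs, sess$speed, t0 = a$t0)
      feats[[length(feats) + 1L]] <- fm
      targs[[length(targs) + 1L]] <- tg
    }
  }
  X <- do.call(rbind, feats)
  y <- unlist(targs, use.names = FALSE)
  if (is.finite(max_steps) && nrow(X) > max_steps) {
    keep <- seq(1L, nrow(X), length.out = max_steps)
    keep <- unique(as.integer(round(keep)))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  models <- list(
    LR.MA = fit_regression(X, y, "MA", kind = "LR"),
    LR.C = fit_regression(X, y, "C", kind = "LR"),
    LR.RBWE = fit_regression(X, y, "RBWE", kind = "LR"),
    SVR.MA = fit_regression(X, y, "MA", kind = "SVR"),
    SVR.C = fit_regression(X, y, "C", kind = "SVR"),
    SVR.Energy = fit_regression(X, y, "Energy", kind = "SVR"))
  attr(models, "n_steps") <- nrow(X)
  models
}

#' Run all twelve algorithms on aligned segments
#'
#' Evaluates every algorithm on each (trimmed) aligned segment. Algorithms
#' whose prerequisites are missing (no trained models, no calibrated walk
#' ratio, unset step lengths) produce explicit skip records rather than
#' silent gaps.
#'
#' @param segments List of [aligned_segment()]s (typically trimmed with
#'   [trim_boundaries()]).
#' @param subject A [subject_profile()].
#' @param models Named model list from [train_speed_models()], or `NULL`.
#' @param wr Default [walk_ratio()].
#' @param wr_calibrated Calibrated [walk_ratio()], or `NULL` (skipped).
#' @param step_params [step_detect_params()].
#' @param k Pendulum correction factor.
#' @return A data.frame with one row per (segment, algorithm): `label`,
#'   `algorithm`, `estimate`, `reference` (mean segment reference speed),
#'   `n_steps`, `skipped`, `reason`.
#' @export
run_algorithm_suite <- function(segments, subject, models = NULL,
                                wr = walk_ratio(), wr_calibrated = NULL,
                                step_params = step_detect_params(), k = 1) {
  rows <- list()
  for (seg in segments) {
    a <- seg$accel
    dur <- n_samples(a) / a$fs
    st <- detect_steps(a, step_params)
    fm <- feature_matrix(a, st)
    durs <- (st$end - st$start) / a$fs
    reference <- if (nrow(seg$speed)) mean(seg$speed$speed) else NA_real_
    est <- function(algorithm, expr) {
      res <- tryCatch(list(value = expr, reason = NA_character_),
                      error = function(e) list(value = NA_real_,
                                               reason = conditionMessage(e)))
      data.frame(label = seg$label, algorithm = algorithm,
                 estimate = as.numeric(res$value), reference = reference,
                 n_steps = n_steps(st), skipped = is.na(res$value),
                 reason = res$reason)
    }
    rows[[length(rows) + 1L]] <- est(
      "Step length (default)", predict_steplength_default(st, subject, dur))
    rows[[length(rows) + 1L]] <- est(
      "Step length (walk/run)", predict_steplength_walkrun(st, subject, dur))
    rows[[length(rows) + 1L]] <- est(
      "Step length (pendulum)",
      as.numeric(predict_steplength_pendulum(a, st, subject, k = k)))
    rows[[length(rows) + 1L]] <- est(
      "Walk ratio (default)", predict_walkratio(st, dur, wr))
    rows[[length(rows) + 1L]] <- est(
      "Walk ratio (calibrated)",
      if (is.null(wr_calibrated))
        stop("no calibrated walk ratio available") else
        predict_walkratio(st, dur, wr_calibrated))
    for (alg in c("LR (MA-model)", "LR (C-model)", "LR (RBWE-model)",
                  "SVR (MA-model)", "SVR (C-model)", "SVR (energy-model)")) {
      key <- regression_key(alg)
      rows[[length(rows) + 1L]] <- est(
        alg,
        if (is.null(models) || is.null(models[[key]]))
          stop("no trained model available") else
          predict_regression(models[[key]], fm, durs)$speed)
    }
    rows[[length(rows) + 1L]] <- est("Integration", predict_integration(a))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate the walk ratio from an aligned segment
#'
#' Uses the segment's detected cadence and mean reference speed (the
#' normal-walking level in the standard protocol) to derive an individual
#' walk ratio.
#'
#' @param segment A trimmed [aligned_segment()].
#' @param step_params [step_detect_params()].
#' @return A calibrated [walk_ratio()].
#' @export
calibrate_from_segment <- function(segment,
                                   step_params = step_detect_params()) {
  a <- segment$accel
  st <- detect_steps(a, step_params)
  dur <- n_samples(a) / a$fs
  cadence <- n_steps(st) / dur * 60
  calibrate_walkratio(cadence, speed = mean(segment$speed$speed))
}

#' Evaluate one subject's session with all algorithms
#'
#' Aligns the session (inactivity detection + synchronization), trims
#' segment boundaries, calibrates the walk ratio on the calibration level,
#' and runs the algorithm suite.
#'
#' @param session A `gait_session`.
#' @param models Trained models from [train_speed_models()].
#' @param calibration_label Segment label used for walk-ratio calibration
#'   (default `"normal_walking"`); `NULL` to skip calibration.
#' @param step_params,wr,trim_s,k As in [run_algorithm_suite()].
#' @return The suite data.frame with a `cluster` column (subject id).
#' @export
evaluate_session <- function(session, models = NULL,
                             calibration_label = "normal_walking",
                             step_params = step_detect_params(),
                             wr = walk_ratio(), trim_s = 5, k = 1) {
  labels <- session$annotation$label[session$annotation$kind == "activity"]
  segs <- align_session(session$accel, session$speed, labels = labels)
  segs <- lapply(segs, trim_boundaries, trim_s = trim_s)
  wr_cal <- NULL
  if (!is.null(calibration_label)) {
    cal_seg <- Filter(function(s) s$label == calibration_label, segs)
    if (length(cal_seg))
      wr_cal <- calibrate_from_segment(cal_seg[[1L]], step_params)
  }
  out <- run_algorithm_suite(segs, session$subject, models = models, wr = wr,
                             wr_calibrated = wr_cal,
                             step_params = step_params, k = k)
  out$cluster <- session$subject$id
  out
}

#' Run configuration
#'
#' All tunables of the end-to-end experiment with their defaults. The
#' serialized configuration fully determines a run.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param n_train,n_eval Training / evaluation cohort sizes.
#' @param protocol A [protocol_spec()].
#' @param noise_sd,rest_noise_sd,step_jitter_sd Simulator settings.
#' @param step_params [step_detect_params()].
#' @param wr_default Default walk ratio.
#' @param pendulum_k Pendulum correction factor.
#' @param deltas CP boundaries (m/s).
#' @param n_boot Bootstrap resamples for report CIs.
#' @param trim_s Boundary trim (s).
#' @param max_train_steps Cap on pooled training steps.
#' @param calibration_label Level used for walk-ratio calibration.
#' @param write_sessions Also write the raw simulated session CSVs.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_train = 15, n_eval = 17,
                       protocol = indoor_protocol(), noise_sd = 0.3,
                       rest_noise_sd = 0.05, step_jitter_sd = 0.03,
                       step_params = step_detect_params(),
                       wr_default = 0.0065, pendulum_k = 1,
                       deltas = c(0.1, 0.2, 0.3), n_boot = 500,
                       trim_s = 5, max_train_steps = 6000,
                       calibration_label = "normal_walking",
                       write_sessions = FALSE, out_dir = tempfile("gaitspeed_run_")) {
  structure(as.list(environment()), class = "run_config")
}

# Stage seeds derived from the master seed; kept below 2^31.
stage_seed <- function(master, counter) {
  (as.integer(master) + counter * 10007L) %% .Machine$integer.max
}

#' Run the full experiment end to end
#'
#' simulate (training cohort) -> train -> simulate (evaluation cohort) ->
#' preprocess/steps/predict -> validate. Writes the per-interval pairs, the
#' ranking reports (including and excluding running), CP-band plots, the
#' trained models, the configuration, and a MANIFEST with checksums to
#' `config$out_dir`. Deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `report` (full), `report_excl_running`,
#'   `pairs`, `models`, `out_dir`.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logf("stage %-10s %.1f s", name, as.numeric(Sys.time() - t0, "secs"))
    res
  }
  models <- stage("train", train_speed_models(
    n_subjects = config$n_train, protocol = config$protocol,
    seed = stage_seed(config$seed, 1L), step_params = config$step_params,
    trim_s = config$trim_s, max_steps = config$max_train_steps,
    noise_sd = config$noise_sd, rest_noise_sd = config$rest_noise_sd,
    step_jitter_sd = config$step_jitter_sd))
  eval_cohort <- simulate_cohort(config$n_eval,
                                 seed = stage_seed(config$seed, 2L),
                                 id_prefix = "E")
  pairs <- stage("evaluate", {
    out <- list()
    for (i in seq_along(eval_cohort)) {
      sess <- simulate_session(config$protocol, eval_cohort[[i]],
                               seed = stage_seed(config$seed, 100L + i),
                               noise_sd = config$noise_sd,
                               rest_noise_sd = config$rest_noise_sd,
                               step_jitter_sd = config$step_jitter_sd)
      if (config$write_sessions)
        write_session(sess, file.path(config$out_dir, "data",
                                      eval_cohort[[i]]$id))
      out[[i]] <- evaluate_session(
        sess, models = models,
        calibration_label = config$calibration_label,
        step_params = config$step_params,
        wr = walk_ratio(config$wr_default), trim_s = config$trim_s,
        k = config$pendulum_k)
    }
    do.call(rbind, out)
  })
  ok <- !pairs$skipped
  report <- stage("validate", rank_algorithms(
    pairs[ok, ], deltas = config$deltas, n_boot = config$n_boot,
    seed = stage_seed(config$seed, 3L)))
  report_ex <- rank_algorithms(pairs[ok, ], deltas = config$deltas,
                               exclude_running = TRUE,
                               n_boot = config$n_boot,
                               seed = stage_seed(config$seed, 3L))
  stage("write", {
    write.csv(pairs, file.path(config$out_dir, "pairs.csv"),
              row.names = FALSE)
    write_agreement_report(report, file.path(config$out_dir, "report.csv"))
    write_agreement_report(report_ex,
                           file.path(config$out_dir,
                                     "report_excl_running.csv"))
    for (key in names(models))
      write_model_json(models[[key]],
                       file.path(config$out_dir,
                                 paste0("model_", key, ".json")))
    cfg <- config
    cfg$protocol <- unclass(cfg$protocol)
    cfg$step_params <- unclass(cfg$step_params)
    jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")],
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    for (lab in unique(pairs$label)) {
      p <- pairs[ok & pairs$label == lab, , drop = FALSE]
      if (nrow(p) >= 2L)
        plot_cp_bands(p, deltas = config$deltas,
                      file = file.path(config$out_dir,
                                       paste0("cp_bands_", lab, ".pdf")))
    }
    TRUE
  })
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "MANIFEST.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))))
  write.csv(manifest, file.path(config$out_dir, "MANIFEST.csv"),
            row.names = FALSE)
  logf("done: %d artifacts", nrow(manifest))
  invisible(list(report = report, report_excl_running = report_ex,
                 pairs = pairs, models = models, out_dir = config$out_dir))
}
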