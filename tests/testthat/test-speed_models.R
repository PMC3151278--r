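# A fixed fake step-detection object with a known peak count and class.
fake_steps <- function(n_peaks, gait_class = "walk", fs = 100,
                       step_samples = 50L) {
  if (n_peaks >= 2L) {
    start <- (seq_len(n_peaks - 1L) - 1L) * step_samples + 1L
    df <- data.frame(start = start, end = start + step_samples,
                     gait_class = gait_class)
  } else {
    df <- data.frame(start = integer(0), end = integer(0),
                     gait_class = character(0))
  }
  structure(df, class = c("step_intervals", "data.frame"),
            peaks = seq_len(n_peaks), n_steps = n_peaks,
            gait_class = gait_class, fs = fs)
}

test_that("step-length models are the stated arithmetic", {
  sub <- subject_profile("S", 0.9, walk_step_length = 0.70,
                         run_step_length = 1.2)
  expect_equal(predict_steplength_default(fake_steps(90), sub, 60), 1.05)
  expect_equal(predict_steplength_default(fake_steps(0), sub, 60), 0)

  # all-walk reduces to the default model
  expect_equal(predict_steplength_walkrun(fake_steps(90), sub, 60),
               predict_steplength_default(fake_steps(90), sub, 60))
  # 100 running steps at 1.2 m over 50 s
  expect_equal(predict_steplength_walkrun(fake_steps(100, "run"), sub, 50),
               2.4)
  sub_nosl <- subject_profile("S", 0.9)
  expect_error(predict_steplength_default(fake_steps(10), sub_nosl, 10),
               "walk_step_length")
})

test_that("walk/run model with equal step lengths equals the default model", {
  sub_eq <- subject_profile("S", 0.9, walk_step_length = 0.8,
                            run_step_length = 0.8)
  for (cls in c("walk", "run")) {
    st <- fake_steps(77, cls)
    expect_identical(predict_steplength_walkrun(st, sub_eq, 45),
                     predict_steplength_default(st, sub_eq, 45))
  }
})

test_that("walk-ratio model follows speed = wr * cadence^2 / 60", {
  wr <- walk_ratio(0.0065)
  st <- fake_steps(120)  # 120 steps over 60 s -> cadence 120 steps/min
  expect_equal(predict_walkratio(st, 60, wr), 0.78 * 2)  # d = 0.78 m
  expect_equal(predict_walkratio(fake_steps(0), 60, wr), 0)
  # doubling cadence quadruples speed
  expect_equal(predict_walkratio(fake_steps(240), 60, wr),
               4 * predict_walkratio(fake_steps(120), 60, wr))
})

test_that("walk-ratio calibration inverts the definition and round-trips", {
  cal <- calibrate_walkratio(110, speed = 1.11)
  expect_equal(cal$ratio, (1.11 * 60 / 110) / 110, tolerance = 1e-12)
  expect_identical(cal$source, "calibrated")
  expect_equal(cal$ratio, 0.005505, tolerance = 1e-3)
  # predicting on the calibration bout recovers the calibration speed
  st <- fake_steps(110)
  expect_equal(predict_walkratio(st, 60, cal), 1.11, tolerance = 1e-9)
  expect_error(calibrate_walkratio(0, speed = 1), "cadence")

  # calibrated ratio recovers a simulated subject's walk ratio
  sub <- subject_profile("S", 0.9, walk_ratio = 0.006, run_step_length = 1.0)
  s <- simulate_session(subject = sub, seed = 17)
  labels <- s$annotation$label[s$annotation$kind == "activity"]
  segs <- lapply(align_session(s$accel, s$speed, labels = labels),
                 trim_boundaries)
  cal_seg <- segs[[which(labels == "normal_walking")]]
  got <- calibrate_from_segment(cal_seg)
  expect_equal(got$ratio, 0.006, tolerance = 0.03)
})

test_that("pendulum geometry inverts the simulator geometry", {
  # closed form: h for L = 0.9, d = 0.7 maps back to d = 0.7 at k = 1
  h <- 0.9 - sqrt(0.81 - 0.7^2 / 4)
  expect_equal(h, 0.0708, tolerance = 1e-3)
  expect_equal(2 * sqrt(2 * 0.9 * h - h^2), 0.7, tolerance = 1e-9)

  b <- simulate_bout(1.8, 0.7, L = 0.9, duration_s = 60)
  st <- detect_steps(b$accel)
  sub <- subject_profile("P", 0.9)
  est <- predict_steplength_pendulum(b$accel, st, sub, k = 1)
  expect_equal(as.numeric(est), b$steps$speed[1], tolerance = 0.05)
  expect_identical(attr(est, "n_skipped"), 0L)

  # k scales the estimate linearly
  est2 <- predict_steplength_pendulum(b$accel, st, sub, k = 1.25)
  expect_equal(as.numeric(est2), 1.25 * as.numeric(est), tolerance = 1e-9)
})

test_that("integration matches closed forms", {
  fs <- 100
  # constant acceleration from rest: v(t) = a * t (detrend hook off)
  n <- 1000
  sig <- accel_signal(rep(0, n), rep(2.5, n), rep(0, n), fs = fs)
  v <- predict_integration(sig, detrend = FALSE, return_velocity = TRUE)
  t <- (seq_len(n) - 1) / fs
  expect_equal(v, 2.5 * t, tolerance = 0.001 * max(2.5 * t))

  # zero signal -> zero speed
  zero <- accel_signal(rep(0, 500), rep(0, 500), rep(0, 500), fs = fs)
  expect_equal(predict_integration(zero), 0)

  # sinusoid A*sin(2*pi*f*t): velocity amplitude A / (2*pi*f)
  n2 <- 3000; t2 <- (seq_len(n2) - 1) / fs
  sig2 <- accel_signal(rep(0, n2), sin(2 * pi * 1 * t2), rep(0, n2),
                       fs = fs)
  expect_equal(predict_integration(sig2), 1 / (2 * pi), tolerance = 0.01)

  expect_error(predict_integration(accel_signal(0:50 * 0, 0:50 * 0,
                                                0:50 * 0, fs = 100)),
               "2 s")
})

test_that("integration recovers simulated constant-speed segments", {
  s <- simulate_session(seed = 77)
  labels <- s$annotation$label[s$annotation$kind == "activity"]
  segs <- lapply(align_session(s$accel, s$speed, labels = labels),
                 trim_boundaries)
  for (seg in segs) {
    ref <- mean(seg$speed$speed)
    expect_equal(predict_integration(seg$accel), ref, tolerance = 0.10 * ref)
  }
})

test_that("regression models use the declared feature subsets", {
  expect_identical(model_features("MA"), "max_minus_mean_x")
  expect_identical(model_features("Energy"),
                   c("sum_abs_x", "sum_abs_y", "sum_abs_z", "mean_e"))
  expect_identical(length(model_features("C")), 13L)
  expect_identical(length(model_features("RBWE")), 5L)
  expect_true(all(unlist(lapply(c("MA", "C", "Energy", "RBWE"),
                                model_features)) %in% feature_names()))
  expect_error(model_features("XYZ"), "unknown")
  expect_equal(svr_defaults("Energy")$C, 64)
  expect_equal(svr_defaults("MA")$gamma, 0.03)
  expect_equal(svr_defaults("C")$epsilon, 0.01)
})

test_that("LR fitting flags a rank-deficient design", {
  set.seed(5)
  n <- 80
  fm <- as.data.frame(matrix(rnorm(n * 41), n, 41))
  names(fm) <- feature_names()
  # duplicate one RBWE feature into another so the design is collinear
  fm$rms_z <- fm$sum_abs_z
  y <- fm$sum_abs_z + rnorm(n, 0, 0.01)
  expect_warning(fit_regression(fm, y, "RBWE", kind = "LR"), "rank")
})

test_that("identity LR model predicts its single feature", {
  model <- structure(list(
    kind = "LR", model_name = "MA", features = "max_minus_mean_x",
    center = c(max_minus_mean_x = 0), scale = c(max_minus_mean_x = 1),
    fit = list(coefficients = c(0, 1)), hyper = NULL, n_train = 50L),
    class = "gait_speed_model")
  fm <- data.frame(max_minus_mean_x = 1.3, step_duration = 0.5)
  out <- predict_regression(model, fm)
  expect_equal(out$per_step, 1.3)
  expect_equal(out$speed, 1.3)
  # empty input gives an empty estimate
  empty <- predict_regression(model, fm[0, , drop = FALSE])
  expect_identical(empty$per_step, numeric(0))
  # negative predictions are clipped and counted
  model$fit$coefficients <- c(0, -1)
  clip <- predict_regression(model, fm)
  expect_equal(clip$per_step, 0)
  expect_identical(clip$n_clipped, 1L)
  expect_error(predict_regression(model,
                                  data.frame(step_duration = 1)),
               "missing column")
})

test_that("grid search selects the dominating point deterministically", {
  set.seed(31)
  n <- 120
  fm <- as.data.frame(matrix(rnorm(n * 41), n, 41))
  names(fm) <- feature_names()
  y <- 2 * fm$max_minus_mean_x + 1
  # single-point grid: that point is returned, CV table has one row
  g1 <- grid_search_svr(fm, y, "MA", C_grid = 10, gamma_grid = 0.5,
                        eps_grid = 0.1, folds = 5, seed = 3)
  expect_identical(nrow(g1$cv), 1L)
  expect_equal(g1$model$hyper$C, 10)

  # noiseless linear target: a tight-epsilon/high-C point dominates a
  # loose-epsilon/low-C one
  g2 <- grid_search_svr(fm, y, "MA", C_grid = c(0.01, 100),
                        gamma_grid = 0.5, eps_grid = c(0.001, 2),
                        folds = 5, seed = 3)
  expect_identical(which.min(g2$cv$mse),
                   which(g2$cv$C == 100 & g2$cv$epsilon == 0.001))
  expect_equal(g2$model$hyper$epsilon, 0.001)

  g3 <- grid_search_svr(fm, y, "MA", C_grid = c(0.01, 100),
                        gamma_grid = 0.5, eps_grid = c(0.001, 2),
                        folds = 5, seed = 3)
  expect_identical(g2$cv, g3$cv)
  expect_error(grid_search_svr(fm[1:4, ], y[1:4], "MA", 1, 1, 0.1,
                               folds = 10), "folds")
})

test_that("fitted models serialize to JSON and predict identically", {
  b <- simulate_bout(1.8, 0.7, duration_s = 120, noise_sd = 0.3, seed = 13)
  st <- detect_steps(b$accel)
  fm <- feature_matrix(b$accel, st)
  y <- b$steps$speed[seq_len(nrow(fm))] + rnorm(nrow(fm), 0, 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  for (kind in c("LR", "SVR")) {
    m <- fit_regression(fm, y, "Energy", kind = kind)
    write_model_json(m, path)
    m2 <- read_model_json(path)
    expect_equal(predict_regression(m2, fm)$per_step,
                 predict_regression(m, fm)$per_step, tolerance = 1e-9)
  }
})

test_that("per-step targets interpolate the reference trace", {
  tr <- speed_trace(0:9, c(rep(1, 5), rep(2, 5)))
  steps <- data.frame(start = c(101L, 701L), end = c(201L, 801L))
  tg <- step_target_speeds(steps, fs = 100, tr)
  expect_equal(tg[1], 1, tolerance = 1e-9)   # fully inside the 1 m/s part
  expect_equal(tg[2], 2, tolerance = 1e-9)   # fully inside the 2 m/s part
})
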