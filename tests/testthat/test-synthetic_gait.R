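test_that("step waveform satisfies the pendulum geometry", {
  p <- gait_waveform_params(2, 0.7, 0.9)
  expect_equal(p$h, 0.9 - sqrt(0.81 - 0.1225), tolerance = 1e-12)

  m <- make_step_waveform(p, 100)
  expect_identical(nrow(m), 50L)  # fs / f samples per step

  # double integration of the vertical channel over whole steps recovers
  # the excursion h within 1% (trapezoidal oracle)
  blocks <- do.call(rbind, lapply(0:4, function(j)
    make_step_waveform(p, 100, stride_phase = j)))
  t <- (seq_len(nrow(blocks)) - 1) / 100
  v <- pracma::cumtrapz(t, blocks[, "x"])
  disp <- pracma::cumtrapz(t, as.numeric(v))
  one_step <- disp[1:50]
  expect_equal(max(one_step) - min(one_step), p$h, tolerance = 0.01)

  # degenerate pendulum: d -> 0 gives a silent vertical channel
  p0 <- gait_waveform_params(2, 1e-9, 0.9)
  m0 <- make_step_waveform(p0, 100)
  expect_true(all(abs(m0[, "x"]) < 1e-12))

  expect_error(gait_waveform_params(2, 1.9, 0.9), "d < 2\\*L")
  expect_error(make_step_waveform(p, fs = 30), "20")
})

test_that("indoor session has the protocol structure and exact trace speeds", {
  s <- simulate_session(seed = 42)
  act <- s$annotation[s$annotation$kind == "activity", ]
  rest <- s$annotation[s$annotation$kind == "rest", ]
  expect_identical(nrow(act), 5L)
  expect_equal(act$end_s - act$start_s, rep(90, 5))
  # 4 internal rests of 15 s between levels (plus lead-in/lead-out)
  internal <- rest[rest$start_s > 0 & rest$end_s < max(s$annotation$end_s), ]
  expect_identical(nrow(internal), 4L)
  expect_equal(internal$end_s - internal$start_s, rep(15, 4))

  # reference trace mean over a level equals the level speed exactly
  for (i in seq_len(nrow(act))) {
    sel <- s$speed$time >= act$start_s[i] & s$speed$time < act$end_s[i] - 1
    expect_equal(mean(s$speed$speed[sel]),
                 s$protocol$speeds[i], tolerance = 1e-6)
  }

  # per-step truth is self-consistent: steps x length / duration = speed
  for (i in seq_len(nrow(act))) {
    st <- s$steps[s$steps$label == act$label[i], ]
    expect_equal(sum(st$step_length) / 90, s$protocol$speeds[i],
                 tolerance = 0.02)
    expect_equal(st$speed, rep(s$protocol$speeds[i], nrow(st)),
                 tolerance = 1e-9)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_session(seed = 7)
  s2 <- simulate_session(seed = 7)
  expect_identical(s1, s2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(s1, d1); write_session(s2, d2)
  f1 <- file.path(d1, "accel.csv"); f2 <- file.path(d2, "accel.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  s3 <- simulate_session(seed = 8)
  expect_false(identical(s1$accel$x, s3$accel$x))
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_session(seed = 99))
  expect_identical(runif(1), a)
})

test_that("outdoor ramp covers the target distance with a symmetric profile", {
  s <- simulate_outdoor_ramp(seed = 3)
  expect_equal(sum(s$steps$step_length), 812, tolerance = 0.01 * 812)
  # symmetric ramp: start and end speeds agree
  expect_equal(s$steps$speed[1], s$steps$speed[nrow(s$steps)],
               tolerance = 0.05)
  # non-decreasing up to the peak
  peak <- which.max(s$steps$speed)
  expect_true(all(diff(s$steps$speed[1:peak]) >= -1e-9))
  expect_identical(
    s$annotation$label[s$annotation$kind == "activity"], "outdoor_ramp")
})

test_that("cohort draws are reproducible and within the stated ranges", {
  coh <- simulate_cohort(15, seed = 5)
  wrs <- vapply(coh, function(s) s$walk_ratio, numeric(1))
  lls <- vapply(coh, function(s) s$leg_length, numeric(1))
  expect_true(all(wrs >= 0.0055 & wrs <= 0.0075))
  expect_true(all(lls >= 0.8 & lls <= 1.05))
  expect_identical(simulate_cohort(15, seed = 5), coh)
  expect_gt(length(unique(wrs)), 10L)
})

test_that("unachievable level speeds are rejected naming the level", {
  sub <- subject_profile("S", 0.6, walk_ratio = 0.0065,
                         run_step_length = 1.4)
  expect_error(
    simulate_session(protocol_spec(c(1.0, 3.8), level_duration_s = 30),
                     subject = sub, seed = 1),
    "level 2")
})
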