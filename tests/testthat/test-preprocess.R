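test_that("inactivity detection finds the protocol rest structure", {
  # all-quiet signal: one interval covering everything
  quiet <- accel_signal(rnorm(2000, 0, 0.01), rnorm(2000, 0, 0.01),
                        rnorm(2000, 0, 0.01), fs = 100)
  r <- detect_inactivity(quiet)
  expect_identical(nrow(r), 1L)
  expect_equal(r$start_s, 0, tolerance = 1e-9)
  expect_equal(r$end_s, 20, tolerance = 1e-9)

  # simulated indoor session: 4 internal rests of about 15 s
  s <- simulate_session(seed = 21)
  rests <- detect_inactivity(s$accel)
  total <- n_samples(s$accel) / s$accel$fs
  internal <- rests[rests$start_s > 1 & rests$end_s < total - 1, ]
  expect_identical(nrow(internal), 4L)
  ann_rest <- s$annotation[s$annotation$kind == "rest", ]
  ann_int <- ann_rest[ann_rest$start_s > 0 & ann_rest$end_s < total, ]
  expect_equal(internal$start_s, ann_int$start_s, tolerance = 2)
  expect_equal(internal$end_s, ann_int$end_s, tolerance = 2)

  # continuous walking: no rests
  b <- simulate_bout(1.8, 0.7, duration_s = 30, noise_sd = 0.3, seed = 2)
  expect_identical(nrow(detect_inactivity(b$accel)), 0L)
})

test_that("synchronization recovers known lags to within a second", {
  s <- simulate_session(seed = 31)
  expect_equal(synchronize(s$accel, s$speed), 0)
  shifted <- speed_trace(s$speed$time + 7, s$speed$speed)
  expect_lte(abs(synchronize(s$accel, shifted) - 7), 1)
  shifted_neg <- speed_trace(s$speed$time - 13, s$speed$speed)
  expect_lte(abs(synchronize(s$accel, shifted_neg) + 13), 1)

  # no transitions: cannot synchronize
  flat_sig <- accel_signal(rep(0, 3000), rep(0, 3000), rep(0, 3000),
                           fs = 100)
  flat_trace <- speed_trace(0:29, rep(1, 30))
  expect_error(synchronize(flat_sig, flat_trace), "transitions")
})

test_that("boundary trimming shortens both streams symmetrically", {
  s <- simulate_session(seed = 41)
  labels <- s$annotation$label[s$annotation$kind == "activity"]
  segs <- align_session(s$accel, s$speed, labels = labels)
  seg <- segs[[2]]
  dur0 <- n_samples(seg$accel) / seg$accel$fs
  tr <- trim_boundaries(seg, 5)
  expect_equal(n_samples(tr$accel) / tr$accel$fs, dur0 - 10,
               tolerance = 0.02)
  expect_true(all(tr$speed$time >= tr$accel$t0 - 1e-9))
  expect_true(all(tr$speed$time <
                    tr$accel$t0 + n_samples(tr$accel) / tr$accel$fs))

  # trim(a) then trim(b) equals trim(a + b)
  t1 <- trim_boundaries(trim_boundaries(seg, 3), 2)
  t2 <- trim_boundaries(seg, 5)
  expect_equal(t1$accel$x, t2$accel$x)
  expect_equal(t1$speed$speed, t2$speed$speed)

  short <- aligned_segment(slice_accel(s$accel, 15, 25),
                           speed_trace(15:24, rep(1, 10)), "short")
  expect_error(trim_boundaries(short, 5), "short")
})

test_that("a 90 s protocol level trims to 80 s", {
  sig <- accel_signal(rnorm(9000), rnorm(9000), rnorm(9000), fs = 100)
  seg <- aligned_segment(sig, speed_trace(0:89, rep(1, 90)), "level")
  tr <- trim_boundaries(seg, 5)
  expect_equal(n_samples(tr$accel) / 100, 80)
  expect_identical(nrow(tr$speed), 80L)
})

test_that("zero-phase Butterworth matches the analytic squared magnitude", {
  fs <- 100
  # DC gain exactly 1
  const <- rep(2.5, 4000)
  expect_equal(butterworth_lowpass(const, fs), const, tolerance = 1e-6)

  # forward-backward order-4 magnitude: (1 + (f/fc)^8)^-1
  gain2 <- function(f, fc) 1 / (1 + (f / fc)^8)
  t <- (0:9999) / fs
  s1 <- sin(2 * pi * 1 * t)
  y1 <- butterworth_lowpass(s1, fs)
  mid <- 4000:6000
  expect_lt(max(abs(y1[mid])), 0.01)          # 1 Hz: gain 1e-8, amp < 1%
  expect_lt(max(abs(y1[mid])), gain2(1, 0.1) + 0.01)

  s2 <- sin(2 * pi * 0.01 * t)
  y2 <- butterworth_lowpass(s2, fs)
  expect_equal(max(abs(y2[mid])), max(abs(s2[mid])) * gain2(0.01, 0.1),
               tolerance = 0.01)

  expect_error(butterworth_lowpass(s1, fs, cutoff_hz = 60), "Nyquist")
})

test_that("low-frequency detrend removes drift but keeps gait-band content", {
  fs <- 100
  t <- (0:7999) / fs
  x <- 0.5 * t + sin(2 * pi * 2 * t)   # drift + 2 Hz gait component
  xd <- detrend_lowfreq(x, fs)
  mid <- 2000:6000
  expect_lt(max(abs(xd[mid] - sin(2 * pi * 2 * t)[mid])), 0.05)
})
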