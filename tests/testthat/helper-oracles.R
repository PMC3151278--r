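# Independent brute-force oracles: plain loops, no shared code with the
# package implementations they check.

naive_ccc <- function(a, b) {
  n <- length(a)
  ma <- 0; mb <- 0
  for (i in seq_len(n)) { ma <- ma + a[i]; mb <- mb + b[i] }
  ma <- ma / n; mb <- mb / n
  va <- 0; vb <- 0; cab <- 0
  for (i in seq_len(n)) {
    va <- va + (a[i] - ma)^2
    vb <- vb + (b[i] - mb)^2
    cab <- cab + (a[i] - ma) * (b[i] - mb)
  }
  2 * (cab / n) / (va / n + vb / n + (ma - mb)^2)
}

naive_cp <- function(a, b, delta) {
  hits <- 0
  for (i in seq_along(a)) if (abs(a[i] - b[i]) <= delta + 1e-9) hits <- hits + 1
  hits / length(a)
}

naive_loa <- function(a, b) {
  n <- length(a)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- a[i] - b[i]
  m <- 0
  for (i in seq_len(n)) m <- m + d[i]
  m <- m / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - m)^2
  s <- sqrt(ss / (n - 1))
  c(bias = m, lower = m - 1.96 * s, upper = m + 1.96 * s)
}

naive_channel_features <- function(v, fs) {
  n <- length(v)
  mn <- v[1]; mx <- v[1]; imin <- 1L; imax <- 1L
  s <- 0; sa <- 0; ss <- 0
  for (i in seq_len(n)) {
    if (v[i] > mx) { mx <- v[i]; imax <- i }
    if (v[i] < mn) { mn <- v[i]; imin <- i }
    s <- s + v[i]; sa <- sa + abs(v[i]); ss <- ss + v[i]^2
  }
  trough <- v[1]
  for (i in seq_len(imax)) if (v[i] < trough) trough <- v[i]
  c(min = mn, max = mx, mean = s / n, sum = s, sum_abs = sa,
    range = mx - mn, rms = sqrt(ss / n), max_minus_mean = mx - s / n,
    step_amplitude = v[imax] - trough,
    minmax_amplitude_duration = (imax - imin) / fs)
}

naive_features <- function(x, y, z, fs) {
  e <- numeric(length(x))
  for (i in seq_along(x)) e[i] <- sqrt(x[i]^2 + y[i]^2 + z[i]^2)
  out <- c(naive_channel_features(x, fs), naive_channel_features(y, fs),
           naive_channel_features(z, fs), naive_channel_features(e, fs),
           length(x) / fs)
  names(out) <- feature_names()
  out
}

# Small helper: a walking bout whose step length follows the walk-ratio
# prior at the given frequency.
wr_bout <- function(f, duration_s = 60, noise_sd = 0, seed = NULL,
                    wr = 0.0065) {
  simulate_bout(f, wr * 60 * f, L = 0.9, duration_s = duration_s,
                noise_sd = noise_sd, seed = seed)
}
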