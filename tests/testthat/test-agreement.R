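test_that("CCC evaluates the worked examples exactly", {
  a <- c(1, 2, 3)
  expect_equal(ccc(a, a), 1.0)
  expect_equal(ccc(a, c(3, 2, 1)), -1.0)
  expect_equal(ccc(a, c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  # identical constants agree perfectly; unequal constants do not
  expect_equal(ccc(c(2, 2), c(2, 2)), 1)
  expect_warning(v <- ccc(c(2, 2), c(3, 3)), "constant")
  expect_equal(v, 0)
})

test_that("CCC has the algebraic properties of Lin's estimator", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    a <- rnorm(n); b <- 0.5 * a + rnorm(n, 0.2, 0.5)
    # |CCC| <= |r| with equality iff no location/scale shift
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
    # invariant under a common permutation of the pairs
    p <- sample(n)
    expect_equal(ccc(a[p], b[p]), ccc(a, b), tolerance = 1e-12)
  }
  a <- rnorm(30)
  expect_equal(ccc(a, a), cor(a, a), tolerance = 1e-12)
})

test_that("coverage probability counts pairs within delta", {
  ref <- c(1.0, 1.2, 1.5); est <- c(1.05, 1.5, 1.55)
  expect_equal(coverage_probability(ref, est, 0.1), 2 / 3)
  expect_equal(coverage_probability(ref, ref, 0.01), 1)
  expect_equal(coverage_probability(ref, est, 1e6), 1)
  # boundary: |1.2 - 1.5| = 0.3 counts at delta = 0.3
  expect_equal(coverage_probability(ref, est, 0.3), 1)
  expect_error(coverage_probability(ref, est, 0), "positive")
})

test_that("limits of agreement match the Bland-Altman formulas", {
  a <- c(1, 2, 3)
  expect_equal(limits_of_agreement(a, a), c(bias = 0, lower = 0, upper = 0))
  expect_equal(limits_of_agreement(a + 0.2, a),
               c(bias = 0.2, lower = 0.2, upper = 0.2))
  b <- a - c(-0.1, 0.0, 0.1)
  loa <- limits_of_agreement(a, b)
  expect_equal(loa[["bias"]], 0)
  expect_equal(loa[["lower"]], -1.96 * 0.1, tolerance = 1e-12)
  expect_equal(loa[["upper"]], 1.96 * 0.1, tolerance = 1e-12)
})

test_that("agreement statistics match brute-force oracles on random data", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    a <- rnorm(n, 1.5, 0.6)
    b <- a + rnorm(n, 0, 0.2)
    expect_equal(ccc(a, b), naive_ccc(a, b), tolerance = 1e-12)
    d <- runif(1, 0.05, 0.4)
    expect_equal(coverage_probability(a, b, d), naive_cp(a, b, d),
                 tolerance = 1e-12)
    expect_equal(limits_of_agreement(a, b), naive_loa(a, b),
                 tolerance = 1e-12)
  }
})

test_that("CP is monotone non-decreasing in delta", {
  set.seed(3)
  a <- rnorm(50, 1.5, 0.5); b <- a + rnorm(50, 0, 0.25)
  deltas <- seq(0.01, 1, by = 0.01)
  cps <- vapply(deltas, function(d) coverage_probability(a, b, d),
                numeric(1))
  expect_true(all(diff(cps) >= 0))
})

test_that("cluster bootstrap is seeded, clipped and degenerate-safe", {
  # identical single-value clusters: CP CI collapses to (1, 1)
  p <- paired_speeds(rep(1, 4), rep(1, 4), cluster = 1:4)
  ci <- bootstrap_ci(p, function(a, b) coverage_probability(a, b, 0.1),
                     n_boot = 200, seed = 1, clip01 = TRUE)
  expect_equal(unname(ci[1:2]), c(1, 1))

  set.seed(8)
  p2 <- paired_speeds(rnorm(40, 1.5, 0.4), rnorm(40, 1.5, 0.4) ,
                      cluster = rep(1:8, each = 5))
  ci_a <- bootstrap_ci(p2, function(a, b) ccc(a, b), n_boot = 300, seed = 7)
  ci_b <- bootstrap_ci(p2, function(a, b) ccc(a, b), n_boot = 300, seed = 7)
  expect_identical(ci_a, ci_b)
  expect_true(ci_a[["lower"]] <= ci_a[["upper"]])
  expect_error(bootstrap_ci(paired_speeds(1:3, 1:3, cluster = rep(1, 3)),
                            ccc), "2 clusters")
})

test_that("algorithm ranking orders by CP1 and respects exclusions", {
  ref <- rep(c(0.65, 1.11, 1.47, 2.70), 3)
  lab <- rep(c("slow", "normal", "fast", "running"), 3)
  cl <- rep(1:3, each = 4)
  pairs <- rbind(
    data.frame(algorithm = "perfect", reference = ref, estimate = ref,
               cluster = cl, label = lab),
    data.frame(algorithm = "constant", reference = ref, estimate = 1.2,
               cluster = cl, label = lab))
  rep_ <- rank_algorithms(pairs, n_boot = 0)
  expect_identical(rep_$algorithm[1], "perfect")
  expect_equal(rep_$cp1[1], 1)
  expect_equal(rep_$cp2[1], 1)
  expect_equal(rep_$cp3[1], 1)
  expect_equal(rep_$ccc[1], 1)

  # excluding the running level drops exactly those pairs
  rep_ex <- rank_algorithms(pairs, n_boot = 0, exclude_running = TRUE)
  expect_equal(rep_$n - rep_ex$n, rep(sum(lab == "running"), 2))

  # report carries the CP/CCC/LOA column structure with CI bounds
  rep_ci <- rank_algorithms(pairs, n_boot = 50, seed = 2)
  expect_true(all(c("cp1", "cp1_lo", "cp1_hi", "cp2", "cp2_lo", "cp2_hi",
                    "cp3", "cp3_lo", "cp3_hi", "ccc", "ccc_lo", "ccc_hi",
                    "bias", "loa_lower", "loa_upper") %in% names(rep_ci)))
  expect_true(all(rep_ci$cp1_lo >= 0 & rep_ci$cp1_hi <= 1))
})

test_that("CP band plot is written and classifies offsets correctly", {
  ref0 <- seq(0.6, 2.6, length.out = 10)
  pairs <- data.frame(reference = rep(ref0, 2),
                      estimate = c(ref0, ref0 + 0.25),
                      algorithm = rep(c("exact", "biased"), each = 10),
                      cluster = rep(1:2, each = 10), label = "x")
  # offset 0.25 lies outside the 0.1/0.2 bands but inside 0.3
  off <- pairs[pairs$algorithm == "biased", ]
  expect_equal(coverage_probability(off$reference, off$estimate, 0.2), 0)
  expect_equal(coverage_probability(off$reference, off$estimate, 0.3), 1)
  f <- withr::local_tempfile(fileext = ".pdf")
  p <- plot_cp_bands(pairs, file = f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
  expect_s3_class(p, "ggplot")
})
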