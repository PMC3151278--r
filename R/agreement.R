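#' Paired reference/estimated speeds
#'
#' @param reference Reference (gold standard) speeds, m/s.
#' @param estimate Estimated speeds, m/s.
#' @param cluster Cluster (subject) ids, used for bootstrap resampling.
#' @param label Optional interval labels (e.g. the speed level).
#' @return A data.frame of class `paired_speeds`.
#' @export
paired_speeds <- function(reference, estimate, cluster = NULL,
                          label = NULL) {
  n <- length(reference)
  if (length(estimate) != n) stop("reference and estimate lengths differ")
  if (n < 2L) stop("need at least 2 pairs")
  df <- data.frame(reference = reference, estimate = estimate,
                   cluster = if (is.null(cluster)) seq_len(n)
                             else as.character(cluster),
                   label = if (is.null(label)) NA_character_
                           else as.character(label))
  structure(df, class = c("paired_speeds", "data.frame"))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2*cov(a, b) / (var(a) + var(b) + (mean(a) - mean(b))^2)` with
#' population (1/n) moments. Unlike Pearson's r, it penalizes any deviation
#' from the line of equality (location and scale shifts as well as
#' scatter).
#'
#' @param a,b Numeric vectors of equal length (n >= 2).
#' @param sample_moments Use n-1 moments instead of the population (1/n)
#'   estimator (the two agree exactly for the CCC ratio up to the squared
#'   mean-shift weighting; default `FALSE`, Lin's original estimator).
#' @return The CCC, in \[-1, 1\]. Two identical constant series are in
#'   perfect agreement (CCC 1); two unequal constant series have CCC 0
#'   (with a warning, as there is no variation to correlate).
#' @export
ccc <- function(a, b, sample_moments = FALSE) {
  n <- length(a)
  if (length(b) != n || n < 2L) stop("need two vectors of equal length >= 2")
  ma <- mean(a); mb <- mean(b)
  w <- if (sample_moments) n / (n - 1) else 1
  va <- w * mean((a - ma)^2)
  vb <- w * mean((b - mb)^2)
  cab <- w * mean((a - ma) * (b - mb))
  denom <- va + vb + (ma - mb)^2
  if (denom == 0) return(1)  # identical constants: perfect agreement
  if (va == 0 && vb == 0)
    warning("both series are constant; CCC is 0 by convention")
  2 * cab / denom
}

#' Coverage probability
#'
#' Fraction of pairs whose absolute difference is within `delta` (an
#' absolute-tolerance comparison at 1e-9 guards against representation
#' error at the boundary).
#'
#' @param a,b Numeric vectors of equal length.
#' @param delta Maximum allowed difference (> 0), same unit as the data.
#' @return The coverage probability, in \[0, 1\].
#' @export
coverage_probability <- function(a, b, delta) {
  if (length(b) != length(a)) stop("lengths differ")
  if (delta <= 0) stop("delta must be positive")
  mean(abs(a - b) <= delta + 1e-9)
}

#' Bland-Altman limits of agreement
#'
#' @param a,b Numeric vectors of equal length (n >= 3). Differences are
#'   `a - b`.
#' @return Named vector `c(bias, lower, upper)` with
#'   `bias +/- 1.96 * sd(d)` (sample sd).
#' @export
limits_of_agreement <- function(a, b) {
  if (length(b) != length(a) || length(a) < 3L)
    stop("need two vectors of equal length >= 3")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  c(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s)
}

#' Cluster percentile bootstrap confidence interval
#'
#' Resamples clusters (subjects) with replacement, recomputes the
#' statistic on each resample, and returns the percentile interval. If the
#' statistic fails (error or non-finite value) on a resample, that
#' resample is redrawn and the redraw counted.
#'
#' @param pairs A [paired_speeds()] data.frame.
#' @param statistic Function `(reference, estimate) -> scalar`.
#' @param n_boot Number of resamples (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param clip01 Clip the interval to \[0, 1\] (for probabilities such as
#'   CP).
#' @return Named vector `c(lower, upper)`; the number of redraws is
#'   attached as attribute `"n_redrawn"`.
#' @export
bootstrap_ci <- function(pairs, statistic, n_boot = 2000, seed = 1,
                         conf = 0.95, clip01 = FALSE) {
  cl <- unique(pairs$cluster)
  if (length(cl) < 2L) stop("need at least 2 clusters for cluster resampling")
  idx_by_cl <- split(seq_len(nrow(pairs)), pairs$cluster)
  with_seed(seed, {
    stats <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      val <- NA_real_
      for (attempt in 1:100) {
        ids <- sample(length(cl), length(cl), replace = TRUE)
        idx <- unlist(idx_by_cl[ids], use.names = FALSE)
        val <- tryCatch(
          suppressWarnings(statistic(pairs$reference[idx],
                                     pairs$estimate[idx])),
          error = function(e) NA_real_)
        if (is.finite(val)) break
        redrawn <- redrawn + 1L
      }
      stats[b] <- val
    }
    alpha <- (1 - conf) / 2
    qs <- quantile(stats, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    if (clip01) qs <- pmin(1, pmax(0, qs))
    structure(c(lower = qs[1L], upper = qs[2L]), n_redrawn = redrawn)
  })
}

#' Rank speed-prediction algorithms by agreement
#'
#' Computes, per algorithm, the coverage probability at each `delta` (with
#' cluster-bootstrap CIs), the CCC (with CI), and the Bland-Altman limits
#' of agreement, and ranks the algorithms by CP at the smallest delta
#' (ties broken by CCC).
#'
#' @param pairs A data.frame with columns `algorithm`, `reference`,
#'   `estimate`, `cluster`, `label` (one row per evaluated interval).
#' @param deltas CP boundaries in m/s (default 0.1, 0.2, 0.3 m/s, i.e.
#'   CP1-CP3).
#' @param exclude_running Drop pairs whose `label` equals `running_label`
#'   before computing the report.
#' @param running_label Label of the running level.
#' @param n_boot,seed,conf Bootstrap settings; set `n_boot = 0` to skip
#'   CIs.
#' @return A data.frame of class `agreement_report`, one row per
#'   algorithm, ordered by decreasing CP at `deltas[1]`.
#' @export
rank_algorithms <- function(pairs, deltas = c(0.1, 0.2, 0.3),
                            exclude_running = FALSE,
                            running_label = "running", n_boot = 2000,
                            seed = 1, conf = 0.95) {
  if (exclude_running)
    pairs <- pairs[is.na(pairs$label) | pairs$label != running_label, ,
                   drop = FALSE]
  if (nrow(pairs) == 0L) stop("no pairs to rank")
  algos <- unique(pairs$algorithm)
  rows <- lapply(algos, function(alg) {
    p <- pairs[pairs$algorithm == alg, , drop = FALSE]
    out <- list(algorithm = alg, n = nrow(p))
    for (k in seq_along(deltas)) {
      dk <- deltas[k]
      cp <- coverage_probability(p$reference, p$estimate, dk)
      out[[paste0("cp", k)]] <- cp
      if (n_boot > 0) {
        ci <- bootstrap_ci(
          paired_speeds(p$reference, p$estimate, p$cluster, p$label),
          function(a, b) coverage_probability(a, b, dk),
          n_boot = n_boot, seed = seed, conf = conf, clip01 = TRUE)
        out[[paste0("cp", k, "_lo")]] <- ci[["lower"]]
        out[[paste0("cp", k, "_hi")]] <- ci[["upper"]]
      }
    }
    out$ccc <- suppressWarnings(ccc(p$reference, p$estimate))
    if (n_boot > 0) {
      ci <- bootstrap_ci(paired_speeds(p$reference, p$estimate, p$cluster,
                                       p$label),
                         function(a, b) ccc(a, b),
                         n_boot = n_boot, seed = seed, conf = conf)
      out$ccc_lo <- ci[["lower"]]; out$ccc_hi <- ci[["upper"]]
    }
    loa <- limits_of_agreement(p$reference, p$estimate)
    out$bias <- loa[["bias"]]
    out$loa_lower <- loa[["lower"]]
    out$loa_upper <- loa[["upper"]]
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  rep_ <- rep_[order(-rep_$cp1, -rep_$ccc), , drop = FALSE]
  rownames(rep_) <- NULL
  structure(rep_, class = c("agreement_report", "data.frame"),
            deltas = deltas, exclude_running = exclude_running)
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  fmt <- function(v, lo, hi) {
    if (is.null(lo)) sprintf("%.*f", digits, v)
    else sprintf("%.*f (%.*f-%.*f)", digits, v, digits, lo, digits, hi)
  }
  has_ci <- "cp1_lo" %in% names(x)
  cat(sprintf("Algorithm ranking (%d algorithms, CP deltas %s m/s%s)\n",
              nrow(x), paste(attr(x, "deltas"), collapse = "/"),
              if (isTRUE(attr(x, "exclude_running"))) ", running excluded"
              else ""))
  df <- data.frame(Algorithm = x$algorithm,
                   CP1 = fmt(x$cp1, if (has_ci) x$cp1_lo, if (has_ci) x$cp1_hi),
                   CP2 = fmt(x$cp2, if (has_ci) x$cp2_lo, if (has_ci) x$cp2_hi),
                   CP3 = fmt(x$cp3, if (has_ci) x$cp3_lo, if (has_ci) x$cp3_hi),
                   CCC = fmt(x$ccc, if (has_ci) x$ccc_lo, if (has_ci) x$ccc_hi))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Write an agreement report as CSV
#' @param report An `agreement_report`.
#' @param path Output CSV path.
#' @export
write_agreement_report <- function(report, path) {
  write.csv(as.data.frame(unclass(report)), path, row.names = FALSE)
  invisible(path)
}
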