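#' Feature subsets of the regression speed models
#'
#' Fixed per-model feature subsets: the energy-model uses the sum of
#' absolute values of each axis plus the mean energy (a biomechanically
#' motivated choice); the other subsets were originally obtained by
#' automated backward feature selection.
#'
#' @param model_name One of `"MA"`, `"C"`, `"Energy"`, `"RBWE"`.
#' @return Character vector of feature names (subset of
#'   [feature_names()]).
#' @export
model_features <- function(model_name) {
  switch(model_name,
    MA = "max_minus_mean_x",
    C = c("max_y", "mean_z", "mean_e", "sum_x", "sum_z", "sum_abs_y",
          "sum_abs_z", "step_duration", "rms_x", "rms_z", "rms_e",
          "max_minus_mean_x", "step_amplitude_x"),
    Energy = c("sum_abs_x", "sum_abs_y", "sum_abs_z", "mean_e"),
    RBWE = c("sum_abs_z", "step_duration", "rms_z", "max_minus_mean_x",
             "step_amplitude_x"),
    stop("unknown model_name: ", model_name)
  )
}

#' Shipped SVR hyperparameters
#'
#' Radial-kernel hyperparameters per model, as found by 10-fold
#' cross-validated grid search in the original development:
#' MA (C=100, gamma=0.03, epsilon=0.2), C (C=5, gamma=0.0024,
#' epsilon=0.01), Energy (C=64, gamma=0.004, epsilon=0.00049).
#'
#' @param model_name One of `"MA"`, `"C"`, `"Energy"`, `"RBWE"` (RBWE has
#'   no shipped SVR variant; generic defaults are returned).
#' @return Named list with `C`, `gamma`, `epsilon`.
#' @export
svr_defaults <- function(model_name) {
  switch(model_name,
    MA = list(C = 100, gamma = 0.03, epsilon = 0.2),
    C = list(C = 5, gamma = 0.0024, epsilon = 0.01),
    Energy = list(C = 64, gamma = 0.004, epsilon = 0.00049),
    RBWE = list(C = 1, gamma = 0.2, epsilon = 0.1),
    stop("unknown model_name: ", model_name)
  )
}

#' Fit a regression speed model
#'
#' Restricts the feature matrix to the model's subset, standardizes the
#' features (z-score; parameters stored with the model), and fits either
#' ordinary least squares (`kind = "LR"`) or radial-kernel support vector
#' regression (`kind = "SVR"`, via [e1071::svm()]). The training target is
#' the per-step reference speed.
#'
#' @param features Data.frame of per-step features ([feature_matrix()]).
#' @param target Per-step reference speeds (m/s), same length as
#'   `nrow(features)`.
#' @param model_name One of `"MA"`, `"C"`, `"Energy"`, `"RBWE"`.
#' @param kind `"LR"` or `"SVR"`.
#' @param hyper SVR hyperparameters (list with `C`, `gamma`, `epsilon`);
#'   defaults to [svr_defaults()].
#' @param min_steps Minimum training size (default 50).
#' @return An object of class `gait_speed_model`.
#' @export
fit_regression <- function(features, target,
                           model_name = c("Energy", "C", "MA", "RBWE"),
                           kind = c("LR", "SVR"), hyper = NULL,
                           min_steps = 50L) {
  model_name <- match.arg(model_name)
  kind <- match.arg(kind)
  feats <- model_features(model_name)
  miss <- setdiff(feats, names(features))
  if (length(miss))
    stop("feature matrix is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(features) != length(target))
    stop("features and target sizes differ")
  if (nrow(features) < min_steps)
    stop(sprintf("need at least %d training steps (got %d)", min_steps,
                 nrow(features)))
  X <- as.matrix(features[feats])
  center <- colMeans(X)
  scale_ <- apply(X, 2L, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Z <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  if (kind == "LR") {
    qrz <- qr(cbind(1, Z))
    if (qrz$rank < ncol(Z) + 1L)
      warning(sprintf("rank-deficient design for LR (%s-model): %d of %d columns independent",
                      model_name, qrz$rank, ncol(Z) + 1L))
    cf <- qr.coef(qrz, target)
    cf[is.na(cf)] <- 0
    fit <- list(coefficients = cf)
  } else {
    hyper <- hyper %||% svr_defaults(model_name)
    fit <- e1071::svm(Z, target, type = "eps-regression", kernel = "radial",
                      cost = hyper$C, gamma = hyper$gamma,
                      epsilon = hyper$epsilon, scale = FALSE)
  }
  structure(list(kind = kind, model_name = model_name, features = feats,
                 center = center, scale = scale_, fit = fit,
                 hyper = if (kind == "SVR") hyper else NULL,
                 n_train = nrow(features)),
            class = "gait_speed_model")
}

#' @export
print.gait_speed_model <- function(x, ...) {
  cat(sprintf("<gait_speed_model> %s (%s-model), %d feature(s), n_train = %d\n",
              x$kind, x$model_name, length(x$features), x$n_train))
  invisible(x)
}

#' Predict per-step and interval speed with a fitted model
#'
#' Features are standardized with the parameters stored at training time;
#' negative raw predictions are clipped to 0. The interval speed is the
#' step-duration-weighted mean of the per-step speeds.
#'
#' @param model A `gait_speed_model` from [fit_regression()].
#' @param features Per-step feature data.frame.
#' @param durations Optional per-step durations (s) used as aggregation
#'   weights; defaults to the `step_duration` column when present, else
#'   equal weights.
#' @return A list with `per_step` (speeds, m/s), `speed` (interval
#'   estimate), `n_clipped` (number of negative predictions clipped).
#' @export
predict_regression <- function(model, features, durations = NULL) {
  miss <- setdiff(model$features, names(features))
  if (length(miss))
    stop("feature matrix is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(features) == 0L)
    return(list(per_step = numeric(0), speed = NA_real_, n_clipped = 0L))
  X <- as.matrix(features[model$features])
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  raw <- if (model$kind == "LR") {
    as.numeric(cbind(1, Z) %*% model$fit$coefficients)
  } else if (inherits(model$fit, "svm")) {
    as.numeric(predict(model$fit, Z))
  } else {
    svr_predict_manual(model$fit, Z)
  }
  n_clipped <- sum(raw < 0)
  per_step <- pmax(raw, 0)
  if (is.null(durations))
    durations <- if ("step_duration" %in% names(features))
      features$step_duration else rep(1, length(per_step))
  list(per_step = per_step,
       speed = sum(per_step * durations) / sum(durations),
       n_clipped = n_clipped)
}

# Radial-kernel SVR prediction from serialized support-vector state.
svr_predict_manual <- function(state, Z) {
  SV <- state$SV
  k <- vapply(seq_len(nrow(Z)), function(i) {
    d2 <- rowSums(sweep(SV, 2L, Z[i, ])^2)
    sum(state$coefs * exp(-state$gamma * d2))
  }, numeric(1))
  k - state$rho
}

#' Grid search for SVR hyperparameters
#'
#' 10-fold cross-validated grid search over `C`, `gamma` and `epsilon`
#' with seeded fold assignment. The grid point with minimal mean CV MSE is
#' selected; ties break toward smaller `C`, then smaller `gamma`, then
#' smaller `epsilon`.
#'
#' @inheritParams fit_regression
#' @param C_grid,gamma_grid,eps_grid Non-empty numeric grids.
#' @param folds Number of CV folds (default 10); must not exceed the number
#'   of samples.
#' @param seed Integer seed for the fold assignment.
#' @return A list with `model` (fitted on all data at the selected point)
#'   and `cv` (data.frame: `C`, `gamma`, `epsilon`, `mse`).
#' @export
grid_search_svr <- function(features, target, model_name, C_grid,
                            gamma_grid, eps_grid, folds = 10, seed = 1,
                            min_steps = 50L) {
  if (!length(C_grid) || !length(gamma_grid) || !length(eps_grid))
    stop("hyperparameter grids must be non-empty")
  n <- nrow(features)
  if (n < folds) stop("fewer samples than folds")
  feats <- model_features(model_name)
  X <- as.matrix(features[feats])
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  grid <- expand.grid(epsilon = sort(eps_grid), gamma = sort(gamma_grid),
                      C = sort(C_grid))
  grid <- grid[order(grid$C, grid$gamma, grid$epsilon), , drop = FALSE]
  mse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      Xtr <- X[tr, , drop = FALSE]
      ctr <- colMeans(Xtr)
      str_ <- apply(Xtr, 2L, sd)
      str_[str_ == 0 | !is.finite(str_)] <- 1
      Ztr <- sweep(sweep(Xtr, 2L, ctr), 2L, str_, "/")
      Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, ctr), 2L, str_, "/")
      tryCatch({
        m <- e1071::svm(Ztr, target[tr], type = "eps-regression",
                        kernel = "radial", cost = grid$C[g],
                        gamma = grid$gamma[g], epsilon = grid$epsilon[g],
                        scale = FALSE)
        mean((as.numeric(predict(m, Zte)) - target[!tr])^2)
      }, error = function(e) Inf)  # e.g. epsilon swallows every sample
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which(mse <= min(mse) + 1e-12)[1L]
  hyper <- list(C = grid$C[best], gamma = grid$gamma[best],
                epsilon = grid$epsilon[best])
  model <- fit_regression(features, target, model_name, kind = "SVR",
                          hyper = hyper, min_steps = min_steps)
  list(model = model,
       cv = data.frame(C = grid$C, gamma = grid$gamma,
                       epsilon = grid$epsilon, mse = mse))
}

#' Greedy backward feature selection
#'
#' Utility for re-deriving model feature subsets: starting from a feature
#' set, repeatedly remove the feature whose deletion minimizes the
#' cross-validated MSE of an OLS fit, stopping when no removal improves.
#' Shipped models use the fixed subsets of [model_features()].
#'
#' @param features Per-step feature data.frame.
#' @param target Per-step reference speeds.
#' @param start Starting feature set (default all 41).
#' @param folds CV folds.
#' @param seed Integer seed for fold assignment.
#' @return Character vector of selected feature names.
#' @export
backward_select_features <- function(features, target,
                                     start = feature_names(), folds = 10,
                                     seed = 1) {
  n <- nrow(features)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv_mse <- function(cols) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      Xtr <- as.matrix(features[tr, cols, drop = FALSE])
      Xte <- as.matrix(features[!tr, cols, drop = FALSE])
      cf <- qr.coef(qr(cbind(1, Xtr)), target[tr])
      cf[is.na(cf)] <- 0
      mean((as.numeric(cbind(1, Xte) %*% cf) - target[!tr])^2)
    }, numeric(1))
    mean(errs)
  }
  current <- start
  best <- cv_mse(current)
  repeat {
    if (length(current) <= 1L) break
    trial <- vapply(seq_along(current),
                    function(i) cv_mse(current[-i]), numeric(1))
    i <- which.min(trial)
    if (trial[i] >= best) break
    best <- trial[i]
    current <- current[-i]
  }
  current
}

#' Per-step reference speeds from a 1 Hz trace
#'
#' Target speeds for regression training: the mean reference speed over
#' each step's time span, with linear interpolation between the 1 Hz
#' samples.
#'
#' @param steps A `step_intervals` object (or data.frame with `start`,
#'   `end`).
#' @param fs Sampling frequency of the accelerometer signal (Hz).
#' @param trace A [speed_trace()] on the same clock.
#' @param t0 Session time of the signal's first sample (s).
#' @return Numeric vector of per-step speeds (m/s).
#' @export
step_target_speeds <- function(steps, fs, trace, t0 = 0) {
  vapply(seq_len(nrow(steps)), function(i) {
    ts <- t0 + (steps$start[i] - 1L) / fs
    te <- t0 + (steps$end[i] - 1L) / fs
    grid <- seq(ts, te, length.out = 9L)
    mean(approx(trace$time, trace$speed, xout = grid, rule = 2)$y)
  }, numeric(1))
}

#' Serialize / load a fitted model as JSON
#'
#' LR models store their coefficients; SVR models store the support
#' vectors, dual coefficients, `rho` and `gamma`, from which predictions
#' are reconstructed exactly.
#'
#' @param model A `gait_speed_model`.
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  out <- list(kind = model$kind, model_name = model$model_name,
              features = model$features, center = as.numeric(model$center),
              scale = as.numeric(model$scale), hyper = model$hyper,
              n_train = model$n_train)
  if (model$kind == "LR") {
    out$coefficients <- as.numeric(model$fit$coefficients)
  } else {
    f <- model$fit
    out$SV <- if (inherits(f, "svm")) unname(as.matrix(f$SV)) else f$SV
    out$coefs <- if (inherits(f, "svm")) as.numeric(f$coefs) else f$coefs
    out$rho <- if (inherits(f, "svm")) as.numeric(f$rho) else f$rho
    out$gamma <- if (inherits(f, "svm")) f$gamma else f$gamma
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- if (lst$kind == "LR") {
    list(coefficients = lst$coefficients)
  } else {
    list(SV = as.matrix(lst$SV), coefs = lst$coefs, rho = lst$rho,
         gamma = lst$gamma)
  }
  structure(list(kind = lst$kind, model_name = lst$model_name,
                 features = lst$features,
                 center = setNames(lst$center, lst$features),
                 scale = setNames(lst$scale, lst$features),
                 fit = fit, hyper = lst$hyper, n_train = lst$n_train),
            class = "gait_speed_model")
}
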