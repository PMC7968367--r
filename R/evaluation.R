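#' Root-mean-square error
#'
#' `sqrt(mean((pred - ref)^2))` over paired values, the standard accuracy
#' criterion for both sensor agreement and forecast skill, in mg/dl.
#'
#' @param pred numeric predictions.
#' @param ref numeric references, same length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("rmse: length mismatch")
  if (length(pred) == 0L) stop("rmse: empty input")
  if (any(!is.finite(pred)) || any(!is.finite(ref)))
    stop("rmse: non-finite values")
  sqrt(mean((pred - ref)^2))
}

#' Sensor accuracy versus fingerstick reference
#'
#' Pairs every fingerstick reading with the glucose channel value at the
#' same grid slot (floor-rule slot matching) and returns their RMSE.
#' Fingersticks falling on slots where the glucose channel is undefined are
#' dropped; the number dropped is attached as attribute `n_dropped`.
#'
#' @param series a [patient_series()] with fingerstick readings.
#' @param glucose dense per-slot glucose, e.g. raw `series$cgm` or a
#'   [smooth_cgm()] mean.
#' @return RMSE in mg/dl, with attributes `n_pairs`, `n_dropped`.
#' @export
sensor_rmse <- function(series, glucose) {
  stopifnot(inherits(series, "patient_series"),
            length(glucose) == series$n_index)
  fs <- series$fingerstick
  if (nrow(fs) == 0L) stop("sensor_rmse: no fingerstick readings")
  g <- glucose[fs$index]
  keep <- !is.na(g)
  if (!any(keep)) stop("sensor_rmse: no usable fingerstick/glucose pairs")
  out <- rmse(g[keep], fs$value[keep])
  attr(out, "n_pairs") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Persistence baseline forecast
#'
#' The naive skill reference: predict that glucose `PH` slots ahead equals
#' the last glucose value of the history window. The predictive sd is the
#' residual sd of this rule over the supplied windows.
#'
#' @param windows a [build_windows()] result.
#' @return a `forecast_result` data frame (`target_index`, `pred_mean`,
#'   `pred_sd`).
#' @export
persistence_baseline <- function(windows) {
  stopifnot(inherits(windows, "feature_windows"))
  if (n_windows(windows) == 0L) stop("persistence_baseline: no windows")
  resid_sd <- stats::sd(windows$targets - windows$last_glucose)
  if (!is.finite(resid_sd)) resid_sd <- 0
  out <- data.frame(target_index = windows$index_map,
                    pred_mean = windows$last_glucose,
                    pred_sd = resid_sd)
  class(out) <- c("forecast_result", "data.frame")
  out
}

#' Evaluate a trained forecaster on an independent test series
#'
#' Builds test windows with the training scaler (smoothing the test file on
#' its own when the model was trained on the smoothed channel — never
#' jointly with the training file), predicts, and reports RMSEs. The
#' reference channel is `truth_bg` when the series is synthetic and carries
#' ground truth, otherwise the model's glucose channel; `reference` can
#' force `"raw"`, `"smoothed"`, or `"truth"`. Evaluating on the same data
#' the model was trained on is refused (leakage).
#'
#' @param trained a [train_model()] result.
#' @param test_series a [patient_series()] disjoint from the training file.
#' @param PH_minutes prediction horizon in minutes (must be a multiple of 5;
#'   default the trained horizon).
#' @param reference reference channel for the forecast RMSE.
#' @param q,r smoothing parameters applied to the test file when needed.
#' @return an `eval_report` list: `forecast_rmse`, `baseline_rmse`,
#'   `sensor_rmse_raw`, `sensor_rmse_smoothed`, `n_points`, plus metadata.
#' @export
evaluate_forecast <- function(trained, test_series,
                              PH_minutes = NULL,
                              reference = c("auto", "truth", "raw",
                                            "smoothed"),
                              q = 1, r = 25) {
  stopifnot(inherits(trained, "bg_trained"),
            inherits(test_series, "patient_series"))
  reference <- match.arg(reference)
  PH <- if (is.null(PH_minutes)) trained$PH
        else {
          if (PH_minutes %% GRID_MINUTES != 0)
            stop("PH_minutes must be a multiple of 5")
          as.integer(PH_minutes / GRID_MINUTES)
        }
  sm <- smooth_cgm(test_series, q = q, r = r)
  channel <- trained$glucose_channel
  windows <- build_windows(test_series, glucose_channel = channel,
                           L = trained$L, PH = PH, scaler = trained$scaler,
                           smoothed = if (channel == "smoothed") sm)
  if (n_windows(windows) == 0L)
    stop("evaluate_forecast: no admissible windows in the test series")
  if (identical(windows_fingerprint(windows), trained$train_fingerprint))
    stop("evaluate_forecast: test data are the model's training data (leakage)")
  if (reference == "auto")
    reference <- if (!is.null(test_series$truth_bg)) "truth" else channel
  ref_channel <- switch(reference,
                        truth = {
                          if (is.null(test_series$truth_bg))
                            stop("no truth_bg channel in the test series")
                          test_series$truth_bg
                        },
                        raw = test_series$cgm,
                        smoothed = sm$mean)
  ref <- ref_channel[windows$index_map]
  usable <- !is.na(ref)
  if (!any(usable))
    stop("evaluate_forecast: reference undefined at every target index")
  fc <- predict(trained, windows)
  base <- persistence_baseline(windows)
  structure(list(
    patient_id = test_series$patient_id,
    PH_minutes = PH * GRID_MINUTES,
    glucose_channel = channel,
    reference = reference,
    forecast_rmse = rmse(fc$pred_mean[usable], ref[usable]),
    baseline_rmse = rmse(base$pred_mean[usable], ref[usable]),
    sensor_rmse_raw = maybe_sensor_rmse(test_series, test_series$cgm),
    sensor_rmse_smoothed = maybe_sensor_rmse(test_series, sm$mean),
    n_points = sum(usable),
    forecast = fc
  ), class = "eval_report")
}

maybe_sensor_rmse <- function(series, glucose) {
  tryCatch(as.numeric(sensor_rmse(series, glucose)),
           error = function(e) NA_real_)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> patient %s, PH = %d min, %s channel (ref: %s)\n",
              x$patient_id, x$PH_minutes, x$glucose_channel, x$reference))
  cat(sprintf("  forecast RMSE   %7.2f mg/dl  (n = %d)\n",
              x$forecast_rmse, x$n_points))
  cat(sprintf("  persistence     %7.2f mg/dl\n", x$baseline_rmse))
  if (!is.na(x$sensor_rmse_raw))
    cat(sprintf("  sensor RMSE     %7.2f raw / %.2f smoothed mg/dl\n",
                x$sensor_rmse_raw, x$sensor_rmse_smoothed))
  invisible(x)
}

#' Sensor-correction experiment: smoothing versus raw CGM
#'
#' For each seed, simulates a patient, Kalman-smooths the faulted CGM, and
#' compares raw and smoothed readings against the simulator's ground truth
#' at slots where the raw CGM is observed.
#'
#' @param seeds integer vector of simulation seeds.
#' @param days simulated days per seed (default 30).
#' @param ... further [sim_config()] overrides.
#' @return data frame with per-seed `rmse_raw`, `rmse_smoothed`.
#' @export
sensor_correction_experiment <- function(seeds, days = 30L, ...) {
  rows <- lapply(seeds, function(s) {
    series <- generate_patient(sim_config(seed = s, days = days, ...))
    sm <- smooth_cgm(series)
    obs <- !is.na(series$cgm)
    data.frame(seed = s,
               rmse_raw = rmse(series$cgm[obs], series$truth_bg[obs]),
               rmse_smoothed = rmse(sm$mean[obs], series$truth_bg[obs]))
  })
  do.call(rbind, rows)
}

#' Forecast-skill experiment: stacked LSTM versus persistence, per channel
#'
#' For one seed: simulates independent training and test records, trains the
#' configured model on the raw-CGM and Kalman-smoothed channels separately,
#' and evaluates both against the simulator's ground truth alongside the
#' persistence baseline.
#'
#' @param seed simulation/model seed.
#' @param days_train,days_test simulated days for the two files.
#' @param PH_minutes horizon in minutes (default 30).
#' @param config a [model_config()]; its seed is overridden by `seed`.
#' @param channels which glucose channels to train (default both).
#' @param L history length in slots.
#' @param ... further [sim_config()] overrides.
#' @return data frame with one row per channel: `forecast_rmse`,
#'   `baseline_rmse` (vs truth), sensor RMSEs, window count.
#' @export
skill_experiment <- function(seed, days_train = 10L, days_test = 5L,
                             PH_minutes = 30L,
                             config = model_config(max_epochs = 20L,
                                                   patience = 8L),
                             channels = c("smoothed", "raw"), L = 24L, ...) {
  PH <- as.integer(PH_minutes / GRID_MINUTES)
  train_series <- generate_patient(sim_config(seed = seed, days = days_train,
                                              ...))
  test_series <- generate_patient(sim_config(seed = seed + 50000L,
                                             days = days_test, ...))
  config$seed <- as.integer(seed)
  rows <- lapply(channels, function(ch) {
    sm_train <- if (ch == "smoothed") smooth_cgm(train_series)
    windows <- build_windows(train_series, glucose_channel = ch,
                             L = L, PH = PH, smoothed = sm_train)
    trained <- train_model(build_model(config, L = L), windows)
    rep <- evaluate_forecast(trained, test_series, reference = "truth")
    data.frame(seed = seed, channel = ch,
               forecast_rmse = rep$forecast_rmse,
               baseline_rmse = rep$baseline_rmse,
               sensor_rmse_raw = rep$sensor_rmse_raw,
               sensor_rmse_smoothed = rep$sensor_rmse_smoothed,
               n_points = rep$n_points,
               stopped_epoch = trained$stopped_epoch)
  })
  do.call(rbind, rows)
}
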