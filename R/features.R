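#' Effective carbohydrate channel
#'
#' Converts sparse meal events into a dense per-slot "effective carbohydrate"
#' signal modelling gastric absorption on the 5-minute grid. After a meal of
#' `C_meal` grams at slot `t_meal`, with elapsed slots `e = t - t_meal`:
#'
#' * `e <= lag` (first 15 min): no effect yet, `C_eff = 0`;
#' * increasing phase, `lag < e <= lag + 9` (up to 1 h post-meal):
#'   `C_eff = min(C_meal, (e - lag) * beta_inc * C_meal)` — the absorbed
#'   fraction rises ~11.1% per slot and peaks near 100% of the meal;
#' * decreasing phase, `e > lag + 9`: with `d = e - (lag + 9)` slots past the
#'   peak, `C_eff = C_meal * (1 - d * beta_dec)`, clamped at 0 — decay over
#'   roughly 3 hours (`36 * 0.028 ~ 1`).
#'
#' In the default `"replace"` mode a new meal overwrites the tracked
#' `(t_meal, C_meal)` pair; `"superpose"` sums the response of every meal
#' (useful for sensitivity analysis when meals overlap).
#'
#' @param meal data frame of `index` (1-based grid slot), `value` (grams).
#' @param n_index grid length.
#' @param beta_inc per-slot increase factor (default 0.111).
#' @param beta_dec per-slot decrease factor (default 0.028).
#' @param lag slots ignored right after the meal (default 3 = 15 min).
#' @param mode `"replace"` (latest meal wins) or `"superpose"` (sum).
#' @return numeric vector of length `n_index`, grams effective carbohydrate.
#' @export
effective_carbs <- function(meal, n_index, beta_inc = 0.111,
                            beta_dec = 0.028, lag = 3L,
                            mode = c("replace", "superpose")) {
  mode <- match.arg(mode)
  meal <- as_events(meal)
  if (any(meal$value < 0)) stop("negative meal carbohydrates")
  stopifnot(beta_inc > 0, beta_inc <= 1, beta_dec > 0, beta_dec <= 1)
  if (n_index == 0L) return(numeric(0))
  out <- numeric(n_index)
  if (nrow(meal) == 0L) return(out)
  meal <- meal[order(meal$index), ]
  kernel <- function(e, C) {
    # response of one meal of C grams at elapsed slots e (vectorised)
    v <- numeric(length(e))
    inc <- e > lag & e <= lag + 9L
    v[inc] <- pmin(C, (e[inc] - lag) * beta_inc * C)
    dec <- e > lag + 9L
    v[dec] <- pmax(0, C * (1 - (e[dec] - (lag + 9L)) * beta_dec))
    v
  }
  if (mode == "superpose") {
    for (r in seq_len(nrow(meal))) {
      t0 <- meal$index[r]
      e <- seq_len(n_index) - t0
      out <- out + kernel(e, meal$value[r])
    }
  } else {
    bounds <- c(meal$index, n_index + 1L)
    for (r in seq_len(nrow(meal))) {
      span <- meal$index[r]:(bounds[r + 1L] - 1L)
      out[span] <- kernel(span - meal$index[r], meal$value[r])
    }
  }
  pmax(out, 0)
}

#' Effective bolus insulin channel
#'
#' Converts sparse bolus events into dense "insulin on board". The most
#' recent bolus of `I_bolus` units at slot `t_bolus` decays linearly at
#' `r_insulin` units per slot with no absorption delay:
#' `I_eff(t) = max(0, I_bolus - (t - t_bolus) * r_insulin)`.
#' The default decrement is 5 min times a 0.014/min weighted absorption rate
#' (two-pathway absorption: 67% at 0.011/min, 33% at 0.021/min).
#'
#' @param bolus data frame of `index`, `value` (insulin units).
#' @param n_index grid length.
#' @param r_insulin per-slot absorption decrement (default `5 * 0.014`).
#' @param mode `"replace"` (latest bolus wins) or `"superpose"` (sum).
#' @return numeric vector of length `n_index`, effective insulin units.
#' @export
effective_insulin <- function(bolus, n_index, r_insulin = 5 * 0.014,
                              mode = c("replace", "superpose")) {
  mode <- match.arg(mode)
  bolus <- as_events(bolus)
  if (any(bolus$value < 0)) stop("negative bolus dose")
  stopifnot(r_insulin > 0)
  if (n_index == 0L) return(numeric(0))
  out <- numeric(n_index)
  if (nrow(bolus) == 0L) return(out)
  bolus <- bolus[order(bolus$index), ]
  if (mode == "superpose") {
    for (r in seq_len(nrow(bolus))) {
      t0 <- bolus$index[r]
      e <- seq_len(n_index) - t0
      out <- out + pmax(0, ifelse(e >= 0, bolus$value[r] - e * r_insulin, 0))
    }
  } else {
    bounds <- c(bolus$index, n_index + 1L)
    for (r in seq_len(nrow(bolus))) {
      span <- bolus$index[r]:(bounds[r + 1L] - 1L)
      out[span] <- pmax(0, bolus$value[r] - (span - bolus$index[r]) * r_insulin)
    }
  }
  out
}

#' Weighted step-count channel
#'
#' Weighted average of the previous `n` slots of step counts (50 min for
#' `n = 10`), the most recent slot weighted highest:
#' `S_avg(t) = (1/n) * sum_{i=0}^{n-1} (n - i) * steps(t - i)`.
#' History before the series start counts as zero steps.
#'
#' @param steps dense per-slot step counts (missing encoded as 0).
#' @param n window length in slots (default 10).
#' @return numeric vector, same length as `steps`.
#' @export
step_feature <- function(steps, n = 10L) {
  stopifnot(n >= 1L)
  steps <- as.numeric(steps)
  if (any(!is.finite(steps))) stop("steps must be dense and finite")
  if (length(steps) == 0L) return(numeric(0))
  w <- (n:1) / n  # weight for lag n-1 .. 0
  padded <- c(numeric(n - 1L), steps)
  out <- stats::filter(padded, w, method = "convolution", sides = 1)
  as.numeric(out[n:(n - 1L + length(steps))])
}

#' Assemble supervised history windows with horizon-shifted targets
#'
#' Builds the forecaster's training tensors from a patient series: one window
#' per grid slot `t` such that all `L` history slots `t-L+1 .. t` have a
#' defined glucose value and the target slot `t + PH` does too. Each window
#' stacks 4 channels — glucose (raw CGM or Kalman-smoothed mean), effective
#' carbohydrates, effective insulin, weighted steps — and the target is the
#' glucose value `PH` slots ahead.
#'
#' Channels are standardised (z-score) with a scaler fitted on these windows
#' when `scaler = NULL` (training) or with the supplied training scaler
#' (test). Targets are stored in mg/dl and never scaled; the forecaster
#' scales internally and inverse-transforms its predictions.
#'
#' @param series a [patient_series()].
#' @param glucose_channel `"raw"` (CGM with gaps) or `"smoothed"`.
#' @param L history length in slots (default 24 = 2 h).
#' @param PH prediction horizon in slots (6 = 30 min, 12 = 60 min).
#' @param scaler optional scaler from a training call.
#' @param smoothed a [smooth_cgm()] result, required when
#'   `glucose_channel = "smoothed"` (smoothing is run per file by the caller
#'   so that train and test files are never smoothed jointly).
#' @param superpose use additive superposition for carb/insulin kernels.
#'
#' @return a `feature_windows` object: `inputs` array `(n, L, 4)` of scaled
#'   channels, `targets` (mg/dl), `index_map` (target grid index per window),
#'   `scaler`, and the build parameters.
#' @export
build_windows <- function(series, glucose_channel = c("smoothed", "raw"),
                          L = 24L, PH = 6L, scaler = NULL, smoothed = NULL,
                          superpose = FALSE) {
  glucose_channel <- match.arg(glucose_channel)
  L <- as.integer(L); PH <- as.integer(PH)
  if (L < 1L || PH < 1L) stop("L and PH must be >= 1")
  glucose <- if (glucose_channel == "smoothed") {
    if (is.null(smoothed))
      stop("glucose_channel = 'smoothed' requires a smooth_cgm() result")
    if (length(smoothed$mean) != series$n_index)
      stop("smoothed series length does not match the patient grid")
    smoothed$mean
  } else {
    series$cgm
  }
  mode <- if (superpose) "superpose" else "replace"
  n <- series$n_index
  ceff <- effective_carbs(series$meal, n, mode = mode)
  ieff <- effective_insulin(series$bolus, n, mode = mode)
  savg <- step_feature(series$steps)

  ok <- !is.na(glucose)
  # admissible t: L consecutive defined glucose slots ending at t, and target
  run <- cumsum_run(ok)
  t_idx <- which(run >= L)
  t_idx <- t_idx[t_idx + PH <= n & ok[pmin(t_idx + PH, n)]]
  n_win <- length(t_idx)

  channels <- cbind(glucose = glucose, carbs = ceff, insulin = ieff,
                    steps = savg)
  if (is.null(scaler)) {
    if (n_win > 0L) {
      used <- unique(unlist(lapply(t_idx, function(t) (t - L + 1L):t)))
      mu <- colMeans(channels[used, , drop = FALSE])
      sdv <- apply(channels[used, , drop = FALSE], 2, stats::sd)
    } else {
      mu <- rep(0, 4); sdv <- rep(1, 4)
    }
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1  # constant channel guard
    scaler <- list(mean = as.numeric(mu), sd = as.numeric(sdv))
  }

  inputs <- array(0, dim = c(n_win, L, 4L))
  for (j in 1:4) {
    scaled <- (channels[, j] - scaler$mean[j]) / scaler$sd[j]
    for (w in seq_len(n_win)) {
      t <- t_idx[w]
      inputs[w, , j] <- scaled[(t - L + 1L):t]
    }
  }
  structure(list(
    inputs = inputs,
    targets = if (n_win) glucose[t_idx + PH] else numeric(0),
    index_map = t_idx + PH,
    last_glucose = if (n_win) glucose[t_idx] else numeric(0),
    scaler = scaler,
    L = L, PH = PH, glucose_channel = glucose_channel,
    patient_id = series$patient_id
  ), class = "feature_windows")
}

# length of the run of TRUEs ending at each position
cumsum_run <- function(ok) {
  r <- integer(length(ok))
  acc <- 0L
  for (i in seq_along(ok)) {
    acc <- if (ok[i]) acc + 1L else 0L
    r[i] <- acc
  }
  r
}

#' @export
print.feature_windows <- function(x, ...) {
  cat(sprintf("<feature_windows> %d windows (L=%d, PH=%d slots, %s glucose)\n",
              nrow(x$inputs), x$L, x$PH, x$glucose_channel))
  invisible(x)
}

#' Number of windows
#' @param x a `feature_windows` object.
#' @return integer count.
#' @export
n_windows <- function(x) nrow(x$inputs)
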