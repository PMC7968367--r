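#' Construct a patient series on a uniform 5-minute grid
#'
#' `patient_series` is the canonical in-memory representation of one patient
#' record: dense per-slot channels (CGM glucose, step counts, optional
#' auxiliary sensor channels and simulator ground truth) plus sparse event
#' lists (fingerstick readings, bolus doses, meals) indexed by grid slot.
#' Grid slot `i` (1-based) covers the half-open interval
#' `[grid_start + 5*(i-1), grid_start + 5*i)` minutes.
#'
#' @param patient_id character scalar identifier.
#' @param grid_start `POSIXct` timestamp of the first slot (5-min aligned), or
#'   `NA` for an empty series.
#' @param n_index number of 5-minute slots.
#' @param cgm numeric vector of length `n_index`; `NA` marks a missing CGM
#'   sample (gaps are preserved, never imputed here).
#' @param fingerstick data frame with columns `index`, `value` (mg/dl).
#' @param bolus data frame with columns `index`, `value` (insulin units).
#' @param meal data frame with columns `index`, `value` (grams carbohydrate).
#' @param steps numeric vector of length `n_index`; missing slots are encoded
#'   as 0 (no fitness-band record is read as no steps).
#' @param basal data frame with columns `index`, `value` (units/hour); parsed
#'   and stored but unused by the default feature set.
#' @param heart_rate,gsr,skin_temp,air_temp optional dense auxiliary channels
#'   (length `n_index`, `NA` where unobserved).
#' @param truth_bg optional numeric vector of true blood glucose (mg/dl);
#'   populated only by the simulator.
#' @param gender one of `"male"`, `"female"`, `"unknown"`.
#'
#' @return an object of class `patient_series`.
#' @export
patient_series <- function(patient_id, grid_start, n_index,
                           cgm = rep(NA_real_, n_index),
                           fingerstick = empty_events(),
                           bolus = empty_events(),
                           meal = empty_events(),
                           steps = rep(0, n_index),
                           basal = empty_events(),
                           heart_rate = NULL, gsr = NULL,
                           skin_temp = NULL, air_temp = NULL,
                           truth_bg = NULL,
                           gender = "unknown") {
  x <- structure(list(
    patient_id = as.character(patient_id),
    gender = match.arg(gender, c("unknown", "male", "female")),
    grid_start = grid_start,
    n_index = as.integer(n_index),
    cgm = as.numeric(cgm),
    fingerstick = as_events(fingerstick),
    bolus = as_events(bolus),
    meal = as_events(meal),
    steps = as.numeric(steps),
    basal = as_events(basal),
    heart_rate = if (is.null(heart_rate)) NULL else as.numeric(heart_rate),
    gsr = if (is.null(gsr)) NULL else as.numeric(gsr),
    skin_temp = if (is.null(skin_temp)) NULL else as.numeric(skin_temp),
    air_temp = if (is.null(air_temp)) NULL else as.numeric(air_temp),
    truth_bg = if (is.null(truth_bg)) NULL else as.numeric(truth_bg)
  ), class = "patient_series")
  validate_patient_series(x)
}

empty_events <- function() {
  data.frame(index = integer(0), value = numeric(0))
}

as_events <- function(df) {
  stopifnot(is.data.frame(df), all(c("index", "value") %in% names(df)))
  data.frame(index = as.integer(df$index), value = as.numeric(df$value))
}

validate_patient_series <- function(x) {
  n <- x$n_index
  stopifnot(length(n) == 1L, n >= 0L)
  for (ch in c("cgm", "steps")) {
    if (length(x[[ch]]) != n)
      stop(sprintf("channel '%s' has length %d, expected n_index = %d",
                   ch, length(x[[ch]]), n))
  }
  for (ch in c("heart_rate", "gsr", "skin_temp", "air_temp", "truth_bg")) {
    if (!is.null(x[[ch]]) && length(x[[ch]]) != n)
      stop(sprintf("channel '%s' has length %d, expected n_index = %d",
                   ch, length(x[[ch]]), n))
  }
  for (ev in c("fingerstick", "bolus", "meal", "basal")) {
    idx <- x[[ev]]$index
    if (length(idx) && (any(idx < 1L) || any(idx > n)))
      stop(sprintf("event stream '%s' has indices outside [1, %d]", ev, n))
    v <- x[[ev]]$value
    if (length(v) && (any(!is.finite(v)) || any(v < 0)))
      stop(sprintf("event stream '%s' has non-finite or negative values", ev))
  }
  if (any(x$cgm[!is.na(x$cgm)] <= 0))
    stop("cgm values must be positive where present")
  if (any(!is.finite(x$steps)) || any(x$steps < 0))
    stop("step counts must be finite and non-negative")
  if (n > 0L && is.na(x$grid_start))
    stop("grid_start must be a valid timestamp when n_index > 0")
  x
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series> id=%s  n_index=%d (%.1f days)\n",
              x$patient_id, x$n_index, x$n_index / SLOTS_PER_DAY))
  if (x$n_index > 0L)
    cat(sprintf("  grid: %s @ 5 min\n", format(x$grid_start)))
  cat(sprintf("  cgm: %d observed / %d missing\n",
              sum(!is.na(x$cgm)), sum(is.na(x$cgm))))
  cat(sprintf("  events: %d fingerstick, %d bolus, %d meal, %d basal\n",
              nrow(x$fingerstick), nrow(x$bolus), nrow(x$meal),
              nrow(x$basal)))
  if (!is.null(x$truth_bg)) cat("  truth_bg: present (simulated)\n")
  invisible(x)
}

#' Grid timestamps of a patient series
#'
#' @param series a [patient_series()].
#' @return `POSIXct` vector of slot start times.
#' @export
grid_times <- function(series) {
  if (series$n_index == 0L) return(as.POSIXct(character(0)))
  series$grid_start + 60 * GRID_MINUTES * (seq_len(series$n_index) - 1L)
}

#' Map event timestamps onto the 5-minute grid
#'
#' Events are assigned to the slot whose half-open interval contains their
#' timestamp (floor rule): index `floor((t - grid_start) / 5 min) + 1`.
#' For dense per-index channels, when two events land on one slot the later
#' one wins and a warning is emitted; sparse streams keep every event.
#'
#' @param times `POSIXct` event timestamps, sorted non-decreasing.
#' @param values numeric event values.
#' @param grid_start `POSIXct` grid origin.
#' @param n_index grid length in slots.
#' @param dense if `TRUE` return a length-`n_index` vector (later event wins
#'   on collision); otherwise a data frame of `index`, `value` keeping all.
#' @param what channel name used in messages.
#'
#' @return dense numeric vector or sparse event data frame (see `dense`).
#' @export
align_to_grid <- function(times, values, grid_start, n_index,
                          dense = FALSE, what = "events") {
  stopifnot(length(times) == length(values))
  if (length(times) == 0L) {
    return(if (dense) rep(NA_real_, n_index) else empty_events())
  }
  mins <- as.numeric(difftime(times, grid_start, units = "mins"))
  idx <- as.integer(floor(mins / GRID_MINUTES)) + 1L
  if (any(idx < 1L))
    stop(sprintf("%s: event timestamp before grid start", what))
  if (any(idx > n_index))
    stop(sprintf("%s: event timestamp at or after grid end", what))
  if (dense) {
    out <- rep(NA_real_, n_index)
    if (anyDuplicated(idx))
      warning(sprintf("%s: multiple events in one 5-min slot; keeping the later one",
                      what))
    out[idx] <- values  # assignment order = time order, so later wins
    out
  } else {
    data.frame(index = idx, value = as.numeric(values))
  }
}

floor_to_grid <- function(t) {
  as.POSIXct(floor(as.numeric(t) / (60 * GRID_MINUTES)) * 60 * GRID_MINUTES,
             origin = "1970-01-01", tz = attr(t, "tzone") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
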