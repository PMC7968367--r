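#' Sensor-fault specification for the simulator
#'
#' Rates are expected events per day; Poisson counts, uniform placement.
#' Three CGM artifact families are modelled: dropouts (contiguous missing
#' samples), isolated additive spikes, and pressure-induced sensor
#' attenuation (PISA) — a transient multiplicative under-reading caused by
#' pressure on the sensor site.
#'
#' @param dropout_rate expected gaps per day (default 1).
#' @param dropout_length gap length range in slots (default 3-12).
#' @param spike_rate expected isolated spikes per day (default 2).
#' @param spike_magnitude additive spike size range in mg/dl (default 30-80).
#' @param pisa_rate expected PISA events per day (default 1).
#' @param pisa_depth fractional attenuation range (default 0.2-0.5).
#' @param pisa_length PISA duration range in slots (default 6-18).
#' @return a `fault_spec` object.
#' @export
fault_spec <- function(dropout_rate = 1, dropout_length = c(3L, 12L),
                       spike_rate = 2, spike_magnitude = c(30, 80),
                       pisa_rate = 1, pisa_depth = c(0.2, 0.5),
                       pisa_length = c(6L, 18L)) {
  stopifnot(dropout_rate >= 0, spike_rate >= 0, pisa_rate >= 0,
            all(pisa_depth >= 0), all(pisa_depth <= 1))
  structure(list(dropout_rate = dropout_rate,
                 dropout_length = as.integer(dropout_length),
                 spike_rate = spike_rate,
                 spike_magnitude = as.numeric(spike_magnitude),
                 pisa_rate = pisa_rate,
                 pisa_depth = as.numeric(pisa_depth),
                 pisa_length = as.integer(pisa_length)),
            class = "fault_spec")
}

#' Simulation configuration
#'
#' Parameters of the discrete-time glucoregulatory toy model used by
#' [generate_patient()]. The input kinetics (carbohydrate absorption, bolus
#' decay, weighted steps) are exactly the feature-crafting kernels of the
#' forecasting pipeline, so the generator and the forecaster share an
#' inductive bias and skill experiments are meaningful.
#'
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @param days simulated days (default 30).
#' @param basal_glucose resting glucose, mg/dl (default 120).
#' @param carb_gain mg/dl rise per gram of effective carbohydrate per slot
#'   (default 0.5).
#' @param insulin_gain mg/dl drop per effective insulin unit per slot
#'   (default 3.0).
#' @param activity_gain mg/dl drop per weighted-step unit per slot
#'   (default 0.002).
#' @param mean_reversion per-slot fraction pulling glucose back toward
#'   `basal_glucose` (default 0.05).
#' @param process_noise_sd physiological noise sd, mg/dl per slot (default 1).
#' @param sensor_noise_sd CGM measurement noise sd, mg/dl (default 5).
#' @param sensor_lag CGM lag behind blood glucose, slots (default 1): the
#'   interstitial-vs-blood glucose delay collapsed to one grid step.
#' @param fault_spec a [fault_spec()].
#' @param meals_per_day integer range (default `c(3, 5)`).
#' @param carbs_per_meal grams range (default `c(20, 100)`).
#' @param insulin_to_carb_ratio bolus units per gram (default 0.1).
#' @param fingersticks_per_day sparse reference readings per day (default 4).
#' @return a `sim_config` object.
#' @export
sim_config <- function(seed = 1L, days = 30L, basal_glucose = 120,
                       carb_gain = 0.5, insulin_gain = 3.0,
                       activity_gain = 0.002, mean_reversion = 0.05,
                       process_noise_sd = 1.0, sensor_noise_sd = 5.0,
                       sensor_lag = 1L, fault_spec = cgmforecast::fault_spec(),
                       meals_per_day = c(3L, 5L),
                       carbs_per_meal = c(20, 100),
                       insulin_to_carb_ratio = 0.1,
                       fingersticks_per_day = 4L) {
  stopifnot(days >= 1, carb_gain >= 0, insulin_gain >= 0, activity_gain >= 0,
            process_noise_sd >= 0, sensor_noise_sd >= 0, sensor_lag >= 0,
            mean_reversion >= 0, mean_reversion <= 1,
            inherits(fault_spec, "fault_spec"))
  structure(list(seed = as.integer(seed), days = as.integer(days),
                 basal_glucose = basal_glucose, carb_gain = carb_gain,
                 insulin_gain = insulin_gain, activity_gain = activity_gain,
                 mean_reversion = mean_reversion,
                 process_noise_sd = process_noise_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 sensor_lag = as.integer(sensor_lag),
                 fault_spec = fault_spec,
                 meals_per_day = as.integer(meals_per_day),
                 carbs_per_meal = as.numeric(carbs_per_meal),
                 insulin_to_carb_ratio = insulin_to_carb_ratio,
                 fingersticks_per_day = as.integer(fingersticks_per_day)),
            class = "sim_config")
}

with_preserved_rng <- function(code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Generate a synthetic type-1-diabetes patient record
#'
#' Simulates true blood glucose with the discrete-time update
#' \deqn{G_{k+1} = G_k + g_C C_{eff,k} - g_I I_{eff,k} - g_S S_{avg,k}
#'   + \rho (G_b - G_k) + \epsilon_k,}
#' clamped to the displayable CGM range 40-400 mg/dl, where the effective
#' carbohydrate, effective insulin, and weighted-step inputs come from the
#' package's own feature kernels applied to randomly scheduled daytime meals
#' (with proportional boluses) and walking bouts. The CGM channel observes
#' the truth with a one-slot sensor lag plus Gaussian noise, and sensor
#' faults from `config$fault_spec` are injected afterwards. Fingerstick
#' readings are truth plus N(0, 2 mg/dl) noise at random daytime slots.
#'
#' @param config a [sim_config()].
#' @return a [patient_series()] with `truth_bg` populated and a `fault_log`
#'   attribute describing injected faults.
#' @export
generate_patient <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_rng({
    set.seed(config$seed)
    n <- config$days * SLOTS_PER_DAY
    day_origin <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

    # meal / bolus schedule: meals between 06:00 and 22:00
    meal_idx <- integer(0); meal_g <- numeric(0)
    for (d in seq_len(config$days)) {
      k <- sample(config$meals_per_day[1]:config$meals_per_day[2], 1)
      slots <- sort(sample(day_slot_range(6, 22), k)) + (d - 1L) * SLOTS_PER_DAY
      meal_idx <- c(meal_idx, slots)
      meal_g <- c(meal_g, runif(k, config$carbs_per_meal[1],
                                config$carbs_per_meal[2]))
    }
    meal <- data.frame(index = meal_idx, value = meal_g)
    bolus <- data.frame(index = meal_idx,
                        value = meal_g * config$insulin_to_carb_ratio)

    # steps: low daytime background plus 2 brisk walks per day
    steps <- numeric(n)
    for (d in seq_len(config$days)) {
      base <- (d - 1L) * SLOTS_PER_DAY
      day_rng <- day_slot_range(7, 22)
      steps[base + day_rng] <- rpois(length(day_rng), 10)
      for (w in seq_len(2)) {
        start <- base + sample(day_slot_range(7, 21), 1)
        span <- start:min(start + 5L, n)
        steps[span] <- steps[span] + rpois(length(span), 400)
      }
    }

    ceff <- effective_carbs(meal, n)
    ieff <- effective_insulin(bolus, n)
    savg <- step_feature(steps)

    truth <- numeric(n)
    truth[1] <- config$basal_glucose
    eps <- rnorm(n, 0, config$process_noise_sd)
    for (k in seq_len(n - 1L)) {
      truth[k + 1] <- truth[k] +
        config$carb_gain * ceff[k] -
        config$insulin_gain * ieff[k] -
        config$activity_gain * savg[k] +
        config$mean_reversion * (config$basal_glucose - truth[k]) +
        eps[k]
      truth[k + 1] <- min(400, max(40, truth[k + 1]))
    }

    lag <- config$sensor_lag
    lagged <- if (lag > 0) c(rep(truth[1], lag), truth[seq_len(n - lag)])
              else truth
    cgm <- pmax(1, lagged + rnorm(n, 0, config$sensor_noise_sd))

    fs_idx <- sort(unlist(lapply(seq_len(config$days), function(d) {
      sample(day_slot_range(6, 23), config$fingersticks_per_day) +
        (d - 1L) * SLOTS_PER_DAY
    })))
    fingerstick <- data.frame(index = fs_idx,
                              value = pmax(1, truth[fs_idx] + rnorm(length(fs_idx), 0, 2)))

    series <- patient_series(
      patient_id = sprintf("sim%03d", config$seed %% 1000L),
      grid_start = day_origin, n_index = n,
      cgm = cgm, fingerstick = fingerstick, bolus = bolus, meal = meal,
      steps = steps, truth_bg = truth)
    inject_faults(series, config$fault_spec, seed = config$seed + 1L)
  })
}

day_slot_range <- function(from_hour, to_hour) {
  (from_hour * 12L + 1L):(to_hour * 12L)
}

#' Inject CGM sensor faults
#'
#' Returns a copy of the series with dropouts (contiguous CGM set to
#' missing), isolated additive spikes, and PISA events (contiguous
#' multiplicative attenuation by `1 - depth`) applied to the CGM channel
#' only; `truth_bg` and all other channels are untouched. The injected
#' faults are recorded in a `fault_log` attribute.
#'
#' @param series a [patient_series()].
#' @param spec a [fault_spec()].
#' @param seed RNG seed for fault placement.
#' @param events optional data frame of forced faults (columns `type`
#'   in dropout/spike/pisa, `start`, `length`, `param` = spike mg/dl or PISA
#'   depth), bypassing random generation — used for targeted testing.
#' @return a [patient_series()] with faulted CGM and a `fault_log` attribute.
#' @export
inject_faults <- function(series, spec, seed = 1L, events = NULL) {
  stopifnot(inherits(series, "patient_series"), inherits(spec, "fault_spec"))
  n <- series$n_index
  days <- n / SLOTS_PER_DAY
  log <- data.frame(type = character(0), start = integer(0),
                    length = integer(0), param = numeric(0))
  if (is.null(events)) {
    events <- with_preserved_rng({
      set.seed(seed)
      ev <- list()
      n_drop <- rpois(1, spec$dropout_rate * days)
      if (n_drop) ev$drop <- data.frame(
        type = "dropout",
        start = sample.int(n, n_drop, replace = TRUE),
        length = sample(spec$dropout_length[1]:spec$dropout_length[2],
                        n_drop, replace = TRUE),
        param = NA_real_)
      n_spk <- rpois(1, spec$spike_rate * days)
      if (n_spk) ev$spk <- data.frame(
        type = "spike",
        start = sample.int(n, n_spk, replace = TRUE),
        length = 1L,
        param = runif(n_spk, spec$spike_magnitude[1], spec$spike_magnitude[2]))
      n_pisa <- rpois(1, spec$pisa_rate * days)
      if (n_pisa) ev$pisa <- data.frame(
        type = "pisa",
        start = sample.int(n, n_pisa, replace = TRUE),
        length = sample(spec$pisa_length[1]:spec$pisa_length[2],
                        n_pisa, replace = TRUE),
        param = runif(n_pisa, spec$pisa_depth[1], spec$pisa_depth[2]))
      do.call(rbind, ev) %||% log
    })
  }
  cgm <- series$cgm
  for (r in seq_len(NROW(events))) {
    span <- events$start[r]:min(events$start[r] + events$length[r] - 1L, n)
    switch(events$type[r],
      dropout = { cgm[span] <- NA_real_ },
      spike = { cgm[span] <- cgm[span] + events$param[r] },
      pisa = { cgm[span] <- cgm[span] * (1 - events$param[r]) },
      stop("unknown fault type: ", events$type[r]))
  }
  out <- series
  out$cgm <- cgm
  attr(out, "fault_log") <- rbind(log, events)
  out
}
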