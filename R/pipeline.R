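#' Pipeline configuration
#'
#' Builds the full-pipeline configuration from optional overrides, merged
#' over defaults. Any field can also come from a YAML file via
#' [read_pipeline_config()]. One global seed fans out to per-stage seeds
#' through a fixed derivation (see [derive_seed()]), so stages can be re-run
#' in isolation yet deterministically.
#'
#' @param seed global seed.
#' @param input list with optional `train`/`test` file paths (CSV or XML);
#'   when absent the simulator supplies both files.
#' @param simulation [sim_config()] overrides plus `days_train`, `days_test`.
#' @param smoothing list of `q`, `r` Kalman parameters.
#' @param features list of `L`, `PH_minutes`, `glucose_channel`, `superpose`.
#' @param model [model_config()] overrides.
#' @param evaluation list with `reference`.
#' @param output_dir artifact directory (default `tempfile()`).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1L, input = list(),
                            simulation = list(), smoothing = list(),
                            features = list(), model = list(),
                            evaluation = list(),
                            output_dir = tempfile("cgm_run_")) {
  defaults <- list(
    seed = 1L,
    input = list(train = NULL, test = NULL),
    simulation = list(days_train = 10L, days_test = 5L),
    smoothing = list(q = 1, r = 25),
    features = list(L = 24L, PH_minutes = 30L,
                    glucose_channel = "smoothed", superpose = FALSE),
    model = list(max_epochs = 60L, patience = 15L),
    evaluation = list(reference = "auto"),
    output_dir = output_dir)
  cfg <- utils::modifyList(defaults, list(
    seed = as.integer(seed), input = input, simulation = simulation,
    smoothing = smoothing, features = features, model = model,
    evaluation = evaluation, output_dir = output_dir))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipeline_config()]
#'   arguments.
#' @param seed optional global seed overriding the file's.
#' @param output_dir optional artifact directory override.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL, output_dir = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path) %||% list()
  args <- raw[intersect(names(raw), c("seed", "input", "simulation",
                                      "smoothing", "features", "model",
                                      "evaluation", "output_dir"))]
  if (!is.null(seed)) args$seed <- as.integer(seed)
  if (!is.null(output_dir)) args$output_dir <- output_dir
  do.call(pipeline_config, args)
}

#' Derive a per-stage seed from the global seed
#'
#' Fixed affine derivation `(seed * 131 + offset) mod (2^31 - 1)` with a
#' documented offset per stage, so that re-running one stage in isolation
#' reproduces its output.
#'
#' @param seed global integer seed.
#' @param stage one of `"sim_train"`, `"sim_test"`, `"model"`.
#' @return integer stage seed.
#' @export
derive_seed <- function(seed, stage = c("sim_train", "sim_test", "model")) {
  stage <- match.arg(stage)
  offset <- c(sim_train = 1L, sim_test = 2L, model = 3L)[[stage]]
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483647)
}

read_any_series <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (grepl("\\.xml$", path, ignore.case = TRUE)) read_ohio_xml(path)
  else read_patient_csv(path)
}

#' Run the full forecasting pipeline
#'
#' simulate/read the training and test files, Kalman-smooth each file
#' independently, craft features, train the stacked LSTM, predict on the
#' test file, and evaluate. All intermediate artifacts plus a manifest
#' (config, config hash, derived seeds, versions, artifact paths) are
#' written under `config$output_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the `eval_report`, invisibly with attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$input$train, config$input$test))
    if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(nm) file.path(config$output_dir, nm)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed (artifacts in %s): %s",
                   name, config$output_dir, conditionMessage(e)),
           call. = FALSE))
  }

  sim_args <- config$simulation
  days_train <- sim_args$days_train %||% 10L
  days_test <- sim_args$days_test %||% 5L
  sim_args$days_train <- sim_args$days_test <- NULL

  train_series <- stage("load_train", {
    if (!is.null(config$input$train)) read_any_series(config$input$train)
    else do.call(generate_patient, list(do.call(sim_config, c(
      list(seed = derive_seed(config$seed, "sim_train"), days = days_train),
      sim_args))))
  })
  test_series <- stage("load_test", {
    if (!is.null(config$input$test)) read_any_series(config$input$test)
    else do.call(generate_patient, list(do.call(sim_config, c(
      list(seed = derive_seed(config$seed, "sim_test"), days = days_test),
      sim_args))))
  })
  write_patient_csv(train_series, art("train.csv"))
  write_patient_csv(test_series, art("test.csv"))

  fe <- config$features
  PH <- as.integer((fe$PH_minutes %||% 30L) / GRID_MINUTES)
  channel <- fe$glucose_channel %||% "smoothed"

  sm_train <- stage("smooth", {
    if (channel == "smoothed")
      smooth_cgm(train_series, q = config$smoothing$q, r = config$smoothing$r)
  })
  windows <- stage("featurize", build_windows(
    train_series, glucose_channel = channel, L = fe$L %||% 24L, PH = PH,
    smoothed = sm_train, superpose = isTRUE(fe$superpose)))

  mc <- do.call(model_config, c(config$model,
                                list(seed = derive_seed(config$seed,
                                                        "model"))))
  trained <- stage("train", train_model(build_model(mc, L = windows$L),
                                        windows))
  saveRDS(trained, art("model.rds"))

  report <- stage("evaluate", evaluate_forecast(
    trained, test_series, reference = config$evaluation$reference %||% "auto",
    q = config$smoothing$q, r = config$smoothing$r))
  utils::write.csv(report$forecast, art("predictions.csv"),
                   row.names = FALSE)

  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    seeds = list(global = config$seed,
                 sim_train = derive_seed(config$seed, "sim_train"),
                 sim_test = derive_seed(config$seed, "sim_test"),
                 model = derive_seed(config$seed, "model")),
    versions = list(package = as.character(utils::packageVersion("cgmforecast")),
                    r = R.version.string),
    artifacts = c("train.csv", "test.csv", "model.rds", "predictions.csv",
                  "report.json", "manifest.json"),
    report = report[c("patient_id", "PH_minutes", "glucose_channel",
                      "reference", "forecast_rmse", "baseline_rmse",
                      "sensor_rmse_raw", "sensor_rmse_smoothed", "n_points")])
  jsonlite::write_json(manifest$report, art("report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  attr(report, "manifest") <- manifest
  invisible(report)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  cfg <- unclass(config)
  cfg$output_dir <- NULL  # location must not change the experiment identity
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}
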