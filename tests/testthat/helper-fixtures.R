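# fixture builders shared across test files

t0 <- function() as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

# a bare series with a chosen cgm vector and optional events
make_series <- function(cgm, fingerstick = NULL, bolus = NULL, meal = NULL,
                        steps = NULL, truth_bg = NULL, id = "t") {
  n <- length(cgm)
  ev <- function(x) if (is.null(x)) data.frame(index = integer(0),
                                               value = numeric(0)) else x
  patient_series(id, t0(), n, cgm = cgm,
                 fingerstick = ev(fingerstick), bolus = ev(bolus),
                 meal = ev(meal),
                 steps = steps %||% rep(0, n), truth_bg = truth_bg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small, fast forecaster configuration for unit tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_units = 8L, dense_sizes = c(16L, 8L), batch_size = 32L,
         max_epochs = 5L, patience = 5L, seed = 7L),
    list(...))
  args$patience <- min(args$patience, args$max_epochs)
  do.call(model_config, args)
}

# a fast, fully specified pipeline configuration for determinism checks
tiny_pipeline <- function(seed = 3L, outdir = tempfile("run_")) {
  pipeline_config(
    seed = seed,
    simulation = list(days_train = 2L, days_test = 1L),
    features = list(L = 12L, PH_minutes = 30L),
    model = list(hidden_units = 8L, dense_sizes = c(16L, 8L),
                 batch_size = 32L, max_epochs = 2L, patience = 2L),
    output_dir = outdir)
}

# write an OhioT1DM-style XML fixture from (stream -> data.frame(ts, value))
write_xml_fixture <- function(streams, path, root_attrs = c(id = "559")) {
  lines <- c("<?xml version=\"1.0\"?>",
             sprintf("<patient %s>",
                     paste(sprintf('%s="%s"', names(root_attrs), root_attrs),
                           collapse = " ")))
  for (el in names(streams)) {
    s <- streams[[el]]
    lines <- c(lines, sprintf("  <%s>", el))
    attr_name <- if (el == "bolus") "dose" else if (el == "meal") "carbs"
                 else "value"
    lines <- c(lines, sprintf('    <event ts="%s" %s="%s"/>',
                              s$ts, attr_name, s$value))
    lines <- c(lines, sprintf("  </%s>", el))
  }
  lines <- c(lines, "</patient>")
  writeLines(lines, path)
  path
}

ohio_ts <- function(minutes_after_midnight) {
  format(t0() + 60 * minutes_after_midnight, "%d-%m-%Y %H:%M:%S")
}
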