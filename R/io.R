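#' Read an OhioT1DM-style patient XML file
#'
#' Parses a per-patient XML event file into a [patient_series()]. The
#' expected layout is a `<patient>` root holding one element per stream
#' (`<glucose_level>`, `<finger_stick>`, `<bolus>`, `<meal>`, `<basal>`,
#' `<basis_steps>`, `<basis_heart_rate>`, `<basis_gsr>`,
#' `<basis_skin_temperature>`, `<basis_air_temperature>`), each a list of
#' `<event ts="..." value="..."/>` records. Real exports differ in attribute
#' naming (e.g. bolus doses in a `dose` attribute, meals in `carbs`), so the
#' attribute lookup is configurable via `attr_map`.
#'
#' The grid spans the earliest to the latest event timestamp, rounded outward
#' to 5-minute boundaries; all streams are aligned with [align_to_grid()].
#' Unknown stream elements are skipped with a warning. CGM gaps are preserved
#' as `NA` — no value is ever fabricated at the I/O layer.
#'
#' @param path path to the XML file.
#' @param attr_map named list overriding, per stream, the candidate value
#'   attribute names tried in order. Defaults cover the common variants, e.g.
#'   `list(bolus = c("dose", "value"), meal = c("carbs", "value"))`.
#' @param tz timezone for parsed clock times (timestamps are treated as
#'   timezone-naive local clock times; default `"UTC"` keeps arithmetic exact).
#'
#' @return a [patient_series()].
#' @export
read_ohio_xml <- function(path, attr_map = list(), tz = "UTC") {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in ", path, ": ", conditionMessage(e)))
  root <- doc
  if (xml2::xml_name(root) != "patient")
    stop("malformed XML: expected <patient> root, found <",
         xml2::xml_name(root), ">")

  kind_of <- c(glucose_level = "cgm", finger_stick = "fingerstick",
               bolus = "bolus", meal = "meal", basal = "basal",
               basis_steps = "steps", basis_heart_rate = "heart_rate",
               basis_gsr = "gsr", basis_skin_temperature = "skin_temp",
               basis_air_temperature = "air_temp")
  value_attrs <- list(
    cgm = "value", fingerstick = "value", basal = "value",
    bolus = c("dose", "value"), meal = c("carbs", "value"),
    steps = "value", heart_rate = "value", gsr = "value",
    skin_temp = "value", air_temp = "value")
  for (nm in names(attr_map)) value_attrs[[nm]] <- attr_map[[nm]]
  ts_attrs <- attr_map[["ts"]] %||% c("ts", "timestamp", "ts_begin")

  streams <- list()
  for (child in xml2::xml_children(root)) {
    el <- xml2::xml_name(child)
    if (!el %in% names(kind_of)) {
      warning("skipping unknown event stream <", el, ">")
      next
    }
    kind <- kind_of[[el]]
    events <- xml2::xml_find_all(child, "./event")
    if (length(events) == 0L) next
    ts_raw <- rep(NA_character_, length(events))
    for (a in ts_attrs) {
      miss <- is.na(ts_raw)
      if (!any(miss)) break
      ts_raw[miss] <- xml2::xml_attr(events[miss], a)
    }
    val_raw <- rep(NA_character_, length(events))
    for (a in value_attrs[[kind]]) {
      miss <- is.na(val_raw)
      if (!any(miss)) break
      val_raw[miss] <- xml2::xml_attr(events[miss], a)
    }
    if (anyNA(ts_raw))
      stop("stream <", el, ">: event without a timestamp attribute (tried: ",
           paste(ts_attrs, collapse = ", "), ")")
    if (anyNA(val_raw))
      stop("stream <", el, ">: event without a value attribute (tried: ",
           paste(value_attrs[[kind]], collapse = ", "), ")")
    times <- parse_clock(ts_raw, tz)
    o <- order(times)
    streams[[kind]] <- data.frame(time = times[o],
                                  value = as.numeric(val_raw[o]))
  }

  build_series_from_streams(
    streams,
    patient_id = xml2::xml_attr(root, "id") %|na|% "unknown",
    gender = tolower(xml2::xml_attr(root, "gender") %|na|% "unknown"))
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

parse_clock <- function(x, tz = "UTC") {
  fmts <- c("%d-%m-%Y %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")
  for (f in fmts) {
    t <- as.POSIXct(x, format = f, tz = tz)
    if (!anyNA(t)) return(t)
  }
  bad <- x[is.na(as.POSIXct(x, format = fmts[1], tz = tz))][1]
  stop("unparseable timestamp: '", bad, "'")
}

build_series_from_streams <- function(streams, patient_id, gender = "unknown") {
  all_times <- do.call(c, lapply(streams, function(s) s$time))
  if (is.null(all_times) || length(all_times) == 0L) {
    return(patient_series(patient_id, as.POSIXct(NA), 0L,
                          gender = gender))
  }
  grid_start <- floor_to_grid(min(all_times))
  n_index <- as.integer(floor(as.numeric(difftime(max(all_times), grid_start,
                                                  units = "mins")) /
                                GRID_MINUTES)) + 1L
  al <- function(kind, dense) {
    s <- streams[[kind]]
    if (is.null(s)) {
      if (dense) rep(NA_real_, n_index) else empty_events()
    } else {
      align_to_grid(s$time, s$value, grid_start, n_index,
                    dense = dense, what = kind)
    }
  }
  steps <- al("steps", dense = TRUE)
  steps[is.na(steps)] <- 0
  patient_series(
    patient_id, grid_start, n_index,
    cgm = al("cgm", dense = TRUE),
    fingerstick = al("fingerstick", dense = FALSE),
    bolus = al("bolus", dense = FALSE),
    meal = al("meal", dense = FALSE),
    basal = al("basal", dense = FALSE),
    steps = steps,
    heart_rate = if (is.null(streams$heart_rate)) NULL else al("heart_rate", TRUE),
    gsr = if (is.null(streams$gsr)) NULL else al("gsr", TRUE),
    skin_temp = if (is.null(streams$skin_temp)) NULL else al("skin_temp", TRUE),
    air_temp = if (is.null(streams$air_temp)) NULL else al("air_temp", TRUE),
    gender = if (gender %in% c("male", "female")) gender else "unknown")
}

#' Write a patient series as OhioT1DM-style XML
#'
#' Inverse of [read_ohio_xml()] for the streams the default pipeline uses.
#'
#' @param series a [patient_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ohio_xml <- function(series, path) {
  doc <- xml2::xml_new_root("patient", id = series$patient_id,
                            gender = series$gender)
  tfmt <- function(i) format(grid_times(series)[i], "%d-%m-%Y %H:%M:%S")
  add_dense <- function(el, v) {
    node <- xml2::xml_add_child(doc, el)
    for (i in which(!is.na(v)))
      xml2::xml_add_child(node, "event", ts = tfmt(i), value = num_str(v[i]))
  }
  add_sparse <- function(el, ev, attr = "value") {
    node <- xml2::xml_add_child(doc, el)
    for (r in seq_len(nrow(ev))) {
      args <- list(node, "event", ts = tfmt(ev$index[r]))
      args[[attr]] <- num_str(ev$value[r])
      do.call(xml2::xml_add_child, args)
    }
  }
  add_dense("glucose_level", series$cgm)
  add_sparse("finger_stick", series$fingerstick)
  add_sparse("bolus", series$bolus, "dose")
  add_sparse("meal", series$meal, "carbs")
  add_sparse("basal", series$basal)
  add_dense("basis_steps", ifelse(series$steps > 0, series$steps, NA))
  xml2::write_xml(doc, path)
  invisible(path)
}

num_str <- function(x) {
  vapply(x, function(v) formatC(v, digits = 17, format = "g"), character(1))
}

#' Read a patient series from the CSV dialect
#'
#' One row per 5-minute slot, header
#' `timestamp,cgm,fingerstick,bolus,meal_carbs,steps,truth_bg`, ISO-8601
#' timestamps, empty cell = missing. Sparse events sit on their slot's row.
#' Missing step cells are read as 0 (no record means no recorded steps).
#'
#' @param path path to the CSV file.
#' @param patient_id identifier; defaults to the file name without extension.
#' @param tz timezone for parsed timestamps.
#' @return a [patient_series()].
#' @export
read_patient_csv <- function(path, patient_id = NULL, tz = "UTC") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("timestamp", "cgm", "fingerstick", "bolus", "meal_carbs",
                "steps")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    return(patient_series(patient_id %||% file_stem(path), as.POSIXct(NA), 0L))
  times <- parse_clock(df$timestamp, tz)
  if (anyDuplicated(times)) stop("duplicate timestamp rows in ", path)
  if (is.unsorted(times)) {
    o <- order(times)
    df <- df[o, ]
    times <- times[o]
  }
  grid_start <- floor_to_grid(times[1])
  idx <- as.integer(floor(as.numeric(difftime(times, grid_start,
                                              units = "mins")) /
                            GRID_MINUTES)) + 1L
  n_index <- idx[length(idx)]
  numcol <- function(nm) suppressWarnings(as.numeric(df[[nm]]))
  dense <- function(nm) {
    out <- rep(NA_real_, n_index)
    out[idx] <- numcol(nm)
    out
  }
  sparse <- function(nm) {
    v <- numcol(nm)
    keep <- !is.na(v)
    data.frame(index = idx[keep], value = v[keep])
  }
  steps <- dense("steps")
  steps[is.na(steps)] <- 0
  truth <- if ("truth_bg" %in% names(df)) dense("truth_bg") else NULL
  if (!is.null(truth) && all(is.na(truth))) truth <- NULL
  patient_series(patient_id %||% file_stem(path), grid_start, n_index,
                 cgm = dense("cgm"),
                 fingerstick = sparse("fingerstick"),
                 bolus = sparse("bolus"),
                 meal = sparse("meal_carbs"),
                 steps = steps,
                 truth_bg = truth)
}

file_stem <- function(path) tools::file_path_sans_ext(basename(path))

#' Write a patient series in the CSV dialect
#'
#' Values are printed at full double precision so that
#' `read_patient_csv(write_patient_csv(x))` round-trips exactly.
#'
#' @param series a [patient_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(series, path) {
  n <- series$n_index
  cell <- function(v) ifelse(is.na(v), "", num_str(v))
  sparse_col <- function(ev) {
    out <- rep(NA_real_, n)
    out[ev$index] <- ev$value
    out
  }
  df <- data.frame(
    timestamp = format(grid_times(series), "%Y-%m-%dT%H:%M:%S"),
    cgm = cell(series$cgm),
    fingerstick = cell(sparse_col(series$fingerstick)),
    bolus = cell(sparse_col(series$bolus)),
    meal_carbs = cell(sparse_col(series$meal)),
    steps = cell(ifelse(series$steps == 0, NA, series$steps)),
    truth_bg = cell(series$truth_bg %||% rep(NA_real_, n)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
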