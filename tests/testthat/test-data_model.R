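test_that("grid alignment uses half-open floor slots", {
  # event 7 min after grid start falls in the second slot
  out <- align_to_grid(t0() + 60 * 7, 42, t0(), 4, dense = FALSE)
  expect_equal(out$index, 2L)
  # event exactly at grid start falls in the first slot
  out <- align_to_grid(t0(), 1, t0(), 4, dense = FALSE)
  expect_equal(out$index, 1L)
  # out-of-range events are errors
  expect_error(align_to_grid(t0() - 1, 1, t0(), 4), "before grid start")
  expect_error(align_to_grid(t0() + 60 * 20, 1, t0(), 4), "grid end")
})

test_that("dense alignment keeps the later of two same-slot events", {
  times <- t0() + 60 * c(0, 2, 5)
  expect_warning(v <- align_to_grid(times, c(10, 11, 12), t0(), 2,
                                    dense = TRUE),
                 "keeping the later")
  expect_equal(v, c(11, 12))
})

test_that("XML reader transcribes CGM events and preserves gaps", {
  f <- tempfile(fileext = ".xml")
  write_xml_fixture(list(glucose_level = data.frame(
    ts = ohio_ts(c(0, 5, 10)), value = c(100, 105, 110))), f)
  s <- read_ohio_xml(f)
  expect_s3_class(s, "patient_series")
  expect_equal(s$n_index, 3L)
  expect_equal(s$cgm, c(100, 105, 110))
  expect_equal(s$patient_id, "559")

  # a 15-min gap stays missing: nothing is fabricated
  write_xml_fixture(list(glucose_level = data.frame(
    ts = ohio_ts(c(0, 15)), value = c(100, 112))), f)
  s <- read_ohio_xml(f)
  expect_equal(s$n_index, 4L)
  expect_equal(s$cgm, c(100, NA, NA, 112))
})

test_that("XML reader handles attribute variants, unknown streams, errors", {
  f <- tempfile(fileext = ".xml")
  write_xml_fixture(list(
    glucose_level = data.frame(ts = ohio_ts(c(0, 5)), value = c(90, 95)),
    bolus = data.frame(ts = ohio_ts(2), value = 4.5),   # dose attribute
    meal = data.frame(ts = ohio_ts(7), value = 60)),    # carbs attribute
    f)
  s <- read_ohio_xml(f)
  expect_equal(s$bolus, data.frame(index = 1L, value = 4.5))
  expect_equal(s$meal, data.frame(index = 2L, value = 60))

  writeLines(c("<?xml version=\"1.0\"?>", "<patient id=\"x\">",
               "<mystery><event ts=\"01-01-2024 00:00:00\" value=\"1\"/></mystery>",
               "<glucose_level><event ts=\"01-01-2024 00:00:00\" value=\"99\"/></glucose_level>",
               "</patient>"), f)
  expect_warning(s <- read_ohio_xml(f), "unknown event stream")
  expect_equal(s$cgm, 99)

  writeLines("<patient><glucose_level>", f)
  expect_error(read_ohio_xml(f), "malformed XML")
})

test_that("empty patient element yields an empty series", {
  f <- tempfile(fileext = ".xml")
  writeLines(c("<?xml version=\"1.0\"?>", "<patient id=\"p\"></patient>"), f)
  s <- read_ohio_xml(f)
  expect_equal(s$n_index, 0L)
  expect_length(s$cgm, 0)
  expect_equal(nrow(s$meal), 0L)
})

test_that("CSV round trip is exact and empty cells stay missing", {
  set.seed(4)
  s <- make_series(cgm = c(100.123456789, NA, 97.5, 110 + pi, NA, 120),
                   fingerstick = data.frame(index = 3L, value = 101.25),
                   bolus = data.frame(index = 2L, value = 4.2),
                   meal = data.frame(index = 2L, value = 55),
                   steps = c(0, 0, 13, 0, 7, 0),
                   truth_bg = runif(6, 80, 200))
  f <- tempfile(fileext = ".csv")
  write_patient_csv(s, f)
  s2 <- read_patient_csv(f, patient_id = "t")
  for (field in c("n_index", "cgm", "fingerstick", "bolus", "meal", "steps",
                  "truth_bg"))
    expect_equal(s2[[field]], s[[field]], info = field)
  expect_equal(s2$grid_start, s$grid_start)
  # second round trip is identical (idempotent)
  f2 <- tempfile(fileext = ".csv")
  write_patient_csv(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("CSV reader rejects duplicates and missing columns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,cgm,fingerstick,bolus,meal_carbs,steps,truth_bg",
               "2024-01-01T00:00:00,100,,,,,",
               "2024-01-01T00:00:00,101,,,,,"), f)
  expect_error(read_patient_csv(f), "duplicate timestamp")
  writeLines(c("timestamp,cgm", "2024-01-01T00:00:00,100"), f)
  expect_error(read_patient_csv(f), "fingerstick")
})

test_that("a full day spans 288 grid slots", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,cgm,fingerstick,bolus,meal_carbs,steps,truth_bg",
               "2024-01-01T00:00:00,100,,,,,",
               "2024-01-01T23:55:00,101,,,,,"), f)
  s <- read_patient_csv(f)
  expect_equal(s$n_index, 288L)
  expect_equal(sum(is.na(s$cgm)), 286L)
})

test_that("series validation enforces the core invariants", {
  expect_error(patient_series("p", t0(), 3, cgm = c(100, -5, 90)),
               "positive")
  expect_error(patient_series("p", t0(), 3,
                              meal = data.frame(index = 5L, value = 10)),
               "outside")
  expect_error(patient_series("p", t0(), 3, cgm = c(100, 100)), "length")
})
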