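test_that("effective carbohydrate follows lag / rise / decay phases", {
  # single 100 g meal in the first slot; elapsed slots e = index - 1
  meal <- data.frame(index = 1L, value = 100)
  ceff <- effective_carbs(meal, 60)
  # first 15 min after the meal have no effect
  expect_equal(ceff[1:4], rep(0, 4))            # e = 0..3
  # increasing phase: e = 6 -> (6-3) * 0.111 * 100
  expect_equal(ceff[7], (6 - 3) * 0.111 * 100)  # 33.3
  # rise is capped at the meal size
  expect_true(all(ceff <= 100))
  # 3 h into the decreasing phase the effect is exhausted:
  # e = 48, d = 36 -> 1 - 36*0.028 < 0 -> clamped to 0
  expect_equal(ceff[49], 0)
  expect_true(all(ceff >= 0))
  # near-continuity at the peak: 9 * 0.111 = 0.999 of the meal
  expect_equal(ceff[13], 99.9)
  expect_lt(abs(ceff[13] - 100), 1)
})

test_that("a later meal replaces the tracked meal; superposition sums", {
  meals <- data.frame(index = c(1L, 10L), value = c(100, 50))
  rep_mode <- effective_carbs(meals, 40)
  # after slot 10 only the 50 g meal drives the response
  expect_equal(rep_mode[17], (7 - 3) * 0.111 * 50)
  sup_mode <- effective_carbs(meals, 40, mode = "superpose")
  one <- effective_carbs(data.frame(index = 1L, value = 100), 40)
  two <- effective_carbs(data.frame(index = 10L, value = 50), 40)
  expect_equal(sup_mode, one + two)
  expect_error(effective_carbs(data.frame(index = 1L, value = -2), 10),
               "negative")
})

test_that("effective insulin decays linearly and clamps at zero", {
  bolus <- data.frame(index = 1L, value = 5)
  ieff <- effective_insulin(bolus, 80)
  expect_equal(ieff[1], 5)                    # zero elapsed
  expect_equal(ieff[11], 5 - 10 * 0.07)       # e = 10 -> 4.3 U
  expect_equal(ieff[73], 0)                   # 5 - 72*0.07 < 0 -> clamped
  expect_true(all(ieff >= 0))
  expect_error(effective_insulin(data.frame(index = 1L, value = -1), 10),
               "negative")
})

test_that("carb and insulin channels are exactly zero without events", {
  none <- data.frame(index = integer(0), value = numeric(0))
  expect_equal(effective_carbs(none, 25), rep(0, 25))
  expect_equal(effective_insulin(none, 25), rep(0, 25))
})

test_that("weighted step average matches its closed forms", {
  expect_equal(step_feature(rep(0, 30)), rep(0, 30))
  # constant steps s with full history: sum((10-i)/10) = 5.5
  s <- step_feature(rep(8, 30))
  expect_equal(s[10:30], rep(5.5 * 8, 21))
  # single impulse of 100: response 100, 90, ..., 10, 0
  x <- numeric(30); x[5] <- 100
  imp <- step_feature(x)
  expect_equal(imp[5:14], seq(100, 10, by = -10))
  expect_equal(imp[15], 0)
})

test_that("step feature is linear in its input", {
  set.seed(11)
  a <- rpois(40, 20); b <- rpois(40, 5)
  expect_equal(step_feature(3 * a + 2 * b),
               3 * step_feature(a) + 2 * step_feature(b))
})

test_that("window count equals brute-force enumeration", {
  L <- 24L; PH <- 6L
  # fully observed series of 40 slots
  s <- make_series(cgm = rep(100, 40) + sin(1:40))
  w <- build_windows(s, "raw", L = L, PH = PH)
  count_oracle <- function(g, L, PH) {
    sum(vapply((L):(length(g) - PH), function(t) {
      all(!is.na(g[(t - L + 1):t])) && !is.na(g[t + PH])
    }, logical(1)))
  }
  expect_equal(n_windows(w), count_oracle(s$cgm, L, PH))
  expect_equal(n_windows(w), 11L)
  expect_equal(w$index_map, 30:40)

  # random missingness patterns
  set.seed(21)
  for (rep in 1:5) {
    g <- rep(120, 120) + rnorm(120)
    g[sample.int(120, 25)] <- NA
    s <- make_series(cgm = g)
    expect_equal(n_windows(build_windows(s, "raw", L = L, PH = PH)),
                 count_oracle(g, L, PH))
  }
  # a gap inside every candidate history yields no windows
  g <- rep(100, 60); g[seq(1, 60, by = 10)] <- NA
  expect_equal(n_windows(build_windows(make_series(cgm = g), "raw",
                                       L = L, PH = PH)), 0L)
})

test_that("targets stay in mg/dl and the training scaler is reused", {
  set.seed(3)
  s <- make_series(cgm = 120 + cumsum(rnorm(80)),
                   meal = data.frame(index = 10L, value = 50),
                   bolus = data.frame(index = 10L, value = 5),
                   steps = rpois(80, 10))
  w_train <- build_windows(s, "raw", L = 12L, PH = 6L)
  expect_equal(w_train$targets, s$cgm[w_train$index_map])  # unscaled
  # test windows built with the training scaler inherit it verbatim
  s2 <- make_series(cgm = 130 + cumsum(rnorm(80)))
  w_test <- build_windows(s2, "raw", L = 12L, PH = 6L,
                          scaler = w_train$scaler)
  expect_identical(w_test$scaler, w_train$scaler)
  expect_equal(w_test$targets, s2$cgm[w_test$index_map])
  # the glucose channel of the inputs is standardised with the train scaler
  t_last <- w_test$index_map[1] - 6L
  expect_equal(w_test$inputs[1, 12, 1],
               (s2$cgm[t_last] - w_train$scaler$mean[1]) /
                 w_train$scaler$sd[1])
})

test_that("smoothed-channel windows require the smoothing result", {
  s <- make_series(cgm = rep(100, 40))
  expect_error(build_windows(s, "smoothed", L = 12L, PH = 6L),
               "requires a smooth_cgm")
  sm <- smooth_cgm(s)
  w <- build_windows(s, "smoothed", L = 12L, PH = 6L, smoothed = sm)
  expect_equal(w$targets, sm$mean[w$index_map])
  expect_error(build_windows(s, "raw", L = 0L, PH = 6L), ">= 1")
})
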