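# a small, quickly learnable dataset: smooth quasi-periodic glucose
learnable_windows <- function(n = 200, L = 12L, PH = 6L, seed = 1) {
  set.seed(seed)
  g <- 120 + 25 * sin(seq_len(n) / 10) + cumsum(rnorm(n, sd = 0.3))
  s <- make_series(cgm = g, steps = rpois(n, 10))
  build_windows(s, "raw", L = L, PH = PH)
}

test_that("weight initialisation is deterministic and shape-checked", {
  cfg <- tiny_config()
  a <- build_model(cfg, L = 12L)
  b <- build_model(cfg, L = 12L)
  expect_identical(a$params, b$params)
  c2 <- build_model(model_config(hidden_units = 8L, dense_sizes = c(16L, 8L),
                                 seed = 8L), L = 12L)
  expect_false(identical(a$params$W1, c2$params$W1))
  # parameter count is a fixed function of the architecture
  np <- sum(vapply(a$params, length, numeric(1)))
  H <- 8; D1 <- 16; D2 <- 8
  expect_equal(np, (4 + H) * 4 * H + 4 * H + (2 * H) * 4 * H + 4 * H +
                 H * D1 + D1 + D1 * D2 + D2 + D2 * 2 + 2)
  # single-layer variant drops the second LSTM block
  single <- build_model(model_config(n_recurrent_layers = 1L,
                                     hidden_units = 8L,
                                     dense_sizes = c(16L, 8L)), L = 12L)
  expect_false("W2" %in% names(single$params))
})

test_that("training reduces validation loss and stops deterministically", {
  w <- learnable_windows()
  m <- build_model(tiny_config(), L = 12L)
  tr1 <- train_model(m, w)
  tr2 <- train_model(m, w)
  expect_identical(tr1$training_log, tr2$training_log)   # bit determinism
  expect_identical(tr1$params, tr2$params)
  log <- tr1$training_log
  expect_lt(log$val_nll[nrow(log)], log$val_nll[1])      # it learns
  # early-stopping contract: reported best is the minimum achieved
  expect_equal(tr1$best_epoch, which.min(log$val_nll))
  expect_equal(tr1$best_val_nll, min(log$val_nll))
})

test_that("returned parameters are those of the best validation epoch", {
  w <- learnable_windows()
  tr <- train_model(build_model(tiny_config(), L = 12L), w)
  # recompute the validation NLL of the returned weights from a fresh
  # forward pass; must match the training loop's reported best
  n <- n_windows(w)
  va <- (floor(0.8 * n) + 1L):n
  nll <- cgmforecast:::forecast_nll(tr, w, va)
  expect_equal(nll, tr$best_val_nll, tolerance = 1e-6)
})

test_that("prediction is permutation-equivariant and inverse-scaled", {
  w <- learnable_windows()
  tr <- train_model(build_model(tiny_config(), L = 12L), w)
  p <- predict(tr, w)
  expect_true(all(is.finite(p$pred_mean)))
  expect_true(all(p$pred_sd > 0))
  # reorder the windows: outputs reorder identically
  perm <- rev(seq_len(n_windows(w)))
  wp <- w
  wp$inputs <- w$inputs[perm, , , drop = FALSE]
  wp$targets <- w$targets[perm]
  wp$index_map <- w$index_map[perm]
  wp$last_glucose <- w$last_glucose[perm]
  pp <- predict(tr, wp)
  expect_equal(pp$pred_mean, p$pred_mean[perm])
  expect_equal(pp$pred_sd, p$pred_sd[perm])
})

test_that("scaler and shape mismatches are refused", {
  w <- learnable_windows()
  tr <- train_model(build_model(tiny_config(), L = 12L), w)
  w_other <- learnable_windows(seed = 2)     # its own scaler
  expect_error(predict(tr, w_other), "training scaler")
  w24 <- learnable_windows(n = 120, L = 24L)
  expect_error(train_model(build_model(tiny_config(), L = 12L), w24),
               "L = 12")
  expect_error(predict(tr, w24), "scaler")
})

test_that("constant glucose is recovered within 2 mg/dl", {
  n <- 150
  s <- make_series(cgm = rep(120, n))
  w <- build_windows(s, "raw", L = 12L, PH = 6L)
  cfg <- tiny_config(max_epochs = 30L, patience = 30L)
  tr <- train_model(build_model(cfg, L = 12L), w)
  p <- predict(tr, w)
  expect_true(all(abs(p$pred_mean - 120) < 2))
})

test_that("the single-exponential head trains and yields positive sd", {
  w <- learnable_windows()
  cfg <- tiny_config(output_head = "single_exponential")
  tr <- train_model(build_model(cfg, L = 12L), w)
  p <- predict(tr, w)
  expect_true(all(p$pred_mean > 0))   # exponential activation
  expect_true(all(p$pred_sd > 0))
  expect_gt(length(unique(p$pred_mean)), 1)
  expect_equal(length(unique(round(p$pred_sd, 6))), 1)  # one global sd
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(n_recurrent_layers = 3L), "n_recurrent_layers")
  expect_error(model_config(patience = 10L, max_epochs = 5L), "patience")
  expect_error(model_config(dropout_rate = 1), "dropout_rate")
})
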