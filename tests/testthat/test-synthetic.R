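test_that("identical config and seed give bit-identical patients", {
  a <- generate_patient(sim_config(seed = 5, days = 2))
  b <- generate_patient(sim_config(seed = 5, days = 2))
  expect_identical(a, b)
  c <- generate_patient(sim_config(seed = 6, days = 2))
  expect_false(identical(a$cgm, c$cgm))
})

test_that("without inputs or noise the basal level is a fixed point", {
  cfg <- sim_config(seed = 1, days = 2, meals_per_day = c(0L, 0L),
                    process_noise_sd = 0, activity_gain = 0,
                    sensor_noise_sd = 0,
                    fault_spec = fault_spec(dropout_rate = 0, spike_rate = 0,
                                            pisa_rate = 0))
  s <- generate_patient(cfg)
  expect_equal(s$truth_bg, rep(120, s$n_index))
  expect_equal(s$cgm, rep(120, s$n_index))
  expect_equal(nrow(s$meal), 0L)
})

test_that("truth follows the stated update rule (independent re-simulation)", {
  cfg <- sim_config(seed = 9, days = 2, process_noise_sd = 0,
                    fault_spec = fault_spec(dropout_rate = 0, spike_rate = 0,
                                            pisa_rate = 0))
  s <- generate_patient(cfg)
  ceff <- effective_carbs(s$meal, s$n_index)
  ieff <- effective_insulin(s$bolus, s$n_index)
  savg <- step_feature(s$steps)
  g <- numeric(s$n_index)
  g[1] <- 120
  for (k in seq_len(s$n_index - 1)) {
    g[k + 1] <- g[k] + 0.5 * ceff[k] - 3.0 * ieff[k] - 0.002 * savg[k] +
      0.05 * (120 - g[k])
    g[k + 1] <- min(400, max(40, g[k + 1]))
  }
  expect_equal(s$truth_bg, g, tolerance = 1e-12)
})

test_that("a meal raises glucose which then relaxes toward basal", {
  cfg <- sim_config(seed = 2, days = 1, meals_per_day = c(1L, 1L),
                    carbs_per_meal = c(60, 60), insulin_to_carb_ratio = 0,
                    process_noise_sd = 0, activity_gain = 0,
                    fault_spec = fault_spec(dropout_rate = 0, spike_rate = 0,
                                            pisa_rate = 0))
  s <- generate_patient(cfg)
  t_meal <- s$meal$index[1]
  post <- s$truth_bg[t_meal:min(t_meal + 36L, s$n_index)]
  expect_gt(max(post), 120)                      # rises above basal
  expect_lt(s$truth_bg[s$n_index], max(post))    # and comes back down
})

test_that("fault injection is a no-op at zero rates and targeted otherwise", {
  base <- generate_patient(sim_config(
    seed = 3, days = 1,
    fault_spec = fault_spec(dropout_rate = 0, spike_rate = 0,
                            pisa_rate = 0)))
  same <- inject_faults(base, fault_spec(dropout_rate = 0, spike_rate = 0,
                                         pisa_rate = 0), seed = 1)
  expect_equal(same$cgm, base$cgm)

  flat <- make_series(cgm = rep(100, 40), truth_bg = rep(100, 40))
  forced <- inject_faults(flat, fault_spec(), events = data.frame(
    type = c("dropout", "pisa"), start = c(11L, 21L), length = c(5L, 5L),
    param = c(NA, 0.3)))
  expect_true(all(is.na(forced$cgm[11:15])))
  expect_equal(forced$cgm[21:25], rep(70, 5))     # 100 * (1 - 0.3)
  expect_equal(forced$cgm[c(1:10, 16:20, 26:40)],
               flat$cgm[c(1:10, 16:20, 26:40)])
  # ground truth and the other channels are never touched
  expect_identical(forced$truth_bg, flat$truth_bg)
  expect_identical(forced$steps, flat$steps)
  log <- attr(forced, "fault_log")
  expect_equal(nrow(log), 2L)
})

test_that("sensor noise magnitude matches the configured sd", {
  cfg <- sim_config(seed = 17, days = 30,
                    fault_spec = fault_spec(dropout_rate = 0, spike_rate = 0,
                                            pisa_rate = 0))
  s <- generate_patient(cfg)
  lagged_truth <- c(s$truth_bg[1], s$truth_bg[-s$n_index])
  resid <- s$cgm - lagged_truth
  expect_lt(abs(sd(resid) - 5) / 5, 0.2)
})

test_that("fault counts match configured rates over many seeds", {
  base <- generate_patient(sim_config(
    seed = 23, days = 10,
    fault_spec = fault_spec(dropout_rate = 0, spike_rate = 0,
                            pisa_rate = 0)))
  spec <- fault_spec()  # 1, 2, 1 events/day
  counts <- t(vapply(1:20, function(sd) {
    log <- attr(inject_faults(base, spec, seed = sd), "fault_log")
    c(dropout = sum(log$type == "dropout"),
      spike = sum(log$type == "spike"),
      pisa = sum(log$type == "pisa"))
  }, numeric(3)))
  # Poisson totals over 20 seeds x 10 days: mean rate*200, sd sqrt(mean)
  for (nm in colnames(counts)) {
    expected <- c(dropout = 1, spike = 2, pisa = 1)[[nm]] * 200
    expect_lt(abs(sum(counts[, nm]) - expected), 4 * sqrt(expected))
  }
})
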