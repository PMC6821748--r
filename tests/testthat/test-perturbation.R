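test_that("alpha kernel normalization and superposition", {
  k <- perturbation_kernel("alpha", tau = 7, triggers = c(100, 107))
  # isolated kernel peaks at 1 one time constant after its trigger
  k1 <- perturbation_kernel("alpha", tau = 7, triggers = 100)
  expect_equal(mu1_kernel(107, k1), 1)
  # causality
  expect_equal(mu1_kernel(99.9, k), 0)
  # two events tau apart: value at the second peak is 1 + 2 exp(-1)
  expect_equal(mu1_kernel(114, k), 1 + 2 * exp(-1), tolerance = 1e-12)
  # gridded series agrees with pointwise evaluation
  tt <- seq(0, 200, by = 0.1)
  ser <- spikefit:::.mu1_alpha_series(c(100, 107), length(tt), 0.1, 7)
  expect_equal(ser, mu1_kernel(tt, k), tolerance = 1e-6)
})

test_that("perturbation strength and shape are recovered (both methods)", {
  np <- default_params()
  dur <- 1e5; dt <- 0.01
  trig <- generate_trigger_times(dur, 200, 50, seed = 60)
  mu1 <- spikefit:::.mu1_alpha_series(trig, ceiling(dur / dt), dt, 10)
  sdat <- simulate_neuron(np, input_model(1.75, 2.5), dur, dt = dt,
                          seed = 61, mu_series = 1.75 + 0.5 * mu1)
  tr <- sdat$trains[[1]]
  bg <- list(mu0 = 1.75, sigma = 2.5)
  f2 <- fit_perturbation(tr, trig, "alpha", "rate_model", np,
                         background = bg)
  expect_equal(f2$estimates$J, 0.5, tolerance = 0.3)
  expect_equal(f2$estimates$tau, 10, tolerance = 0.3)
  f1 <- fit_perturbation(tr, trig, "alpha", "fp_perturbative", np,
                         background = bg)
  expect_equal(sign(f1$estimates$J), 1)
  expect_equal(f1$estimates$tau, 10, tolerance = 0.5)
  expect_gt(f1$loglik_gain, 5)
})

test_that("delta-pulse perturbations recover strength, delay and sign", {
  np <- default_params()
  dur <- 2e5; dt <- 0.01; d_true <- 1.5
  trig <- generate_trigger_times(dur, 40, 10, seed = 62)
  n <- ceiling(dur / dt)
  idx <- round((trig + d_true) / dt)
  mu1 <- tabulate(idx[idx >= 1 & idx <= n], nbins = n) / dt
  bg <- list(mu0 = 1.75, sigma = 2.5)
  for (J in c(0.6, -0.6)) {
    sdat <- simulate_neuron(np, input_model(1.75, 2.5), dur, dt = dt,
                            seed = 63 + round(J), mu_series = 1.75 + J * mu1)
    f <- fit_perturbation(sdat$trains[[1]], trig, "delta",
                          "fp_perturbative", np, background = bg)
    # the first-order expansion inflates |J| at this strength (documented
    # behavior of the weak-coupling approximation); sign, rough magnitude
    # and the delay are recovered
    expect_equal(f$estimates$J, J, tolerance = 0.5)
    expect_equal(f$estimates$d, d_true, tolerance = 0.4)
    expect_gt(f$loglik_gain, 30)
  }
})

test_that("null data yield small estimated strengths", {
  np <- default_params()
  dur <- 2e5
  sdat <- simulate_neuron(np, input_model(1.75, 2.5), dur, dt = 0.01,
                          seed = 64)
  trig <- generate_trigger_times(dur, 40, 10, seed = 65)
  f <- fit_perturbation(sdat$trains[[1]], trig, "delta",
                        "fp_perturbative", np,
                        background = list(mu0 = 1.75, sigma = 2.5))
  # the delay search maximizes over ~100 candidate delays, so the null
  # estimate is selection-inflated but carries little likelihood gain
  expect_lt(abs(f$estimates$J), 0.45)
  expect_lt(f$loglik_gain, 12)
})

test_that("trigger-aligned CCG is normalized and detects strong input", {
  np <- default_params()
  dur <- 1e5; dt <- 0.01
  trig <- generate_trigger_times(dur, 200, 50, seed = 66)
  mu1 <- spikefit:::.mu1_alpha_series(trig, ceiling(dur / dt), dt, 10)
  sdat <- simulate_neuron(np, input_model(1.75, 2.5), dur, dt = dt,
                          seed = 67, mu_series = 1.75 + 1.5 * mu1)
  cc <- trigger_ccg(sdat$trains[[1]], trig, n_null = 50, seed = 1)
  lag_step <- cc$lags[2] - cc$lags[1]
  expect_equal(sum(cc$curve) * lag_step, 1, tolerance = 1e-6)
  expect_true(cc$significant)
  expect_gt(cc$z, 2)
  expect_true(cc$extremum_lag >= 0 && cc$extremum_lag <= 50)
  # independent triggers: mostly insignificant
  sd0 <- simulate_neuron(np, input_model(1.75, 2.5), dur, dt = dt,
                         seed = 68)
  cc0 <- trigger_ccg(sd0$trains[[1]], trig, n_null = 50, seed = 2)
  expect_lt(abs(cc0$z), 3)
})

test_that("detection time is finite for strong coupling and identifies misses", {
  np <- default_params()
  dur <- 1.2e5; dt <- 0.01; d_true <- 1.5
  trig <- generate_trigger_times(dur, 40, 10, seed = 69)
  n <- ceiling(dur / dt)
  idx <- round((trig + d_true) / dt)
  mu1 <- tabulate(idx[idx >= 1 & idx <= n], nbins = n) / dt
  sdat <- simulate_neuron(np, input_model(1.75, 2.5), dur, dt = dt,
                          seed = 70, mu_series = 1.75 + 0.8 * mu1)
  dtec <- detection_time(sdat$trains[[1]], trig, "delta",
                         "fp_perturbative", np, folds = 4,
                         segment_grid = c(6e4, 1.2e5))
  expect_false(is.na(dtec$detection_time))
  # uncoupled data: likelihood ratio should not favor coupling
  sd0 <- simulate_neuron(np, input_model(1.75, 2.5), dur, dt = dt,
                         seed = 71)
  dtec0 <- detection_time(sd0$trains[[1]], trig, "delta",
                          "fp_perturbative", np, folds = 4,
                          segment_grid = c(1.2e5))
  expect_true(is.na(dtec0$detection_time) ||
                max(dtec0$llr$llr, na.rm = TRUE) <
                  max(dtec$llr$llr, na.rm = TRUE))
})
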