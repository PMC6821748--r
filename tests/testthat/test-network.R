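# shared small network fixture: 4 neurons, strong mixed couplings,
# 2.5 minutes
net_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      J <- matrix(0, 4, 4)
      J[1, 2] <- 0.7; J[3, 1] <- -0.7; J[2, 4] <- 0.5
      net <- network_params(J, d = 1, mu = 1.75, sigma = 2.5)
      data <- simulate_network(net, 1.2e5, dt = 0.01, seed = 80)
      fit <- infer_network(data)
      fit_bc <- bias_correct(fit, n_rep = 1, seed = 81)
      cache <<- list(net = net, data = data, fit = fit, fit_bc = fit_bc)
    }
    cache
  }
})

test_that("per-neuron background fits absorb the coupling input", {
  fx <- net_fixture()
  bgs <- fit_backgrounds(fx$data)
  mus <- vapply(bgs, function(b) b$mu, numeric(1))
  sigs <- vapply(bgs, function(b) b$sigma, numeric(1))
  expect_true(all(abs(mus - 1.75) < 0.3))
  expect_true(all(abs(sigs - 2.5) < 0.4))
})

test_that("network inference recovers strong couplings, delays and nulls", {
  fx <- net_fixture()
  fit <- fx$fit_bc
  expect_gt(fit$J[1, 2], 0.3)
  expect_lt(fit$J[3, 1], -0.2)
  expect_gt(fit$J[2, 4], 0.15)
  expect_lt(abs(fit$d[1, 2] - 1), 0.7)
  off <- row(fit$J) != col(fit$J)
  truth0 <- fx$net$J[off] == 0
  expect_lt(mean(abs(fit$J[off][truth0])), 0.3)
  # relabeling invariance: swapping two neurons permutes the estimates
  perm <- c(2, 1, 3, 4)
  data_p <- spike_data(fx$data$trains[perm], t_span = fx$data$t_span)
  fit_p <- infer_network(data_p,
                         backgrounds = fit$backgrounds[perm])
  expect_equal(fit_p$J[2, 1], fit$J_raw[1, 2], tolerance = 1e-6)
})

test_that("detection metrics separate true from absent connections", {
  fx <- net_fixture()
  met <- detection_metrics(fx$fit_bc$J, fx$net$J)
  expect_gt(met$max_bacc, 0.8)
  # sweeping the threshold down can only add detections
  ord <- order(-met$roc$threshold)
  expect_true(all(diff(met$roc$tpr[ord]) >= -1e-9))
  expect_true(all(diff(met$roc$fpr[ord]) >= -1e-9))
  # arithmetic identities from the definitions
  expect_equal(met$roc$acc, (met$roc$tpr * 3 + (1 - met$roc$fpr) * 9) / 12)
  # perfect scores give BACC 1; random guessing stays near the diagonal
  perfect <- abs(fx$net$J) + 0
  expect_equal(detection_metrics(perfect, fx$net$J)$max_bacc, 1)
})

test_that("CCG z-score baseline flags the strong connections with correct sign", {
  fx <- net_fixture()
  z <- ccg_zscore_baseline(fx$data, n_rep = 40, seed = 83)
  expect_gt(z[1, 2], 2)
  expect_lt(z[3, 1], -2)
  off <- row(z) != col(z)
  null_z <- z[off][fx$net$J[off] == 0]
  expect_lt(mean(abs(null_z) > 2.6), 0.3)
})

test_that("coupling z-scores separate connected from unconnected pairs", {
  fx <- net_fixture()
  z <- coupling_zscores(fx$fit, jitter = 5, n_rep = 8, seed = 84)
  expect_gt(abs(z[1, 2]), abs(z[4, 3]))
  expect_gt(abs(z[1, 2]), 1)
})

test_that("time-varying background tracking follows a slow modulation", {
  np <- default_params()
  dur <- 1.2e5; dt <- 0.02
  tt <- seq_len(ceiling(dur / dt)) * dt
  mu_t <- 1.75 + 0.6 * sin(2 * pi * tt / 3e4)   # 30 s period
  sdat <- simulate_neuron(np, input_model(1.75, 2.5), dur, dt = dt,
                          seed = 85, mu_series = mu_t)
  data <- spike_data(sdat$trains, t_span = c(0, dur))
  bg <- fit_backgrounds(data, mode = "time_varying", sigma_G = 1)[[1]]
  tr <- data$trains[[1]]
  centers <- (tr[-1] + tr[-length(tr)]) / 2
  mu_true <- 1.75 + 0.6 * sin(2 * pi * centers / 3e4)
  expect_gt(stats::cor(bg$mu, mu_true), 0.8)
  expect_equal(bg$sigma, 2.5, tolerance = 0.2)
  # constant-rate neuron: time-varying mode agrees with the constant fit
  sd0 <- simulate_neuron(np, input_model(1.75, 2.5), 6e4, dt = 0.02,
                         seed = 86)
  d0 <- spike_data(sd0$trains, t_span = c(0, 6e4))
  bg_tv <- fit_backgrounds(d0, mode = "time_varying", sigma_G = 1)[[1]]
  bg_c <- fit_backgrounds(d0)[[1]]
  expect_lt(stats::sd(bg_tv$mu), 0.15)
  expect_equal(mean(bg_tv$mu), bg_c$mu, tolerance = 0.15)
})
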