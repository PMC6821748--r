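test_that("noise-free leaky integration reproduces the closed-form ISI", {
  np <- default_params()
  sd <- simulate_neuron(np, input_model(1.75, 1e-8), duration = 500,
                        dt = 0.001, seed = 1)
  isis <- diff(sd$trains[[1]])
  expect_equal(mean(isis), noise_free_isi(1.75), tolerance = 1e-3)
  # subthreshold drive never fires
  sd0 <- simulate_neuron(np, input_model(1.4, 1e-8), duration = 2000,
                         dt = 0.01, seed = 2)
  expect_length(sd0$trains[[1]], 0)
})

test_that("simulations are reproducible under a fixed seed", {
  np <- default_params()
  a <- simulate_neuron(np, input_model(1.75, 2.5), 5000, seed = 7)
  b <- simulate_neuron(np, input_model(1.75, 2.5), 5000, seed = 7)
  expect_identical(a$trains, b$trains)
  c <- simulate_neuron(np, input_model(1.75, 2.5), 5000, seed = 8)
  expect_false(identical(a$trains, c$trains))
})

test_that("long-run simulated rate matches the Fokker-Planck steady state", {
  np <- default_params()
  sd <- simulate_neuron(np, input_model(1.75, 2.5), duration = 2e5,
                        dt = 0.005, seed = 3)
  r_sim <- length(sd$trains[[1]]) / 2e5
  r_fp <- steady_state(np, 1.75, 2.5)$r_inf
  expect_equal(r_sim, r_fp, tolerance = 0.03)
})

test_that("adaptation disabled reproduces the plain trajectory; traces decay", {
  np <- default_params()
  plain <- simulate_neuron(np, input_model(1.75, 2.5), 20000, seed = 5)
  ad0 <- simulate_adaptive_neuron(np, adaptation_params(0, 100),
                                  input_model(1.75, 2.5), 20000, seed = 5)
  expect_identical(plain$trains, ad0$trains)
  # single-exponential decay between spikes
  ad <- simulate_adaptive_neuron(np, adaptation_params(0.5, 80),
                                 input_model(1.75, 2.5), 5000, seed = 6,
                                 keep_adaptation = TRUE)
  tr <- ad$trains[[1]]
  w <- attr(ad, "adaptation")
  k <- 3
  seg <- w$time_ms > tr[k] + 1 & w$time_ms < tr[k + 1] - 1
  lw <- log(w$w[seg])
  fit <- stats::lm(lw ~ w$time_ms[seg])
  expect_equal(unname(-1 / coef(fit)[2]), 80, tolerance = 0.01)
})

test_that("step increase of mean input gives rapid rise then adaptation decline", {
  np <- default_params()
  n_steps <- 8e5
  mu_series <- c(rep(1.2, 2e5), rep(2.6, 6e5))   # step at 2 s, dt 0.01
  ad <- simulate_adaptive_neuron(np, adaptation_params(0.5, 150),
                                 input_model(1.2, 0.8), duration = 8000,
                                 dt = 0.01, seed = 9,
                                 mu_series = mu_series)
  tr <- ad$trains[[1]]
  early <- sum(tr > 2000 & tr <= 2500) / 0.5   # spikes/s
  late <- sum(tr > 6500 & tr <= 7999) / 1.5
  expect_gt(early, late * 1.2)
})

test_that("OU current matches its stationary moments and correlation time", {
  ou <- ou_params(mu_I = 100, sigma_I = 30, tau_I = 3)
  x <- generate_ou_current(ou, duration = 2e5, dt = 0.05, seed = 4)$I
  expect_equal(mean(x), 100, tolerance = 0.01)
  expect_equal(stats::sd(x), 30, tolerance = 0.02)
  ac <- stats::acf(x, lag.max = 100, plot = FALSE)$acf[, 1, 1]
  lags_ms <- (seq_along(ac) - 1) * 0.05
  keep <- ac > 0.05 & lags_ms > 0
  tau_hat <- -1 / stats::lm(log(ac[keep]) ~ lags_ms[keep])$coefficients[2]
  expect_equal(unname(tau_hat), 3, tolerance = 0.05)
})

test_that("trigger gaps follow the truncated Gaussian design", {
  tt <- generate_trigger_times(2e5, 200, 50, seed = 10)
  gaps <- diff(tt)
  expect_equal(mean(gaps), 200, tolerance = 0.03)
  expect_equal(stats::sd(gaps), 50, tolerance = 0.1)
  expect_true(all(gaps >= 1))
  # sd 0 gives periodic events; count ~ duration / gap
  tp <- generate_trigger_times(1e4, 100, 0, seed = 11)
  expect_equal(diff(tp), rep(100, length(tp) - 1), tolerance = 1e-10)
  expect_equal(length(tt), 1000, tolerance = 0.1)
})

test_that("random networks respect the sampling scheme", {
  net <- sample_random_network(40, p_exc = 0.3, seed = 12)
  off <- row(net$J) != col(net$J)
  dens <- mean(net$J[off] != 0)
  expect_equal(dens, 0.3, tolerance = 0.2)
  expect_true(all(diag(net$J) == 0))
  w <- net$J[net$J != 0]
  expect_true(all(w >= -0.75 & w <= 0.75))
  expect_gt(suppressWarnings(stats::ks.test(w, "punif", -0.75, 0.75))$p.value,
            0.01)
  # Dale-consistent E/I variant
  ei <- sample_random_network(30, p_exc = 0.2, p_inh = 0.4,
                              strength_spec = list(kind = "ei",
                                                   mean_exc = 1,
                                                   mean_inh = -1,
                                                   n_exc = 20),
                              seed = 13)
  expect_true(all(ei$J[, 1:20] >= 0))
  expect_true(all(ei$J[, 21:30] <= 0))
  # empty network
  z <- sample_random_network(5, p_exc = 0, seed = 14)
  expect_true(all(z$J == 0))
})

test_that("decoupled network neurons match isolated-neuron ISI statistics", {
  np <- default_params()
  net <- network_params(matrix(0, 3, 3), d = 1, mu = 1.75, sigma = 2.5,
                       c = 0, params = np)
  data <- simulate_network(net, 6e4, dt = 0.01, seed = 15)
  iso <- simulate_neuron(np, input_model(1.75, 2.5), 6e4, dt = 0.01,
                         seed = 16)
  pooled <- unlist(lapply(data$trains, diff))
  ks <- suppressWarnings(stats::ks.test(pooled, diff(iso$trains[[1]])))
  expect_gt(ks$p.value, 0.01)
})

test_that("shared external drive correlates network input as specified", {
  # with strong c, spike counts in small bins correlate; with c = 0 not
  np <- default_params()
  net_c <- network_params(matrix(0, 2, 2), d = 1, mu = 1.75, sigma = 2.5,
                          c = 0.5, params = np)
  data <- simulate_network(net_c, 2e5, dt = 0.01, seed = 17)
  bins <- seq(0, 2e5, by = 20)
  n1 <- tabulate(findInterval(data$trains[[1]], bins), length(bins))
  n2 <- tabulate(findInterval(data$trains[[2]], bins), length(bins))
  expect_gt(stats::cor(n1, n2), 0.1)
})

test_that("halving the integration step changes long-run counts weakly", {
  np <- default_params()
  a <- simulate_neuron(np, input_model(1.75, 2.5), 1e5, dt = 0.02,
                       seed = 18)
  b <- simulate_neuron(np, input_model(1.75, 2.5), 1e5, dt = 0.01,
                       seed = 18)
  ka <- length(a$trains[[1]]); kb <- length(b$trains[[1]])
  expect_lt(abs(ka - kb) / kb, 0.02)
})
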