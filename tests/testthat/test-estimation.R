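test_that("renewal log-likelihood equals the sum of log densities", {
  np <- default_params()
  isis <- c(25, 32, 40.5, 28, 55)
  g <- fp_grid(s_max = 80, dt = 0.05)
  d <- solve_isi_density(np, 1.75, 2.5, g)
  by_hand <- sum(log(stats::approx(d$s, d$density, isis)$y))
  ll <- spike_train_loglik(isis_as_sample(isis),
                           list(mu = 1.75, sigma = 2.5),
                           fit_spec("fp_full"), np, g)
  expect_equal(ll, by_hand, tolerance = 1e-10)
})

test_that("likelihood surface peaks near the truth for 400 spikes", {
  np <- default_params()
  sd <- simulate_neuron(np, input_model(1.75, 2.5), 60000, dt = 0.005,
                        seed = 50, n_spikes = 400)
  isis <- diff(sd$trains[[1]])
  g <- fp_grid(s_max = max(isis) * 1.02 + 1)
  spec <- fit_spec("fp_full")
  mus <- seq(1.45, 2.05, by = 0.1)
  sigs <- seq(2.0, 3.0, by = 0.125)
  surf <- outer(mus, sigs, Vectorize(function(m, s)
    spike_train_loglik(isis_as_sample(isis), list(mu = m, sigma = s),
                       spec, np, g)))
  peak <- which(surf == max(surf), arr.ind = TRUE)
  expect_lt(abs(mus[peak[1]] - 1.75), 0.15)
  expect_lt(abs(sigs[peak[2]] - 2.5), 0.3)
})

test_that("background fit recovers the input statistics", {
  np <- default_params()
  sd <- simulate_neuron(np, input_model(1.75, 2.5), 2e5, dt = 0.005,
                        seed = 51, n_spikes = 2000)
  f <- fit_background(sd$trains[[1]], np)
  expect_equal(f$estimates$mu, 1.75, tolerance = 0.05)
  expect_equal(f$estimates$sigma, 2.5, tolerance = 0.05)
  expect_equal(f$aic, 2 * 2 - 2 * f$loglik)
})

test_that("voltage-offset symmetry leaves the maximized likelihood invariant", {
  np1 <- default_params()
  np2 <- neuron_params(V_s = 40, V_r = 10, tau_m = 20)
  sd <- simulate_neuron(np1, input_model(1.75, 2.5), 6e4, dt = 0.01,
                        seed = 52, n_spikes = 300)
  tr <- sd$trains[[1]]
  f1 <- fit_background(tr, np1)
  f2 <- fit_background(tr, np2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-3)
  expect_equal(f2$estimates$mu - f1$estimates$mu, 10 / 20,
               tolerance = 0.02)
})

test_that("censoring applies the percentile window and minimum length", {
  set.seed(53)
  isis <- c(stats::rexp(100, 1 / 30) + 1, 2, 3, 250, 400)
  out <- censor_isis(c(0, cumsum(isis)), central = 0.9, min_isi = 5)
  expect_true(all(out > 5))
  qs <- stats::quantile(isis, c(0.05, 0.95))
  expect_true(all(out >= qs[1] & out <= qs[2]))
  expect_lte(length(out), 0.9 * length(isis) + 1)
  # identity policy
  idp <- censor_isis(c(0, cumsum(isis)), central = 1, min_isi = 0)
  expect_equal(as.numeric(idp), isis)
})

test_that("AIC comparison prefers the generating model", {
  np <- default_params()
  sd <- simulate_neuron(np, input_model(1.75, 2.5), 6e4, dt = 0.01,
                        seed = 54, n_spikes = 400)
  tr <- sd$trains[[1]]
  f_if <- fit_background(tr, np)
  f_po <- fit_poisson_baseline(tr)
  cmp <- aic_compare(list(iaf = f_if, poisson = f_po))
  expect_equal(cmp$model[1], "iaf")
  expect_gt(cmp$delta_aic[2], 10)
  # arithmetic: N_theta = 2, loglik = -100 -> AIC = 204
  fake <- structure(list(estimates = list(), loglik = -100, n_isi = 10,
                         aic = 2 * 2 - 2 * (-100)), class = "fit_result")
  expect_equal(fake$aic, 204)
})

test_that("Fisher information is symmetric and orders mu vs sigma correctly", {
  np <- default_params()
  info <- fisher_information(list(mu = 1.75, sigma = 2.5), np)
  expect_equal(info$matrix, t(info$matrix), tolerance = 1e-6)
  ev <- eigen(info$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  b <- crb_sd(info, K = 400)
  # the bound for mu is smaller than for sigma at the default setting
  expect_lt(b["mu"], b["sigma"])
})

test_that("adaptive likelihood reduces exactly to renewal when Delta_w = 0", {
  np <- default_params()
  sd <- simulate_neuron(np, input_model(1.75, 2.5), 3e4, dt = 0.01,
                        seed = 55, n_spikes = 150)
  tr <- sd$trains[[1]]
  g <- fp_grid(s_max = max(diff(tr)) * 1.02 + 1, dt = 0.05)
  ll_ad <- adaptive_loglik(tr, list(mu = 1.75, sigma = 2.5, Delta_w = 0,
                                    tau_w = 100), np, g)
  ll_re <- spike_train_loglik(isis_as_sample(diff(tr)),
                              list(mu = 1.75, sigma = 2.5),
                              fit_spec("fp_full"), np, g)
  expect_equal(ll_ad, ll_re, tolerance = 1e-10)
})
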