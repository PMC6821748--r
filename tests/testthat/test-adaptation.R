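test_that("adaptation reconstruction from spikes is exact", {
  ad <- adaptation_params(0.3, 120)
  tr <- toy_train()
  traj <- adaptation_trajectory(tr, ad)
  # single prior spike, one time constant later: e^-1 per unit increment
  tr2 <- c(0, 120)
  expect_equal(adaptation_trajectory(tr2, ad)$mu1[1], 1)
  expect_equal(adaptation_trajectory(tr2, ad)$w_of(120 - 1e-9) / ad$Delta_w,
               exp(-1), tolerance = 1e-6)
  # two prior spikes at equal gaps g: mu1 at the next spike
  g <- 35
  tr3 <- c(0, g, 2 * g)
  m <- adaptation_trajectory(tr3, ad)$mu1
  expect_equal(m[2], exp(-g / 120) + 1)
  expect_equal(adaptation_trajectory(tr3, ad)$w_of(2 * g - 1e-9) / ad$Delta_w,
               exp(-2 * g / 120) + exp(-g / 120), tolerance = 1e-6)
  # against the simulator trace, given the true parameters
  np <- default_params()
  sd <- simulate_adaptive_neuron(np, ad, input_model(1.75, 2.5), 2e4,
                                 dt = 0.01, seed = 90,
                                 keep_adaptation = TRUE)
  trs <- sd$trains[[1]]
  w_tr <- attr(sd, "adaptation")
  rec <- adaptation_trajectory(trs, ad)
  at <- trs[5:10] + 3   # 3 ms after spikes 5..10
  w_sim <- stats::approx(w_tr$time_ms, w_tr$w, xout = at)$y
  expect_equal(rec$w_of(at), w_sim, tolerance = 0.01)
})

test_that("w0-conditioned table likelihood matches per-ISI direct solves", {
  np <- default_params()
  ad <- adaptation_params(0.4, 100)
  sd <- simulate_adaptive_neuron(np, ad, input_model(1.75, 2.5), 1e5,
                                 dt = 0.01, seed = 91, n_spikes = 60)
  tr <- sd$trains[[1]]
  g <- fp_grid(s_max = max(diff(tr)) * 1.02 + 1, dt = 0.05)
  th <- list(mu = 1.75, sigma = 2.5, Delta_w = 0.4, tau_w = 100)
  ll_tab <- adaptive_loglik(tr, th, np, g, n_w0 = 10)
  # direct: one Fokker-Planck solve per ISI with its own w0
  w0 <- adaptation_trajectory(tr, ad)$w0
  isis <- diff(tr)
  ll_dir <- sum(vapply(seq_along(isis), function(k) {
    mu_s <- function(s) 1.75 - w0[k] * exp(-s / 100)
    d <- solve_isi_density(np, mu_s, 2.5, g)
    log(max(spikefit:::.interp_density(d$s, d$density, isis[k]), 1e-12))
  }, numeric(1)))
  expect_equal(ll_tab, ll_dir, tolerance = 1e-3)
})

test_that("adaptation surface peaks near truth and joint fit recovers it", {
  np <- default_params()
  ad <- adaptation_params(0.4, 100)
  sd <- simulate_adaptive_neuron(np, ad, input_model(1.75, 2.5), 1e6,
                                 dt = 0.01, seed = 92, n_spikes = 1000)
  tr <- sd$trains[[1]]
  g <- fp_grid(s_max = max(diff(tr)) * 1.02 + 1, dt = 0.1, n_V = 200)
  # profile over Delta_w at the true remaining parameters
  dws <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  lls <- vapply(dws, function(dw)
    adaptive_loglik(tr, list(mu = 1.75, sigma = 2.5, Delta_w = dw,
                             tau_w = 100), np, g), numeric(1))
  expect_equal(dws[which.max(lls)], 0.4, tolerance = 0.11)
  f <- fit_adaptive(tr, np, grid = g)
  expect_equal(f$estimates$Delta_w, 0.4, tolerance = 0.35)
  expect_equal(f$estimates$tau_w, 100, tolerance = 35)
  expect_equal(f$estimates$mu, 1.75, tolerance = 0.25)
})

test_that("AIC prefers the adaptive model only when adaptation is present", {
  np <- default_params()
  ad <- adaptation_params(0.4, 100)
  sda <- simulate_adaptive_neuron(np, ad, input_model(1.75, 2.5), 5e5,
                                  dt = 0.01, seed = 93, n_spikes = 400)
  tra <- sda$trains[[1]]
  fa <- fit_adaptive(tra, np)
  fr <- fit_background(tra, np)
  cmp <- aic_compare(list(adaptive = fa, renewal = fr))
  expect_equal(cmp$model[1], "adaptive")
  # non-adaptive data: Delta_w near zero and the renewal model preferred
  sd0 <- simulate_neuron(np, input_model(1.75, 2.5), 5e5, dt = 0.01,
                         seed = 94, n_spikes = 400)
  tr0 <- sd0$trains[[1]]
  fa0 <- fit_adaptive(tr0, np)
  fr0 <- fit_background(tr0, np)
  cmp0 <- aic_compare(list(adaptive = fa0, renewal = fr0))
  expect_lt(fa0$estimates$Delta_w * fa0$estimates$tau_w / mean(diff(tr0)),
            0.6)   # small mean adaptation level
  expect_lt(cmp0$aic[cmp0$model == "renewal"] -
              cmp0$aic[cmp0$model == "adaptive"], 4)
})
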