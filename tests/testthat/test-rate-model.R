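tabs_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_lnexp_tables(default_params(), 2.5,
                                   seq(-0.5, 4, by = 0.1))
    cache
  }
})

test_that("cascade tables are admissible and consistent with steady states", {
  tabs <- tabs_default()
  expect_true(all(tabs$r_inf_tab >= 0))
  expect_true(all(diff(tabs$r_inf_tab) > 0))    # monotone in mu
  expect_true(all(is.finite(tabs$tau_mu_tab) & tabs$tau_mu_tab > 0))
  r_tab <- tabs$r_inf_tab[match(1.8, round(tabs$mu_grid, 10))]
  expect_equal(r_tab, steady_state(default_params(), 1.8, 2.5)$r_inf,
               tolerance = 1e-3)
})

test_that("constant input is a fixed point of the rate ODE", {
  tabs <- tabs_default()
  tg <- seq(0, 500, by = 0.1)
  rt <- integrate_rate(tabs, rep(1.75, length(tg)), tg)
  expect_equal(diff(range(rt$r)), 0, tolerance = 1e-12)
  expect_equal(rt$r[1], stats::approx(tabs$mu_grid, tabs$r_inf_tab,
                                      1.75)$y, tolerance = 1e-6)
})

test_that("slow modulation is tracked adiabatically", {
  tabs <- tabs_default()
  tg <- seq(0, 4000, by = 0.1)
  mu_t <- 1.75 + 0.5 * sin(2 * pi * tg / 2000)   # period >> tau_mu
  rt <- integrate_rate(tabs, mu_t, tg)
  r_qs <- stats::approx(tabs$mu_grid, tabs$r_inf_tab, xout = mu_t)$y
  late <- tg > 500
  expect_lt(max(abs(rt$r[late] - r_qs[late])) / max(r_qs), 0.03)
})

test_that("step response of the reduced model approximates the full FP rate", {
  np <- default_params()
  tabs <- tabs_default()
  # full time-dependent FP solve as oracle
  sigma <- 2.5; mu0 <- 1.5; mu1 <- 2.2
  V_lb <- np$V_r - max(6 * sigma * sqrt(np$tau_m / 2), 40)
  n_V <- 256; fp_dt <- 0.05
  dV <- (np$V_s - V_lb) / n_V
  centers <- V_lb + (seq_len(n_V) - 0.5) * dV
  ss <- steady_state(np, mu0, sigma, n_V = n_V, V_lb = V_lb)
  p_init <- stats::approx(ss$V, ss$p_V, xout = centers, rule = 2)$y
  p_init <- p_init / (sum(p_init) * dV)
  settle <- spikefit:::fp_rate_cpp(mu0, sigma, np$V_s, np$V_r, np$tau_m,
                                   0L, 0, 0, V_lb, n_V, fp_dt, 6000L,
                                   p_init, 0, 0)
  n_resp <- 3000L
  resp <- spikefit:::fp_rate_cpp(mu1, sigma, np$V_s, np$V_r, np$tau_m,
                                 0L, 0, 0, V_lb, n_V, fp_dt, n_resp,
                                 as.numeric(settle$p_V), 0, 0)
  tg <- seq(0, n_resp * fp_dt, by = 0.1)
  rt <- integrate_rate(tabs, rep(mu1, length(tg)), tg,
                       mu_f_init = mu0)
  r_full <- stats::approx(seq_len(n_resp) * fp_dt, as.numeric(resp$rate),
                          xout = tg, rule = 2)$y
  # peak deviation of the reduced model within 15% of the full response
  expect_lt(max(abs(rt$r - r_full)) / max(r_full), 0.15)
})

test_that("Poisson log-likelihood reduces to the homogeneous closed form", {
  r0 <- 0.02   # 20 Hz in 1/ms
  tg <- seq(0, 10000, by = 0.5)
  rate <- list(t = tg, r = rep(r0, length(tg)))
  set.seed(40)
  tr <- cumsum(stats::rexp(100, r0))
  tr <- tr[tr < 9000]
  K <- length(tr)
  ll <- poisson_loglik(tr, rate)
  expect_equal(as.numeric(ll),
               (K - 1) * log(r0) - r0 * (tr[K] - tr[1]),
               tolerance = 1e-10)
  # doubling the rate shifts the log-likelihood by the closed-form amount
  rate2 <- list(t = tg, r = rep(2 * r0, length(tg)))
  ll2 <- poisson_loglik(tr, rate2)
  expect_equal(as.numeric(ll2 - ll),
               (K - 1) * log(2) - r0 * (tr[K] - tr[1]), tolerance = 1e-10)
})

test_that("rate-model likelihood surface peaks near the true parameters", {
  np <- default_params()
  sd <- simulate_neuron(np, input_model(1.75, 2.5), 60000, dt = 0.01,
                        seed = 41)
  tr <- sd$trains[[1]]
  tabs <- tabs_default()
  tg <- seq(0, 60000, by = 0.5)
  ll_of <- function(mu) {
    rt <- integrate_rate(tabs, rep(mu, length(tg)), tg)
    as.numeric(poisson_loglik(tr, rt))
  }
  mus <- seq(1.2, 2.4, by = 0.1)
  lls <- vapply(mus, ll_of, numeric(1))
  expect_equal(mus[which.max(lls)], 1.75, tolerance = 0.2)
})
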