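test_that("ISI density conserves probability and is nonnegative", {
  np <- default_params()
  g <- fp_grid(s_max = 400, dt = 0.05)
  d <- solve_isi_density(np, 1.75, 2.5, g)
  expect_true(all(d$density >= 0))
  mass <- sum(d$density) * g$dt + d$survival[length(d$survival)]
  expect_lt(abs(mass - 1), 1e-6)
  # near-total absorption for suprathreshold drift at a long horizon
  expect_lt(d$survival[length(d$survival)], 1e-3)
  # density starts at zero
  expect_lt(d$density[1], 1e-10)
})

test_that("small-noise ISI density concentrates at the deterministic ISI", {
  np <- default_params()
  d <- solve_isi_density(np, 1.75, 0.25,
                         fp_grid(s_max = 100, dt = 0.02, n_V = 512))
  expect_equal(mean(d), noise_free_isi(1.75), tolerance = 5e-3)
})

test_that("steady-state rate matches Siegert quadrature over a grid", {
  np <- default_params()
  for (mu in c(0.5, 1.25, 1.75, 2.5, 3)) {
    for (sigma in c(0.5, 1.5, 2.5, 4)) {
      r_fp <- steady_state(np, mu, sigma)$r_inf
      r_sg <- siegert_rate(mu, sigma)
      expect_equal(r_fp, r_sg, tolerance = 0.01,
                   label = sprintf("rate at mu=%g sigma=%g", mu, sigma))
    }
  }
  # subthreshold, vanishing noise: rate tends to zero
  expect_lt(steady_state(np, 0.5, 0.15)$r_inf, 1e-8)
})

test_that("stationary voltage density is normalized and vanishes at threshold", {
  np <- default_params()
  ss <- steady_state(np, 1.75, 2.5)
  h <- ss$V[2] - ss$V[1]
  expect_equal(sum(ss$p_V) * h, 1, tolerance = 1e-3)
  expect_equal(ss$p_V[length(ss$p_V)], 0)
  # agrees with the simulated voltage histogram
  sd <- simulate_neuron(np, input_model(1.75, 2.5), 6e4, dt = 0.01,
                        seed = 21, keep_voltage = TRUE)
  V <- attr(sd, "voltage")$V
  qs <- stats::quantile(V, c(0.25, 0.5, 0.75))
  cdf <- cumsum(ss$p_V) * h
  qs_fp <- stats::approx(cdf, ss$V, xout = c(0.25, 0.5, 0.75),
                         ties = "ordered")$y
  expect_equal(unname(qs_fp), unname(qs), tolerance = 0.06)
})

test_that("renewal consistency: mean ISI equals the inverse stationary rate", {
  np <- default_params()
  d <- solve_isi_density(np, 1.75, 2.5, fp_grid(s_max = 600, dt = 0.05))
  r <- steady_state(np, 1.75, 2.5)$r_inf
  expect_equal(mean(d), 1 / r, tolerance = 0.01)
})

test_that("grid refinement changes the density by less than 0.5% in L1", {
  np <- default_params()
  g1 <- fp_grid(s_max = 200, dt = 0.05, n_V = 256)
  g2 <- fp_grid(s_max = 200, dt = 0.025, n_V = 512)
  d1 <- solve_isi_density(np, 1.75, 2.5, g1)
  d2 <- solve_isi_density(np, 1.75, 2.5, g2)
  at <- seq(1, 199, by = 0.5)
  v1 <- stats::approx(d1$s, d1$density, at)$y
  v2 <- stats::approx(d2$s, d2$density, at)$y
  expect_lt(sum(abs(v1 - v2)) / sum(v2), 0.005)
})

test_that("voltage-offset symmetry leaves the ISI density invariant", {
  # shifting threshold, reset and mu*tau_m by a common offset is a pure
  # change of variables
  np1 <- default_params()
  off <- 12
  np2 <- neuron_params(V_s = 30 + off, V_r = off, tau_m = 20)
  g <- fp_grid(s_max = 150, dt = 0.05, V_lb = -50)
  g2 <- fp_grid(s_max = 150, dt = 0.05, V_lb = -50 + off)
  d1 <- solve_isi_density(np1, 1.75, 2.5, g)
  d2 <- solve_isi_density(np2, 1.75 + off / 20, 2.5, g2)
  expect_equal(d1$density, d2$density, tolerance = 1e-8)
})

test_that("first-order correction matches differencing the full solver", {
  np <- default_params()
  g <- fp_grid(s_max = 150, dt = 0.05)
  mu1 <- function(s) ifelse(s > 20, ((s - 20) / 10) * exp(1 - (s - 20) / 10),
                            0)
  pp <- solve_isi_perturbation(np, 1.75, 2.5, mu1, g)
  eps <- 0.01
  dp <- solve_isi_density(np, function(s) 1.75 + eps * mu1(s), 2.5, g)
  dm <- solve_isi_density(np, function(s) 1.75 - eps * mu1(s), 2.5, g)
  fd <- (dp$density - dm$density) / (2 * eps)
  expect_lt(max(abs(pp$p1 - fd)) / max(abs(fd)), 0.01)
  # no perturbation: p1 identically zero, p0 the plain density
  p0 <- solve_isi_density(np, 1.75, 2.5, g)
  pz <- solve_isi_perturbation(np, 1.75, 2.5, function(s) 0 * s, g)
  expect_equal(pz$p1, rep(0, length(pz$p1)))
  expect_equal(pz$p0, p0$density)
})

test_that("first-order correction integrates to ~0 (mass conservation)", {
  np <- default_params()
  g <- fp_grid(s_max = 400, dt = 0.05)
  mu1 <- function(s) ifelse(s > 20, ((s - 20) / 10) * exp(1 - (s - 20) / 10),
                            0)
  pp <- solve_isi_perturbation(np, 1.75, 2.5, mu1, g)
  expect_lt(abs(sum(pp$p1) * g$dt), 5e-3)
})

test_that("ISI tables reproduce stored solves exactly at nodes and
           interpolate accurately between them", {
  np <- default_params()
  g <- fp_grid(s_max = 150, dt = 0.05)
  tab <- precompute_isi_tables(np, 2.5, seq(1.4, 2.2, by = 0.1), g)
  d_node <- solve_isi_density(np, 1.8, 2.5, g)
  at <- c(20, 30.5, 44, 61)
  expect_equal(isi_table_density(tab, 1.8, at),
               stats::approx(d_node$s, d_node$density, at)$y,
               tolerance = 1e-10)
  # midpoint between nodes vs direct solve
  d_mid <- solve_isi_density(np, 1.85, 2.5, g)
  direct <- stats::approx(d_mid$s, d_mid$density, at)$y
  expect_equal(isi_table_density(tab, 1.85, at), direct,
               tolerance = 1e-3)
  # extrapolation refused
  expect_error(isi_table_density(tab, 2.5, 30), "extrapolation")
})

test_that("Monte-Carlo first-passage sample agrees with the FP density", {
  # moderate-size version of the oracle comparison (the full-scale one
  # runs in the acceptance suite)
  np <- default_params()
  g <- fp_grid(s_max = 300, dt = 0.02, n_V = 400)
  d <- solve_isi_density(np, 1.75, 2.5, g)
  n <- 20000
  sd <- simulate_neuron(np, input_model(1.75, 2.5),
                        duration = n * 45, dt = 0.0025, seed = 31)
  isis <- diff(sd$trains[[1]])[seq_len(n)]
  cdf_fp <- cumsum(d$density) * g$dt
  ks <- max(abs(stats::ecdf(isis)(d$s) - cdf_fp))
  expect_lt(ks, 0.015)
})
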