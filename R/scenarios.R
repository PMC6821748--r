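# Packaged simulation studies ("scenarios"): ground-truth data are
# generated by the synth module at the declared study conditions and the
# corresponding estimator is run; each function returns the summary
# quantities of its design. Problem sizes default to the values used in
# the package's own evaluation and can be scaled via arguments.

#' Background-input recovery study
#'
#' Simulates independent spike trains of a leaky I&F neuron at the
#' default parameters (`V_s` = 30 mV, `V_r` = 0, `tau_m` = 20 ms,
#' `mu` = 1.75 mV/ms, `sigma` = 2.5 mV/sqrt(ms)), truncates each at `K`
#' spikes, fits `(mu, sigma)` per train with the Fokker-Planck likelihood
#' (membrane time constant fixed at the true value), and summarizes the
#' relative estimation errors.
#'
#' @param n_trains number of independent trains
#' @param K spikes per train
#' @param mu,sigma true background parameters
#' @param params [neuron_params()]
#' @param seed integer RNG seed
#' @param sim_dt simulation step, ms
#' @return list with `estimates` (data.frame), `mean_rel_err_mu`,
#'   `mean_rel_err_sigma`, `max_mean_rel_err` (percent)
#' @export
scenario_background_recovery <- function(n_trains = 100, K = 50,
                                         mu = 1.75, sigma = 2.5,
                                         params = neuron_params(),
                                         seed = 1, sim_dt = 0.01) {
  seeds <- seed + 1000L * seq_len(n_trains)
  est <- t(vapply(seeds, function(s) {
    sd <- simulate_neuron(params, input_model(mu, sigma),
                          duration = K * 2000, dt = sim_dt, seed = s,
                          n_spikes = K)
    tr <- sd$trains[[1]]
    if (length(tr) < K)
      stop("simulation horizon too short for the requested spike count")
    f <- fit_background(tr[seq_len(K)], params)
    c(mu = f$estimates$mu, sigma = f$estimates$sigma)
  }, numeric(2)))
  err_mu <- mean(abs(est[, "mu"] - mu) / abs(mu)) * 100
  err_sigma <- mean(abs(est[, "sigma"] - sigma) / sigma) * 100
  list(estimates = data.frame(mu = est[, "mu"], sigma = est[, "sigma"]),
       mean_rel_err_mu = err_mu, mean_rel_err_sigma = err_sigma,
       max_mean_rel_err = max(err_mu, err_sigma),
       n_trains = n_trains, K = K)
}

#' Cramer-Rao bound versus empirical estimator spread
#'
#' Computes the theoretical standard-deviation bound for `(mu, sigma)`
#' estimates from `K`-spike trains at the default parameters and compares
#' it with the empirical standard deviation of maximum-likelihood
#' estimates over `n_trains` simulated trains.
#'
#' @inheritParams scenario_background_recovery
#' @return list with `crb_sd`, `empirical_sd` (named vectors) and the
#'   per-train estimates
#' @export
scenario_crb <- function(n_trains = 100, K = 400, mu = 1.75, sigma = 2.5,
                         params = neuron_params(), seed = 1,
                         sim_dt = 0.01) {
  info <- fisher_information(list(mu = mu, sigma = sigma), params)
  bound <- crb_sd(info, K)
  rec <- scenario_background_recovery(n_trains, K, mu, sigma, params,
                                      seed, sim_dt)
  emp <- c(mu = stats::sd(rec$estimates$mu),
           sigma = stats::sd(rec$estimates$sigma))
  list(crb_sd = bound, empirical_sd = emp, estimates = rec$estimates,
       fisher = info$matrix, n_trains = n_trains, K = K)
}

#' Perturbation-detection sensitivity study
#'
#' Wrapper around [detection_sensitivity()] at the default background and
#' alpha-kernel perturbations (tau = 10 ms) with trigger gaps of
#' 200 +- 50 ms; spike trains of 100 s length.
#'
#' @param J_values nonzero perturbation strengths, mV/ms
#' @param n_rep_model,n_rep_ccg repetitions per strength
#' @param duration spike-train length, ms
#' @param tau alpha time constant, ms
#' @param seed integer RNG seed
#' @return the [detection_sensitivity()] data.frame
#' @export
scenario_perturbation_detection <- function(J_values = c(-0.75, -0.25,
                                                         0.25, 0.75),
                                            n_rep_model = 50,
                                            n_rep_ccg = 300,
                                            duration = 1e5, tau = 10,
                                            seed = 1) {
  detection_sensitivity(
    list(duration = duration, tau = tau), J_values,
    n_rep_model = n_rep_model, n_rep_ccg = n_rep_ccg, seed = seed)
}

#' Network coupling-recovery study
#'
#' Samples a random network (couplings uniform on [-0.75, 0.75] mV,
#' global delay 1 ms), simulates it, runs the two-step pairwise
#' inference, and reports the agreement between true and estimated
#' couplings. With `c > 0` (correlated external drive) the jitter bias
#' correction can be applied.
#'
#' @param N number of neurons
#' @param duration recording length, ms
#' @param c external-input correlation coefficient
#' @param p_conn connection probability
#' @param delay true global delay, ms
#' @param bias_correction apply [bias_correct()] before summarizing
#'   (part of the standard pipeline: pairwise first-order estimates share
#'   a network-wide offset from residual background misfit)
#' @param n_bias_rep surrogate repetitions for the bias correction
#' @param seed integer RNG seed
#' @param sim_dt simulation step, ms
#' @return list with `correlation` (Pearson, true vs estimated J),
#'   `mae`, `mae_raw` (before correction, if applied), `delays`
#'   (estimated delays of true connections), `J_true`, `J_hat`, `fit`
#' @export
scenario_network_recovery <- function(N = 10, duration = 3e5, c = 0,
                                      p_conn = 1, delay = 1,
                                      bias_correction = TRUE,
                                      n_bias_rep = 2, seed = 1,
                                      sim_dt = 0.01) {
  net <- sample_random_network(
    N, p_exc = p_conn,
    strength_spec = list(kind = "uniform", range = c(-0.75, 0.75)),
    delay = delay, seed = seed, c = c)
  data <- simulate_network(net, duration, dt = sim_dt, seed = seed + 1)
  fit <- infer_network(data)
  mae_raw <- NULL
  if (bias_correction) {
    raw <- fit$J
    off <- row(raw) != col(raw)
    mae_raw <- mean(abs(raw[off] - net$J[off]))
    fit <- bias_correct(fit, jitter = 10, n_rep = n_bias_rep,
                        seed = seed + 2)
  }
  off <- row(fit$J) != col(fit$J)
  J_true <- net$J[off]; J_hat <- fit$J[off]
  conn <- net$J != 0 & off
  list(correlation = stats::cor(J_true, J_hat),
       mae = mean(abs(J_hat - J_true)),
       mae_raw = mae_raw,
       delays = fit$d[conn], true_delay = delay,
       J_true = net$J, J_hat = fit$J, fit = fit)
}

#' Adaptation-parameter recovery study
#'
#' Simulates adaptive leaky I&F neurons at the default background
#' parameters with the declared adaptation setting (`Delta_w` = 0.4
#' mV/ms, `tau_w` = 100 ms: an increment in the range reported for
#' cortical pyramidal cells, and a time constant several times the
#' membrane time constant so that adaptation clearly lengthens ISIs),
#' truncates each train at `K` spikes, jointly fits
#' `(mu, sigma, Delta_w, tau_w)`, and summarizes relative errors.
#'
#' @param n_trains number of trains
#' @param K spikes per train
#' @param Delta_w,tau_w true adaptation parameters
#' @param mu,sigma true background parameters
#' @param params [neuron_params()]
#' @param seed integer RNG seed
#' @param sim_dt simulation step, ms
#' @param fit_dt,fit_n_V,n_w0 likelihood-solver resolution
#' @param control optimizer settings passed to [fit_adaptive()]
#' @return list with per-train `estimates`, `mean_rel_err` (named,
#'   percent, for all four parameters) and `adapt_mean_rel_err` (average
#'   over `Delta_w` and `tau_w`)
#' @export
scenario_adaptation_recovery <- function(n_trains = 50, K = 500,
                                         Delta_w = 0.4, tau_w = 100,
                                         mu = 1.75, sigma = 2.5,
                                         params = neuron_params(),
                                         seed = 1, sim_dt = 0.01,
                                         fit_dt = 0.1, fit_n_V = 320,
                                         n_w0 = 6,
                                         control = list(reltol = 1e-4,
                                                        maxit = 150)) {
  ad <- adaptation_params(Delta_w, tau_w)
  seeds <- seed + 1000L * seq_len(n_trains)
  est <- t(vapply(seeds, function(s) {
    sd <- simulate_adaptive_neuron(params, ad, input_model(mu, sigma),
                                   duration = K * 2000, dt = sim_dt,
                                   seed = s, n_spikes = K)
    tr <- sd$trains[[1]][seq_len(K)]
    g <- fp_grid(s_max = max(diff(tr)) * 1.02 + 1, dt = fit_dt,
                 n_V = fit_n_V)
    f <- fit_adaptive(tr, params, grid = g, n_w0 = n_w0,
                      control = control)
    unlist(f$estimates)[c("mu", "sigma", "Delta_w", "tau_w")]
  }, numeric(4)))
  truth <- c(mu = mu, sigma = sigma, Delta_w = Delta_w, tau_w = tau_w)
  err <- colMeans(abs(sweep(est, 2, truth) ) /
                    rep(abs(truth), each = nrow(est))) * 100
  list(estimates = as.data.frame(est),
       mean_rel_err = err,
       adapt_mean_rel_err = mean(err[c("Delta_w", "tau_w")]),
       n_trains = n_trains, K = K,
       truth = as.list(truth))
}
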