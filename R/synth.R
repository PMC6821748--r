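#' Simulate a single integrate-and-fire neuron
#'
#' Euler-Maruyama integration of the stochastic membrane-voltage equation
#' with spike-and-reset rule. A spike is registered at the first grid point
#' with \eqn{V \ge V_s} (no sub-step interpolation); after a spike the
#' voltage is clamped at the reset for the refractory period.
#'
#' @param params [neuron_params()]
#' @param input [input_model()] with scalar `mu` (ignored when `mu_series`
#'   is given)
#' @param duration simulated time, ms
#' @param dt integration step, ms (default 0.01)
#' @param seed integer RNG seed (mandatory: simulations are reproducible)
#' @param mu_series optional time-resolved mean input sampled at the
#'   integration step (length `duration/dt`)
#' @param n_spikes optional: stop once this many spikes were emitted
#'   (`duration` then acts as an upper bound)
#' @param keep_voltage return the voltage trace (time series at `dt`)
#' @return a [spike_data()] object; if `keep_voltage`, the trace is attached
#'   as attribute `"voltage"` (data.frame `time_ms`, `V`)
#' @examples
#' sd <- simulate_neuron(neuron_params(), input_model(1.75, 2.5),
#'                       duration = 1000, seed = 1)
#' @export
simulate_neuron <- function(params, input, duration, dt = 0.01, seed,
                            mu_series = NULL, n_spikes = NULL,
                            keep_voltage = FALSE) {
  stopifnot(inherits(params, "neuron_params"), inherits(input, "input_model"),
            is.finite(duration), duration > 0, is.finite(dt), dt > 0)
  if (missing(seed)) stop("seed is required")
  n_steps <- as.integer(ceiling(duration / dt))
  mu <- if (is.null(mu_series)) input$mu[1] else {
    stopifnot(length(mu_series) >= n_steps)
    as.numeric(mu_series[seq_len(n_steps)])
  }
  set.seed(seed)
  res <- sim_if_cpp(mu, input$sigma, params$V_s, params$V_r, params$tau_m,
                    .nonlin_code(params), params$Delta_T, params$V_T,
                    params$t_ref, dt, n_steps,
                    max_spikes = if (is.null(n_spikes)) 0L else
                      as.integer(n_spikes),
                    keep_v = keep_voltage)
  out <- spike_data(res$spikes, t_span = c(0, res$t_end))
  if (keep_voltage)
    attr(out, "voltage") <- data.frame(
      time_ms = seq(0, by = dt, length.out = length(res$V)), V = res$V)
  out
}

#' Simulate an adaptive integrate-and-fire neuron
#'
#' As [simulate_neuron()], with a spike-triggered adaptation variable `w`
#' that decays with `tau_w` between spikes, is incremented by `Delta_w` at
#' spikes and subtracts from the mean input. With `Delta_w = 0` the
#' trajectory is identical to the non-adaptive simulation under the same
#' seed.
#'
#' @inheritParams simulate_neuron
#' @param adapt [adaptation_params()]
#' @param keep_adaptation return the adaptation trace
#' @return a [spike_data()] object; optional attributes `"voltage"` and
#'   `"adaptation"`
#' @export
simulate_adaptive_neuron <- function(params, adapt, input, duration,
                                     dt = 0.01, seed, mu_series = NULL,
                                     n_spikes = NULL, keep_voltage = FALSE,
                                     keep_adaptation = FALSE) {
  stopifnot(inherits(adapt, "adaptation_params"),
            inherits(params, "neuron_params"), inherits(input, "input_model"),
            duration > 0, dt > 0)
  if (missing(seed)) stop("seed is required")
  n_steps <- as.integer(ceiling(duration / dt))
  mu <- if (is.null(mu_series)) input$mu[1] else {
    stopifnot(length(mu_series) >= n_steps)
    as.numeric(mu_series[seq_len(n_steps)])
  }
  set.seed(seed)
  res <- sim_if_cpp(mu, input$sigma, params$V_s, params$V_r, params$tau_m,
                    .nonlin_code(params), params$Delta_T, params$V_T,
                    params$t_ref, dt, n_steps,
                    max_spikes = if (is.null(n_spikes)) 0L else
                      as.integer(n_spikes),
                    Delta_w = adapt$Delta_w, tau_w = adapt$tau_w,
                    keep_v = keep_voltage, keep_w = keep_adaptation)
  out <- spike_data(res$spikes, t_span = c(0, res$t_end))
  if (keep_voltage)
    attr(out, "voltage") <- data.frame(
      time_ms = seq(0, by = dt, length.out = length(res$V)), V = res$V)
  if (keep_adaptation)
    attr(out, "adaptation") <- data.frame(
      time_ms = seq(0, by = dt, length.out = length(res$w)), w = res$w)
  out
}

#' Simulate a coupled integrate-and-fire network
#'
#' Delayed delta-pulse coupling: each presynaptic spike of neuron j adds
#' `J[i, j]` mV to neuron i's voltage at the grid point nearest to
#' `t_spike + d[i, j]`. External noise has a shared component with
#' correlation coefficient `c`.
#'
#' @param net [network_params()]
#' @param duration simulated time, ms
#' @param dt integration step, ms
#' @param seed integer RNG seed
#' @return a [spike_data()] object with one train per neuron
#' @export
simulate_network <- function(net, duration, dt = 0.01, seed) {
  stopifnot(inherits(net, "network_params"), duration > 0, dt > 0)
  if (missing(seed)) stop("seed is required")
  np <- net$params
  if (np$nonlinearity != "leaky")
    stop("network simulation supports the leaky model")
  n_steps <- as.integer(ceiling(duration / dt))
  set.seed(seed)
  trains <- sim_net_cpp(net$J, net$d, net$mu, net$sigma, net$c,
                        np$V_s, np$V_r, np$tau_m, np$t_ref, dt, n_steps)
  spike_data(trains, t_span = c(0, n_steps * dt))
}

#' Draw a random network
#'
#' Connectivity is sampled independently per ordered pair (diagonal
#' excluded). Two strength schemes are supported:
#' * `list(kind = "uniform", range = c(lo, hi))` - every realized connection
#'   has a strength uniform on `range`; `p_exc` is then the overall
#'   connection probability and `p_inh` is ignored.
#' * `list(kind = "ei", mean_exc, mean_inh, n_exc)` - the first `n_exc`
#'   neurons are excitatory (connection probability `p_exc`, strengths
#'   uniform on `[0, 2*mean_exc]`), the rest inhibitory (probability
#'   `p_inh`, strengths uniform on `[2*mean_inh, 0]`), so columns are
#'   Dale-consistent.
#'
#' @param N_tot total neuron count
#' @param p_exc,p_inh connection probabilities in `[0, 1]`
#' @param strength_spec strength scheme, see Details
#' @param delay global coupling delay, ms
#' @param seed integer RNG seed
#' @param ... further arguments passed to [network_params()] (`mu`, `sigma`,
#'   `c`, `params`)
#' @return a [network_params()] object
#' @export
sample_random_network <- function(N_tot, p_exc, p_inh = 0,
                                  strength_spec = list(kind = "uniform",
                                                       range = c(-0.75, 0.75)),
                                  delay = 1, seed, ...) {
  stopifnot(p_exc >= 0, p_exc <= 1, p_inh >= 0, p_inh <= 1, N_tot >= 1)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  J <- matrix(0, N_tot, N_tot)
  if (strength_spec$kind == "uniform") {
    rng <- strength_spec$range
    conn <- matrix(stats::runif(N_tot^2) < p_exc, N_tot, N_tot)
    J[conn] <- stats::runif(sum(conn), rng[1], rng[2])
  } else if (strength_spec$kind == "ei") {
    n_exc <- strength_spec$n_exc
    stopifnot(n_exc >= 0, n_exc <= N_tot)
    for (j in seq_len(N_tot)) {
      exc <- j <= n_exc
      p <- if (exc) p_exc else p_inh
      conn <- stats::runif(N_tot) < p
      m <- if (exc) strength_spec$mean_exc else strength_spec$mean_inh
      J[conn, j] <- stats::runif(sum(conn), min(0, 2 * m), max(0, 2 * m))
    }
  } else stop("unknown strength_spec kind")
  diag(J) <- 0
  network_params(J, d = delay, ...)
}

#' Generate an Ornstein-Uhlenbeck current
#'
#' Exact discretization of the OU process: stationary distribution
#' N(`mu_I`, `sigma_I`^2), autocorrelation time `tau_I`. The initial value
#' is drawn from the stationary distribution.
#'
#' @param ou [ou_params()]
#' @param duration length of the series, ms
#' @param dt sampling step, ms (must be below `tau_I`)
#' @param seed integer RNG seed
#' @return data.frame with columns `time_ms` and `I`
#' @export
generate_ou_current <- function(ou, duration, dt = 0.05, seed) {
  stopifnot(inherits(ou, "ou_params"), duration > 0, dt > 0, dt < ou$tau_I)
  if (missing(seed)) stop("seed is required")
  n <- as.integer(ceiling(duration / dt)) + 1L
  rho <- exp(-dt / ou$tau_I)
  set.seed(seed)
  eps <- stats::rnorm(n, sd = ou$sigma_I * sqrt(1 - rho^2))
  eps[1] <- stats::rnorm(1, sd = ou$sigma_I)
  x <- as.numeric(stats::filter(eps, rho, method = "recursive"))
  data.frame(time_ms = seq(0, by = dt, length.out = n), I = ou$mu_I + x)
}

#' Generate perturbation trigger times
#'
#' Successive gaps are Gaussian with the given mean and standard deviation,
#' truncated below at 1 ms so that events stay strictly increasing.
#'
#' @param duration recording span, ms
#' @param mean_gap,sd_gap gap distribution, ms (defaults 200 and 50)
#' @param seed integer RNG seed
#' @return numeric vector of event times in `(0, duration)`
#' @export
generate_trigger_times <- function(duration, mean_gap = 200, sd_gap = 50,
                                   seed) {
  stopifnot(duration > 0, mean_gap > 0, sd_gap >= 0)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n_guess <- as.integer(ceiling(duration / mean_gap * 1.5) + 20L)
  times <- numeric(0)
  t_cur <- 0
  repeat {
    gaps <- pmax(stats::rnorm(n_guess, mean_gap, sd_gap), 1)
    tt <- t_cur + cumsum(gaps)
    times <- c(times, tt[tt < duration])
    if (tt[length(tt)] >= duration) break
    t_cur <- tt[length(tt)]
  }
  times
}
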