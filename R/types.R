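#' Integrate-and-fire neuron constants
#'
#' Fixed constants of the membrane-voltage model. The voltage obeys
#' \deqn{dV/dt = f(V) + \mu(t) + \sigma\,\xi(t),}
#' with a spike-and-reset rule: whenever \eqn{V \ge V_s} a spike is
#' registered and \eqn{V \leftarrow V_r}. For the leaky model
#' \eqn{f(V) = -V/\tau_m}; the exponential model adds a spike-initiation
#' term \eqn{\Delta_T \exp((V - V_T)/\Delta_T)/\tau_m}.
#'
#' Because a common shift and scaling of \eqn{(V_s, V_r)} can be absorbed
#' into \eqn{\mu} and \eqn{\sigma}, threshold and reset are treated as fixed
#' conventions rather than free parameters.
#'
#' @param V_s spike (threshold) voltage, mV
#' @param V_r reset voltage, mV (must be below `V_s`)
#' @param tau_m membrane time constant, ms
#' @param nonlinearity `"leaky"` or `"exponential"`
#' @param Delta_T spike-slope factor, mV (exponential model only)
#' @param V_T effective threshold, mV (exponential model only)
#' @param t_ref absolute refractory period, ms
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(V_s = 30, V_r = 0, tau_m = 20,
                          nonlinearity = c("leaky", "exponential"),
                          Delta_T = NULL, V_T = NULL, t_ref = 0) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(is.finite(V_s), is.finite(V_r), V_s > V_r,
            is.finite(tau_m), tau_m > 0, is.finite(t_ref), t_ref >= 0)
  if (nonlinearity == "exponential") {
    if (is.null(Delta_T) || is.null(V_T))
      stop("Delta_T and V_T are required for the exponential model")
    stopifnot(is.finite(Delta_T), Delta_T > 0, is.finite(V_T))
  } else {
    Delta_T <- 0; V_T <- 0
  }
  structure(list(V_s = V_s, V_r = V_r, tau_m = tau_m,
                 nonlinearity = nonlinearity,
                 Delta_T = Delta_T, V_T = V_T, t_ref = t_ref),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> %s I&F: V_s=%g mV, V_r=%g mV, tau_m=%g ms, t_ref=%g ms\n",
              x$nonlinearity, x$V_s, x$V_r, x$tau_m, x$t_ref))
  if (x$nonlinearity == "exponential")
    cat(sprintf("  Delta_T=%g mV, V_T=%g mV\n", x$Delta_T, x$V_T))
  invisible(x)
}

# integer nonlinearity code for the C++ kernels
.nonlin_code <- function(params) {
  if (params$nonlinearity == "exponential") 1L else 0L
}

#' Background-input model
#'
#' Mean and noise amplitude of the Gaussian white-noise input. `mu` may be a
#' single value or a per-ISI piecewise-constant sequence (one value per ISI).
#'
#' @param mu mean input, mV/ms (scalar or vector)
#' @param sigma noise amplitude, mV/sqrt(ms), strictly positive
#' @return an object of class `input_model`
#' @export
input_model <- function(mu, sigma) {
  stopifnot(all(is.finite(mu)), is.finite(sigma), sigma > 0)
  structure(list(mu = mu, sigma = sigma), class = "input_model")
}

#' Spike-train container
#'
#' One or many ordered spike-time sequences with a common recording span.
#'
#' @param trains a numeric vector (single train) or a list of numeric
#'   vectors, each strictly increasing (ms)
#' @param t_span recording interval `c(t_start, t_end)` (ms); defaults to
#'   `[0, max spike time]`
#' @param ids optional neuron identifiers (defaults to `seq_along(trains)`)
#' @return an object of class `spike_data`
#' @export
spike_data <- function(trains, t_span = NULL, ids = NULL) {
  if (is.numeric(trains)) trains <- list(trains)
  stopifnot(is.list(trains), length(trains) >= 1)
  for (tr in trains) {
    if (length(tr) > 1 && any(diff(tr) <= 0))
      stop("spike times must be strictly increasing within each train")
  }
  all_t <- unlist(trains, use.names = FALSE)
  if (is.null(t_span))
    t_span <- c(0, if (length(all_t)) max(all_t) else 0)
  stopifnot(length(t_span) == 2, t_span[2] >= t_span[1])
  if (length(all_t) &&
      (min(all_t) < t_span[1] || max(all_t) > t_span[2]))
    stop("spike times outside t_span")
  if (is.null(ids)) ids <- seq_along(trains)
  names(trains) <- as.character(ids)
  structure(list(trains = trains, t_span = t_span), class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  k <- vapply(x$trains, length, integer(1))
  cat(sprintf("<spike_data> %d train(s), %d spikes total, t_span [%g, %g] ms\n",
              length(x$trains), sum(k), x$t_span[1], x$t_span[2]))
  invisible(x)
}

# coerce a numeric vector / spike_data to a single spike-time vector
.as_train <- function(spikes) {
  if (inherits(spikes, "spike_data")) {
    if (length(spikes$trains) != 1)
      stop("a single spike train is required here")
    spikes$trains[[1]]
  } else {
    stopifnot(is.numeric(spikes))
    as.numeric(spikes)
  }
}

#' Network model parameters
#'
#' Coupled leaky I&F network: each presynaptic spike of neuron j adds
#' `J[i, j]` mV to the voltage of neuron i after delay `d[i, j]` ms. The
#' external drive of neuron i is white noise with mean `mu[i]` and amplitude
#' `sigma[i]`; a fraction `c` of the noise variance is shared across neurons.
#'
#' @param J coupling-strength matrix, mV, zero diagonal (no autapses)
#' @param d delay matrix, ms, strictly positive (scalar recycled)
#' @param mu,sigma per-neuron background input (scalars recycled)
#' @param c external-input correlation coefficient in `[0, 1)`
#' @param params shared [neuron_params()]
#' @return an object of class `network_params`
#' @export
network_params <- function(J, d = 1, mu = 1.75, sigma = 2.5, c = 0,
                           params = neuron_params()) {
  J <- as.matrix(J)
  N <- nrow(J)
  stopifnot(ncol(J) == N, all(diag(J) == 0), c >= 0, c < 1)
  if (length(d) == 1) d <- matrix(d, N, N)
  d <- as.matrix(d)
  stopifnot(all(d > 0))
  mu <- rep_len(mu, N); sigma <- rep_len(sigma, N)
  stopifnot(all(sigma > 0))
  structure(list(N_tot = N, J = J, d = d, mu = mu, sigma = sigma, c = c,
                 params = params),
            class = "network_params")
}

#' Spike-frequency adaptation parameters
#'
#' Adaptation variable `w` (mV/ms) decays with time constant `tau_w`, is
#' incremented by `Delta_w` at each spike, and subtracts from the mean input.
#'
#' @param Delta_w spike-triggered increment, mV/ms (>= 0)
#' @param tau_w adaptation time constant, ms (> 0, typically >> tau_m)
#' @return an object of class `adaptation_params`
#' @export
adaptation_params <- function(Delta_w, tau_w) {
  stopifnot(is.finite(Delta_w), Delta_w >= 0, is.finite(tau_w), tau_w > 0)
  structure(list(Delta_w = Delta_w, tau_w = tau_w),
            class = "adaptation_params")
}

#' Ornstein-Uhlenbeck input parameters
#'
#' Stationary distribution N(`mu_I`, `sigma_I`^2) with correlation time
#' `tau_I`; units of `mu_I`/`sigma_I` are the caller's (pA or mV/ms).
#'
#' @param mu_I stationary mean
#' @param sigma_I stationary standard deviation (> 0)
#' @param tau_I correlation time, ms (> 0)
#' @return an object of class `ou_params`
#' @export
ou_params <- function(mu_I, sigma_I, tau_I = 3) {
  stopifnot(is.finite(mu_I), sigma_I > 0, tau_I > 0)
  structure(list(mu_I = mu_I, sigma_I = sigma_I, tau_I = tau_I),
            class = "ou_params")
}
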