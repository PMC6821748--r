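#' Build lookup tables for the LNexp cascade rate model
#'
#' The reduced spike-rate model filters the mean input with an adaptive
#' exponential filter and passes the result through the steady-state rate
#' nonlinearity:
#' \deqn{d\mu_f/dt = (\mu(t) - \mu_f)/\tau_\mu(\mu_f), \quad r(t) = r_\infty(\mu_f).}
#' `r_inf` at each grid node comes from the stationary Fokker-Planck
#' solution; the filter time constant `tau_mu` is obtained by a
#' least-squares exponential fit to the full time-dependent Fokker-Planck
#' rate response to a small step of the mean input at that operating point
#' (fit window `fit_window` ms, default 5 membrane time constants).
#'
#' @param params [neuron_params()]
#' @param sigma noise amplitude, mV/sqrt(ms)
#' @param mu_grid uniformly spaced mean-input nodes, mV/ms
#' @param fp_dt,fp_n_V resolution of the time-dependent solves
#' @param d_mu step amplitude used for the filter extraction, mV/ms
#' @param fit_window length of the fitted transient, ms (default `5 tau_m`)
#' @return an object of class `lnexp_tables` with fields `mu_grid`,
#'   `r_inf_tab` (1/ms), `tau_mu_tab` (ms)
#' @export
build_lnexp_tables <- function(params, sigma, mu_grid, fp_dt = 0.05,
                               fp_n_V = 256, d_mu = 0.1,
                               fit_window = NULL) {
  stopifnot(inherits(params, "neuron_params"), sigma > 0,
            length(mu_grid) >= 2)
  if (max(abs(diff(diff(mu_grid)))) > 1e-8)
    stop("mu_grid must be uniformly spaced")
  if (is.null(fit_window)) fit_window <- 5 * params$tau_m
  V_lb <- params$V_r - max(6 * sigma * sqrt(params$tau_m / 2), 40)
  n_resp <- as.integer(ceiling(2 * fit_window / fp_dt))
  n_settle <- as.integer(ceiling(15 * params$tau_m / fp_dt))
  tt <- seq_len(n_resp) * fp_dt
  fit_n <- as.integer(ceiling(fit_window / fp_dt))
  dV <- (params$V_s - V_lb) / fp_n_V
  centers <- V_lb + (seq_len(fp_n_V) - 0.5) * dV
  r_inf_tab <- numeric(length(mu_grid))
  tau_mu_tab <- numeric(length(mu_grid))
  for (i in seq_along(mu_grid)) {
    mu0 <- mu_grid[i]
    ss0 <- steady_state(params, mu0, sigma, n_V = fp_n_V, V_lb = V_lb)
    r_inf_tab[i] <- ss0$r_inf
    # settle the finite-volume solver onto its own fixed point, then
    # apply a small step of the mean input and record the relaxation;
    # start and end rates are taken from the same discretization so the
    # normalized transient runs from ~1 to 0
    p_init <- stats::approx(ss0$V, ss0$p_V, xout = centers, rule = 2)$y
    p_init <- p_init / (sum(p_init) * dV)
    settle <- fp_rate_cpp(mu0, sigma, params$V_s, params$V_r,
                          params$tau_m, .nonlin_code(params),
                          params$Delta_T, params$V_T, V_lb, fp_n_V, fp_dt,
                          n_settle, p_init, t_ref = params$t_ref)
    r0f <- settle$rate[n_settle]
    resp <- fp_rate_cpp(mu0 + d_mu, sigma, params$V_s, params$V_r,
                        params$tau_m, .nonlin_code(params), params$Delta_T,
                        params$V_T, V_lb, fp_n_V, fp_dt, n_resp,
                        as.numeric(settle$p_V), t_ref = params$t_ref)
    r_t <- as.numeric(resp$rate)
    r1f <- r_t[n_resp]
    # least-squares exponential relaxation fit:
    # r(t) ~ r1 + (r0 - r1) exp(-t / tau), tau by 1-D least squares
    resid <- (r_t[seq_len(fit_n)] - r1f) / (r0f - r1f)
    ttf <- tt[seq_len(fit_n)]
    sse <- function(tau) sum((resid - exp(-ttf / tau))^2)
    opt <- stats::optimize(sse, c(0.05, 10 * params$tau_m))
    tau <- opt$minimum
    if (!is.finite(tau) || tau <= 0 ||
        opt$objective > 0.5 * max(sum(resid^2), 1))
      stop(sprintf("filter fit failed at mu = %g", mu0))
    tau_mu_tab[i] <- tau
  }
  structure(list(mu_grid = mu_grid, r_inf_tab = r_inf_tab,
                 tau_mu_tab = tau_mu_tab, params = params, sigma = sigma),
            class = "lnexp_tables")
}

#' Integrate the cascade rate model
#'
#' Solves the one-dimensional filter ODE with explicit midpoint stepping
#' and linear table lookups; the rate is the steady-state nonlinearity
#' evaluated at the filtered mean input.
#'
#' @param tables [build_lnexp_tables()] output
#' @param mu_series mean input sampled on `t_grid`, mV/ms (scalar recycled)
#' @param t_grid uniform time grid, ms
#' @param mu_f_init initial filtered mean input (defaults to
#'   `mu_series[1]`)
#' @return an object of class `rate_trajectory` with fields `t`, `mu_f`
#'   (not retained per step; initial value only), `r` (1/ms)
#' @export
integrate_rate <- function(tables, mu_series, t_grid, mu_f_init = NULL) {
  stopifnot(inherits(tables, "lnexp_tables"), length(t_grid) >= 2)
  dt <- t_grid[2] - t_grid[1]
  n <- length(t_grid)
  mu_series <- rep_len(as.numeric(mu_series), n)
  rng <- range(tables$mu_grid)
  out_of_range <- mu_series < rng[1] | mu_series > rng[2]
  if (any(out_of_range))
    warning(sprintf("%d of %d mean-input samples outside the table support;
clamped to the edge", sum(out_of_range), n))
  if (is.null(mu_f_init)) mu_f_init <- mu_series[1]
  r <- lnexp_integrate_cpp(mu_series, dt, tables$mu_grid, tables$r_inf_tab,
                           tables$tau_mu_tab, mu_f_init)
  structure(list(t = t_grid, r = as.numeric(r), mu_f_init = mu_f_init,
                 tables = tables),
            class = "rate_trajectory")
}

#' Inhomogeneous-Poisson spike-train log-likelihood
#'
#' Approximates the spike train by an inhomogeneous Poisson point process
#' with the model rate: each conditioned spike-time factor contributes
#' \eqn{\log r(t_{k+1}) - \int_{t_k}^{t_{k+1}} r\,d\tau} (trapezoid rule on
#' the rate grid). The rate is floored at `r_floor` inside the logarithm;
#' if the floor is hit at an observed spike the result carries attribute
#' `"floored" = TRUE`.
#'
#' @param spikes spike times (numeric vector or single-train
#'   [spike_data()]), within the rate-grid span
#' @param rate a `rate_trajectory` from [integrate_rate()], or a list with
#'   fields `t` and `r`
#' @param r_floor rate floor inside logs, 1/ms
#' @return log-likelihood (scalar)
#' @export
poisson_loglik <- function(spikes, rate, r_floor = 1e-10) {
  tr <- .as_train(spikes)
  if (length(tr) < 2) stop("at least two spikes are required")
  t <- rate$t; r <- rate$r
  if (tr[1] < t[1] - 1e-9 || tr[length(tr)] > t[length(t)] + 1e-9)
    stop("spikes outside the rate-grid span")
  r_at <- stats::approx(t, r, xout = tr[-1], rule = 2)$y
  floored <- any(r_at < r_floor)
  dt <- t[2] - t[1]
  # integral of r between first and last spike by trapezoid + end corrections
  cumr <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * dt))
  cum_at <- stats::approx(t, cumr, xout = c(tr[1], tr[length(tr)]),
                          rule = 2)$y
  ll <- sum(log(pmax(r_at, r_floor))) - (cum_at[2] - cum_at[1])
  attr(ll, "floored") <- floored
  ll
}
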