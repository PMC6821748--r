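# Inference for the adaptive I&F model.
#
# With spike-triggered adaptation the process is not renewal, but the
# dependence on history enters only through the adaptation value at each
# ISI onset, w0, which is determined by the observed spike times and
# (Delta_w, tau_w). The per-ISI likelihood factor is the first-passage
# density under the effective mean input mu - w0 exp(-s/tau_w); factors are
# evaluated from a small table of densities conditioned on w0, with cubic
# interpolation in w0.

#' Reconstruct the adaptation trajectory from observed spikes
#'
#' Given spike times and adaptation parameters, the adaptation variable at
#' the start of ISI k (just after spike k, increment included) is
#' \deqn{w_0(k) = \Delta w \sum_{i \le k} e^{-(t_k - t_i)/\tau_w},}
#' assuming the adaptation current just before the first spike is zero.
#' Within an ISI, `w(t) = w0 * exp(-(t - t_k)/tau_w)`. Given the spikes
#' this reconstruction is exact.
#'
#' @param spikes spike times (vector or single-train [spike_data()])
#' @param adapt [adaptation_params()]
#' @return list with `w0` (one value per ISI, mV/ms), `mu1` (unit-increment
#'   kernel value per ISI start, `w0 / Delta_w`), and `w_of` (function of
#'   absolute time returning the reconstructed w)
#' @export
adaptation_trajectory <- function(spikes, adapt) {
  tr <- .as_train(spikes)
  stopifnot(inherits(adapt, "adaptation_params"), length(tr) >= 2)
  K <- length(tr)
  # unit-increment accumulation: m_k = sum_{i<=k} exp(-(t_k - t_i)/tau_w)
  m <- numeric(K)
  m[1] <- 1
  for (k in 2:K)
    m[k] <- m[k - 1] * exp(-(tr[k] - tr[k - 1]) / adapt$tau_w) + 1
  w0 <- adapt$Delta_w * m[-K]
  w_of <- function(t) {
    vapply(t, function(tt) {
      prev <- which(tr <= tt)
      if (!length(prev)) return(0)
      k <- max(prev)
      adapt$Delta_w * m[k] * exp(-(tt - tr[k]) / adapt$tau_w)
    }, numeric(1))
  }
  list(w0 = w0, mu1 = m[-K], w_of = w_of)
}

# density at (isi_k, w0_k) from a per-node density matrix via cubic
# (4-point Lagrange) interpolation on the uniform w0 grid, linear in s
.w0_table_eval <- function(dens_mat, s_grid, w0_grid, isis, w0) {
  n_w <- length(w0_grid)
  at_isis <- vapply(seq_len(n_w), function(j)
    .interp_density(s_grid, dens_mat[, j], isis), numeric(length(isis)))
  if (!is.matrix(at_isis)) at_isis <- matrix(at_isis, nrow = length(isis))
  if (n_w == 1) return(pmax(at_isis[, 1], 0))
  if (n_w < 4) {
    # linear interpolation for very small tables
    j <- pmin(pmax(findInterval(w0, w0_grid), 1L), n_w - 1L)
    u <- (w0 - w0_grid[j]) / diff(w0_grid)[1]
    k <- seq_along(isis)
    return(pmax((1 - u) * at_isis[cbind(k, j)] +
                  u * at_isis[cbind(k, j + 1L)], 0))
  }
  h <- w0_grid[2] - w0_grid[1]
  i1 <- pmin(pmax(findInterval(w0, w0_grid), 2L), n_w - 2L)
  u <- (w0 - w0_grid[i1]) / h
  W <- cbind(-u * (u - 1) * (u - 2) / 6,
             (u^2 - 1) * (u - 2) / 2,
             -u * (u + 1) * (u - 2) / 2,
             u * (u^2 - 1) / 6)
  k <- seq_along(isis)
  out <- W[, 1] * at_isis[cbind(k, i1 - 1L)] +
    W[, 2] * at_isis[cbind(k, i1)] +
    W[, 3] * at_isis[cbind(k, i1 + 1L)] +
    W[, 4] * at_isis[cbind(k, i1 + 2L)]
  pmax(out, 0)
}

#' Log-likelihood of the adaptive I&F model
#'
#' Evaluates the spike-train likelihood with per-ISI effective mean input
#' `mu - w0_k exp(-s/tau_w)`: densities are solved on a grid of `n_w0`
#' adaptation states spanning the realized `w0` range and interpolated
#' (cubic in w0). With `Delta_w = 0` this reduces exactly to the renewal
#' likelihood.
#'
#' @param spikes spike times (vector or single-train [spike_data()])
#' @param theta named list with `mu`, `sigma`, `Delta_w`, `tau_w`
#' @param params [neuron_params()]
#' @param grid [fp_grid()]; defaults to a horizon just above the largest
#'   ISI with `dt = 0.1` ms
#' @param n_w0 number of adaptation-state nodes
#' @return log-likelihood (scalar)
#' @export
adaptive_loglik <- function(spikes, theta, params = neuron_params(),
                            grid = NULL, n_w0 = 8) {
  tr <- .as_train(spikes)
  isis <- diff(tr)
  if (is.null(grid))
    grid <- fp_grid(s_max = max(isis) * 1.02 + 1, dt = 0.1, n_V = 200)
  if (theta$Delta_w <= 0) {
    d <- solve_isi_density(params, theta$mu, theta$sigma, grid)
    dens <- .interp_density(d$s, d$density, isis)
    return(sum(log(pmax(dens, .DENSITY_FLOOR))))
  }
  w0 <- adaptation_trajectory(tr, adaptation_params(theta$Delta_w,
                                                    theta$tau_w))$w0
  rng <- range(w0)
  n_steps <- as.integer(ceiling((grid$s_max - params$t_ref) / grid$dt))
  s_mid <- params$t_ref + (seq_len(n_steps) - 0.5) * grid$dt
  s_end <- params$t_ref + seq_len(n_steps) * grid$dt
  if (diff(rng) < 1e-9) {
    nodes <- rng[1]
  } else {
    nodes <- seq(rng[1], rng[2], length.out = n_w0)
  }
  dens_mat <- vapply(nodes, function(w) {
    mu_s <- theta$mu - w * exp(-s_mid / theta$tau_w)
    d <- solve_isi_density(params, mu_s, theta$sigma, grid, coef_tol = 2e-3)
    d$density
  }, numeric(n_steps))
  if (!is.matrix(dens_mat)) dens_mat <- matrix(dens_mat, ncol = 1)
  dens <- .w0_table_eval(dens_mat, s_end, nodes, isis, w0)
  sum(log(pmax(dens, .DENSITY_FLOOR)))
}

#' Joint fit of background and adaptation parameters
#'
#' Simplex maximization of the adaptive likelihood over
#' `(mu, sigma, Delta_w, tau_w)` (`N_theta = 4` for the AIC). The start is
#' moment-matched: a renewal fit supplies provisional `(mu, sigma)`, and
#' the mean adaptation level implied by the starting `(Delta_w, tau_w)`
#' and the observed rate is added back onto `mu`.
#'
#' @inheritParams adaptive_loglik
#' @param start optional named list overriding starting values
#' @param bounds optional named list overriding plausible limits
#' @param control passed to [stats::optim()]
#' @return a `fit_result` with estimates of `mu`, `sigma`, `Delta_w`,
#'   `tau_w`
#' @export
fit_adaptive <- function(spikes, params = neuron_params(), grid = NULL,
                         n_w0 = 8, start = NULL, bounds = list(),
                         control = list()) {
  tr <- .as_train(spikes)
  isis <- diff(tr)
  if (is.null(grid))
    grid <- fp_grid(s_max = max(isis) * 1.02 + 1, dt = 0.1, n_V = 200)
  b <- utils::modifyList(
    list(mu = c(-1, 8), sigma = c(0.1, 6), Delta_w = c(1e-3, 3),
         tau_w = c(10, 1000)), bounds)
  # moment-matched start
  ren <- fit_background(isis_as_sample(isis), params, grid = grid,
                        control = list(reltol = 1e-4))
  r_obs <- 1 / mean(isis)
  th0 <- list(mu = NA, sigma = ren$estimates$sigma,
              Delta_w = 0.15, tau_w = 100)
  if (!is.null(start)) th0 <- utils::modifyList(th0, start)
  if (is.na(th0$mu))
    th0$mu <- ren$estimates$mu + th0$Delta_w * th0$tau_w * r_obs
  for (nm in names(b))
    th0[[nm]] <- min(max(th0[[nm]], b[[nm]][1] * 1.0001),
                     b[[nm]][2] * 0.9999)
  free <- c("mu", "sigma", "Delta_w", "tau_w")
  x0 <- .to_internal(th0, free)
  obj <- function(x) {
    th <- .from_internal(x, free)
    pen <- .bounds_penalty(th, b)
    ll <- tryCatch(adaptive_loglik(tr, th, params, grid, n_w0),
                   error = function(e) -Inf)
    if (!is.finite(ll)) ll <- -1e12
    -(ll - pen)
  }
  ctl <- utils::modifyList(list(maxit = 400, reltol = 1e-5), control)
  opt <- stats::optim(x0, obj, method = "Nelder-Mead", control = ctl)
  # restart from the optimum: the simplex degenerates on the flat
  # mu / (Delta_w tau_w) ridge, and a fresh simplex reliably improves it
  ctl2 <- utils::modifyList(ctl, list(maxit = min(ctl$maxit, 100)))
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctl2)
  if (opt2$value < opt$value) opt <- opt2
  est <- .from_internal(opt$par, free)
  ll_hat <- -opt$value
  structure(list(estimates = est, theta = est, loglik = ll_hat,
                 n_isi = length(isis), aic = 2 * 4 - 2 * ll_hat,
                 convergence = opt$convergence, counts = opt$counts,
                 method = "fp_full_adaptive"),
            class = "fit_result")
}
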