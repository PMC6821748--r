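#' Discretization for the Fokker-Planck first-passage solver
#'
#' Voltage domain `[V_lb, V_s]` with `n_V` finite-volume cells and implicit
#' time stepping of size `dt` up to the ISI horizon `s_max`. When `V_lb` is
#' `NULL` it is placed at `V_r - max(6 sigma sqrt(tau_m/2), 40)` mV at solve
#' time, i.e. several stationary standard deviations below reset, where the
#' no-flux truncation of the lower boundary condition is innocuous.
#'
#' @param s_max maximal time since last spike, ms (must exceed the largest
#'   ISI to be evaluated)
#' @param dt solver time step, ms
#' @param n_V number of voltage cells (at least 200)
#' @param V_lb lower voltage bound, mV, or `NULL` for automatic placement
#' @return an object of class `fp_grid`
#' @export
fp_grid <- function(s_max, dt = 0.05, n_V = 256, V_lb = NULL) {
  stopifnot(s_max > 0, dt > 0, n_V >= 200)
  structure(list(s_max = s_max, dt = dt, n_V = as.integer(n_V), V_lb = V_lb),
            class = "fp_grid")
}

# resolve the lower bound for given parameters and noise amplitude
.fp_vlb <- function(grid, params, sigma) {
  if (!is.null(grid$V_lb)) {
    if (grid$V_lb >= params$V_r) stop("V_lb must lie below V_r")
    return(grid$V_lb)
  }
  params$V_r - max(6 * sigma * sqrt(params$tau_m / 2), 40)
}

# sample a scalar / vector / function mean-input trajectory on the solver
# steps; s values are times since ISI onset at the END of each step, offset
# by the refractory period (the solver clock starts at s = t_ref)
.mu_on_steps <- function(mu, n_steps, dt, t_ref = 0) {
  if (is.function(mu)) {
    s <- t_ref + (seq_len(n_steps) - 0.5) * dt
    as.numeric(mu(s))
  } else if (length(mu) == 1) {
    as.numeric(mu)
  } else {
    if (length(mu) < n_steps) stop("mu trajectory shorter than the horizon")
    as.numeric(mu[seq_len(n_steps)])
  }
}

.fp_call <- function(params, mu_steps, sigma, grid, n_steps, V_lb,
                     coef_tol = 0, keep_pv = FALSE) {
  fp_isi_cpp(mu_steps, sigma, params$V_s, params$V_r, params$tau_m,
             .nonlin_code(params), params$Delta_T, params$V_T,
             V_lb, grid$n_V, grid$dt, n_steps,
             coef_tol = coef_tol, keep_pv = keep_pv)
}

#' Solve for the inter-spike-interval density
#'
#' Computes the first-passage-time density of the membrane voltage from
#' reset to threshold: the Fokker-Planck equation is solved with an
#' absorbing boundary at `V_s` and initial condition concentrated at `V_r`;
#' the ISI density is the absorbed probability flux. A refractory period
#' shifts the density (`p_ISI(s) = 0` for `s < t_ref`).
#'
#' The scheme is conservative, so remaining interior mass plus the
#' integrated flux equals one up to round-off; a deviation beyond
#' `mass_tol` signals solver failure.
#'
#' @param params [neuron_params()]
#' @param mu mean-input trajectory over the ISI: scalar, function of s (ms),
#'   or vector sampled at the solver steps
#' @param sigma noise amplitude, mV/sqrt(ms)
#' @param grid [fp_grid()]
#' @param coef_tol tolerance for reusing drift coefficients while `mu`
#'   varies (0 = always rebuild); a small positive value speeds up slowly
#'   varying trajectories
#' @param mass_tol mass-conservation tolerance
#' @return an object of class `isi_density` with fields `s` (ms), `density`
#'   (1/ms), `survival` (probability of no spike up to s), `p_V`, `V`
#' @examples
#' g <- fp_grid(s_max = 200)
#' d <- solve_isi_density(neuron_params(), mu = 1.75, sigma = 2.5, g)
#' sum(d$density) * g$dt + d$survival[length(d$survival)]  # ~ 1
#' @export
solve_isi_density <- function(params, mu, sigma, grid, coef_tol = 0,
                              mass_tol = 1e-6) {
  stopifnot(inherits(params, "neuron_params"), inherits(grid, "fp_grid"),
            sigma > 0)
  n_steps <- as.integer(ceiling((grid$s_max - params$t_ref) / grid$dt))
  if (n_steps < 1) stop("s_max must exceed the refractory period")
  V_lb <- .fp_vlb(grid, params, sigma)
  mu_steps <- .mu_on_steps(mu, n_steps, grid$dt, params$t_ref)
  res <- .fp_call(params, mu_steps, sigma, grid, n_steps, V_lb,
                  coef_tol = coef_tol)
  s <- params$t_ref + seq_len(n_steps) * grid$dt
  dens <- pmax(as.numeric(res$flux), 0)
  absorbed <- cumsum(dens) * grid$dt
  bal <- abs(res$mass + absorbed[n_steps] - 1)
  if (!is.finite(bal) || bal > mass_tol)
    stop(sprintf(paste0("Fokker-Planck mass conservation violated ",
                        "(|error| = %.3g); refine the grid"), bal))
  structure(list(s = s, density = dens, survival = 1 - absorbed,
                 p_V = as.numeric(res$p_V),
                 V = V_lb + (seq_len(grid$n_V) - 0.5) * res$dV,
                 params = params, mu = mu, sigma = sigma, grid = grid),
            class = "isi_density")
}

# interpolate an ISI density (or any flux trace on the solver s-grid) at
# arbitrary ISIs; density is 0 before the first step / refractory period
.interp_density <- function(s_grid, dens, s_query) {
  out <- stats::approx(s_grid, dens, xout = s_query, yleft = 0,
                       yright = 0, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Mean of an ISI density
#'
#' Expected ISI computed from the density with a tail correction from the
#' remaining survival mass (assigned to the horizon).
#' @param x an `isi_density`
#' @param ... unused
#' @return mean ISI, ms
#' @export
mean.isi_density <- function(x, ...) {
  dt <- diff(x$s[1:2])
  sum(x$s * x$density) * dt + x$survival[length(x$survival)] * max(x$s)
}

#' First-order ISI-density correction for a weak input perturbation
#'
#' For mean input \eqn{\mu(s) = \mu_0(s) + J \mu_1(s)} with small |J|, the
#' ISI density is expanded as \eqn{p_{ISI} \approx p_0 + J p_1}. `p1` is
#' obtained from a linearized Fokker-Planck solve driven by `mu1` with the
#' unperturbed solution as source (not by differencing two nonlinear
#' solves, which serves as an independent check instead).
#'
#' @inheritParams solve_isi_density
#' @param mu0 unperturbed mean input (scalar, function, or vector)
#' @param mu1 unit perturbation trajectory (function of s or vector on the
#'   solver steps; delta pulses can be encoded as `1/dt` at single steps)
#' @return an object of class `perturbed_isi_density` with fields `s`,
#'   `p0`, `p1`
#' @export
solve_isi_perturbation <- function(params, mu0, sigma, mu1, grid,
                                   coef_tol = 0) {
  stopifnot(inherits(params, "neuron_params"), inherits(grid, "fp_grid"))
  n_steps <- as.integer(ceiling((grid$s_max - params$t_ref) / grid$dt))
  V_lb <- .fp_vlb(grid, params, sigma)
  mu0_steps <- .mu_on_steps(mu0, n_steps, grid$dt, params$t_ref)
  mu1_steps <- .mu_on_steps(mu1, n_steps, grid$dt, params$t_ref)
  res <- fp_isi_p1_cpp(mu0_steps, mu1_steps, sigma, params$V_s, params$V_r,
                       params$tau_m, .nonlin_code(params), params$Delta_T,
                       params$V_T, V_lb, grid$n_V, grid$dt, n_steps,
                       coef_tol = coef_tol)
  s <- params$t_ref + seq_len(n_steps) * grid$dt
  structure(list(s = s, p0 = pmax(as.numeric(res$flux0), 0),
                 p1 = as.numeric(res$flux1),
                 params = params, sigma = sigma, grid = grid),
            class = "perturbed_isi_density")
}

#' Green-kernel table for delta-pulse perturbations
#'
#' For constant background mean input, the first-order density correction
#' responds linearly to the perturbation trajectory, so the response to a
#' unit delta pulse at pulse time `t_p` (time since ISI onset) acts as a
#' Green kernel: the correction for an arbitrary trajectory `mu1(t)` is
#' `integral G(s, t) mu1(t) dt`, and for delayed presynaptic pulses it is a
#' sum of kernel columns. Columns are computed on a coarser pulse-time grid
#' (`tp_step`) and interpolated linearly in `t_p`.
#'
#' @inheritParams solve_isi_density
#' @param mu0 constant background mean input, mV/ms
#' @param tp_step spacing of the pulse-time grid, ms
#' @return an object of class `fp_green` with fields `s`, `t_p`, `G`
#'   (matrix `length(s)` x `length(t_p)`), `p0` (unperturbed density)
#' @export
fp_green_kernel <- function(params, mu0, sigma, grid, tp_step = 1) {
  stopifnot(inherits(params, "neuron_params"), inherits(grid, "fp_grid"),
            length(mu0) == 1, tp_step >= grid$dt)
  n_steps <- as.integer(ceiling((grid$s_max - params$t_ref) / grid$dt))
  V_lb <- .fp_vlb(grid, params, sigma)
  stride <- max(1L, as.integer(round(tp_step / grid$dt)))
  tp_idx <- seq.int(0L, n_steps - 2L, by = stride)
  G <- fp_green_cpp(mu0, sigma, params$V_s, params$V_r, params$tau_m,
                    .nonlin_code(params), params$Delta_T, params$V_T,
                    V_lb, grid$n_V, grid$dt, n_steps, tp_idx)
  p0 <- solve_isi_density(params, mu0, sigma, grid)
  raw <- .fp_call(params, mu0, sigma, grid, 2L, V_lb)
  # prompt-response band: between the tabulated columns the kernel varies
  # steeply just after the pulse (a pulse can fire the neuron within a
  # fraction of a millisecond), so the response within one column stride
  # of the spike is computed exactly for every pulse step
  band_steps <- as.integer(stride + 2L)
  H <- fp_band_cpp(mu0, sigma, params$V_s, params$V_r, params$tau_m,
                   .nonlin_code(params), params$Delta_T, params$V_T,
                   V_lb, grid$n_V, grid$dt, n_steps, band_steps)
  structure(list(s = p0$s, t_p = params$t_ref + (tp_idx + 1L) * grid$dt,
                 G = G, p0 = p0,
                 H = H, band = stride * grid$dt,
                 dflux_ratio = raw$dflux_coef / raw$flux_coef,
                 params = params, mu0 = mu0, sigma = sigma,
                 grid = grid),
            class = "fp_green")
}

# rows of the Green matrix interpolated at given ISIs -> matrix
# length(s_query) x length(t_p); each row l gives P1(s_l, t_p_j) over j
# (linear interpolation between the two bracketing s rows, vectorized)
.green_rows <- function(gk, s_query) {
  ds <- gk$s[2] - gk$s[1]
  ns <- length(gk$s)
  si <- (s_query - gk$s[1]) / ds + 1
  inside <- si >= 1 & si <= ns
  i0 <- pmin(pmax(floor(si), 1), ns - 1)
  f <- pmin(pmax(si - i0, 0), 1)
  out <- gk$G[i0, , drop = FALSE] * (1 - f) +
    gk$G[i0 + 1, , drop = FALSE] * f
  out[!inside, ] <- 0
  out
}

#' Stationary voltage density and spike rate
#'
#' Steady state of the Fokker-Planck system with reinjection of the
#' absorbed flux at the reset voltage, for constant mean input. Obtained by
#' backward "threshold integration" of the stationary flux equation from
#' `V_s` (where the density vanishes) down to the lower bound, with an
#' exponential integrating factor per step; the rate follows from
#' normalization, `r_inf = 1 / (t_ref + integral of the unit-flux
#' density)`.
#'
#' @inheritParams solve_isi_density
#' @param mu constant mean input, mV/ms
#' @param n_V number of integration points (default 1024)
#' @param V_lb lower bound, mV, or `NULL` for automatic placement
#' @return an object of class `fp_steady_state` with fields `V`, `p_V`
#'   (normalized stationary density, 1/mV), `r_inf` (1/ms)
#' @export
steady_state <- function(params, mu, sigma, n_V = 1024, V_lb = NULL) {
  stopifnot(inherits(params, "neuron_params"), length(mu) == 1, sigma > 0)
  if (is.null(V_lb))
    V_lb <- params$V_r - max(6 * sigma * sqrt(params$tau_m / 2), 40)
  V <- seq(V_lb, params$V_s, length.out = n_V)
  h <- V[2] - V[1]
  D <- sigma^2 / 2
  fV <- -V / params$tau_m
  if (params$nonlinearity == "exponential")
    fV <- fV + params$Delta_T * exp((V - params$V_T) / params$Delta_T) /
      params$tau_m
  A <- fV + mu
  qflux <- as.numeric(V >= params$V_r)   # unit stationary flux above reset
  p <- numeric(n_V)
  # integrate downward: p(V - h) = p(V) e^{-A h / D} + (q/A)(1 - e^{-A h/D})
  for (k in n_V:2) {
    Am <- 0.5 * (A[k] + A[k - 1])
    qm <- if (V[k - 1] >= params$V_r || V[k] >= params$V_r) 1 else 0
    x <- Am * h / D
    if (abs(x) < 1e-10) {
      p[k - 1] <- p[k] + qm * h / D
    } else {
      e <- exp(-x)
      p[k - 1] <- p[k] * e + (qm / Am) * (1 - e)
    }
  }
  p <- pmax(p, 0)
  Tmean <- sum((p[-1] + p[-n_V]) / 2) * h    # mean first-passage time
  r_inf <- 1 / (params$t_ref + Tmean)
  if (!is.finite(r_inf) || r_inf < 0) r_inf <- 0
  structure(list(V = V, p_V = p * r_inf, r_inf = r_inf,
                 params = params, mu = mu, sigma = sigma),
            class = "fp_steady_state")
}

# vectorized steady-state rate over a mu grid (1/ms)
.rinf_curve <- function(params, mu_values, sigma, n_V = 600) {
  vapply(mu_values,
         function(m) steady_state(params, m, sigma, n_V = n_V)$r_inf,
         numeric(1))
}

# 4-point Lagrange (cubic) interpolation weights on a sorted node vector;
# exact at nodes, reduces to the available points near the edges
.cubic_weights <- function(nodes, x) {
  n <- length(nodes)
  if (n == 1) return(list(idx = 1L, w = 1))
  k <- findInterval(x, nodes, all.inside = TRUE)
  i0 <- max(1L, min(k - 1L, n - 3L))
  idx <- i0:min(i0 + 3L, n)
  xs <- nodes[idx]
  w <- vapply(seq_along(idx), function(j) {
    others <- xs[-j]
    prod((x - others) / (xs[j] - others))
  }, numeric(1))
  list(idx = idx, w = w)
}

#' Precompute ISI-density tables over a mean-input grid
#'
#' Solves the first-passage problem once per grid node so that spike-train
#' likelihoods with per-ISI mean input (or adaptation state) can be
#' evaluated by interpolation instead of per-ISI solves. Interpolation is
#' cubic (4-point Lagrange) in `mu` and in `w0`, linear in `s`. Queries
#' outside the tabulated range are refused.
#'
#' @inheritParams solve_isi_density
#' @param mu_grid sorted mean-input nodes, mV/ms
#' @param w0_grid optional adaptation-state nodes (mV/ms); requires `tau_w`.
#'   The tabulated trajectories are `mu - w0 * exp(-s/tau_w)`.
#' @param tau_w adaptation time constant for `w0_grid`, ms
#' @return an object of class `isi_table`
#' @export
precompute_isi_tables <- function(params, sigma, mu_grid, grid,
                                  w0_grid = NULL, tau_w = NULL) {
  stopifnot(length(mu_grid) >= 1, !is.unsorted(mu_grid))
  if (!is.null(w0_grid)) stopifnot(!is.null(tau_w), !is.unsorted(w0_grid))
  n_steps <- as.integer(ceiling((grid$s_max - params$t_ref) / grid$dt))
  s <- params$t_ref + seq_len(n_steps) * grid$dt
  n_w <- if (is.null(w0_grid)) 1L else length(w0_grid)
  dens <- array(0, dim = c(n_steps, length(mu_grid), n_w))
  for (im in seq_along(mu_grid)) {
    for (iw in seq_len(n_w)) {
      mu_tr <- if (is.null(w0_grid)) mu_grid[im] else {
        sdec <- exp(-(s - grid$dt / 2) / tau_w)
        mu_grid[im] - w0_grid[iw] * sdec
      }
      d <- solve_isi_density(params, mu_tr, sigma, grid,
                             coef_tol = if (is.null(w0_grid)) 0 else 2e-3)
      dens[, im, iw] <- d$density
    }
  }
  structure(list(s = s, mu_grid = mu_grid, w0_grid = w0_grid, tau_w = tau_w,
                 density = dens, params = params, sigma = sigma,
                 grid = grid),
            class = "isi_table")
}

#' Query a precomputed ISI-density table
#'
#' @param table an `isi_table` from [precompute_isi_tables()]
#' @param mu mean-input value(s); scalar or one per query
#' @param s ISI value(s), ms
#' @param w0 adaptation state value(s), required if the table has a
#'   `w0_grid`
#' @return density values (1/ms) at the queried points
#' @export
isi_table_density <- function(table, mu, s, w0 = NULL) {
  stopifnot(inherits(table, "isi_table"))
  rng <- range(table$mu_grid)
  if (any(mu < rng[1] - 1e-12) || any(mu > rng[2] + 1e-12))
    stop("mu query outside the tabulated range; extrapolation refused")
  has_w <- !is.null(table$w0_grid)
  if (has_w) {
    if (is.null(w0)) stop("table is conditioned on w0; supply w0")
    wr <- range(table$w0_grid)
    if (any(w0 < wr[1] - 1e-12) || any(w0 > wr[2] + 1e-12))
      stop("w0 query outside the tabulated range; extrapolation refused")
  }
  n <- max(length(mu), length(s))
  mu <- rep_len(mu, n); s <- rep_len(s, n)
  if (has_w) w0 <- rep_len(w0, n)
  vapply(seq_len(n), function(l) {
    cw <- .cubic_weights(table$mu_grid, mu[l])
    if (has_w) {
      vw <- .cubic_weights(table$w0_grid, w0[l])
      d_s <- numeric(length(table$s))
      for (a in seq_along(cw$idx))
        for (b in seq_along(vw$idx))
          d_s <- d_s + cw$w[a] * vw$w[b] * table$density[, cw$idx[a], vw$idx[b]]
    } else {
      d_s <- as.numeric(table$density[, cw$idx, 1, drop = TRUE] %*% cw$w)
    }
    .interp_density(table$s, pmax(d_s, 0), s[l])
  }, numeric(1))
}
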