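# Likelihood assembly and maximization.
#
# The spike-train likelihood factorizes over ISIs into conditioned
# spike-time likelihoods; for renewal settings (constant input statistics)
# every factor is the same first-passage ISI density evaluated at the
# observed ISI, so a single Fokker-Planck solve per parameter vector
# suffices.

.DENSITY_FLOOR <- 1e-12

# default plausible limits for free parameters
.default_bounds <- list(mu = c(-1, 5), sigma = c(0.1, 6), tau_m = c(5, 50),
                        J = c(-10, 10), tau = c(2, 50), d = c(0.1, 10),
                        Delta_w = c(1e-4, 3), tau_w = c(10, 1000))

#' Specification of a model fit
#'
#' @param method likelihood route: `"fp_full"` (Fokker-Planck ISI density),
#'   `"fp_perturbative"` (first-order expansion for weak perturbations) or
#'   `"rate_model"` (inhomogeneous-Poisson via the cascade rate model)
#' @param free names of free parameters (non-empty subset of
#'   `mu, sigma, tau_m, J, tau, d, Delta_w, tau_w`)
#' @param bounds named list of `c(lower, upper)` plausible limits;
#'   defaults are used for parameters not listed
#' @param fixed named list of fixed parameter values
#' @return an object of class `fit_spec`
#' @export
fit_spec <- function(method = c("fp_full", "fp_perturbative", "rate_model"),
                     free = c("mu", "sigma"), bounds = list(),
                     fixed = list()) {
  method <- match.arg(method)
  stopifnot(length(free) >= 1, all(free %in% names(.default_bounds)))
  b <- .default_bounds
  for (nm in names(bounds)) {
    stopifnot(length(bounds[[nm]]) == 2, bounds[[nm]][1] < bounds[[nm]][2],
              all(is.finite(bounds[[nm]])))
    b[[nm]] <- bounds[[nm]]
  }
  structure(list(method = method, free = free, bounds = b[free],
                 fixed = fixed),
            class = "fit_spec")
}

# log-transform positive-constrained parameters for the simplex search
.positive_params <- c("sigma", "tau", "tau_m", "tau_w", "Delta_w", "d")

.to_internal <- function(theta, free) {
  x <- unlist(theta[free])
  for (nm in free) if (nm %in% .positive_params) x[nm] <- log(x[[nm]])
  x
}

.from_internal <- function(x, free) {
  th <- as.list(x)
  names(th) <- free
  for (nm in free) if (nm %in% .positive_params) th[[nm]] <- exp(th[[nm]])
  th
}

# quadratic penalty outside the plausible limits (keeps the simplex inside)
.bounds_penalty <- function(theta, bounds) {
  pen <- 0
  for (nm in names(bounds)) {
    v <- theta[[nm]]
    b <- bounds[[nm]]
    if (v < b[1]) pen <- pen + 1e4 * (1 + (b[1] - v)^2)
    if (v > b[2]) pen <- pen + 1e4 * (1 + (v - b[2])^2)
  }
  pen
}

# maximize the first-order likelihood gain sum(log1p(J q / p0)) over the
# strength J.  The expanded density p0 + J q must stay positive for
# every observed ISI; inside that interval the gain is strictly concave,
# with infinite walls at the interval edges, so the interior optimum is
# found by golden-section search.
.fit_J_profile <- function(p0, q, J_max = 5, p0_min = 1e-8) {
  # ISIs in the far tail of the unperturbed density (p0 below p0_min/ms)
  # carry no usable first-order information: both p0 and q are at the
  # solver's noise floor there and their ratio would clamp the feasible
  # interval spuriously
  ok <- p0 > p0_min
  x <- q[ok] / p0[ok]
  if (!any(x != 0)) return(list(J = 0, gain = 0))
  pos <- x > 0; neg <- x < 0
  lo <- if (any(pos)) max(-1 / x[pos]) else -J_max
  hi <- if (any(neg)) min(-1 / x[neg]) else J_max
  lo <- max(lo, -J_max); hi <- min(hi, J_max)
  if (lo >= hi) return(list(J = 0, gain = 0))
  span <- hi - lo
  o <- stats::optimize(function(J) -sum(log1p(J * x)),
                       c(lo + 1e-6 * span, hi - 1e-6 * span), tol = 1e-5)
  list(J = o$minimum, gain = max(-o$objective, 0))
}

# extract the ISIs used for a renewal likelihood
.isis_of <- function(spikes) {
  if (inherits(spikes, "isi_sample")) return(as.numeric(spikes))
  tr <- .as_train(spikes)
  if (length(tr) < 2) stop("at least two spikes are required")
  diff(tr)
}

#' Spike-train log-likelihood
#'
#' Sum over ISIs of the log conditioned spike-time likelihood, dispatching
#' on the method in `spec`:
#' * `fp_full`: constant background mean input per evaluation; one
#'   Fokker-Planck ISI-density solve, evaluated at every observed ISI.
#'   Supports per-ISI mean input through a precomputed table in
#'   `context$table` (with `theta$mu` a vector, one value per ISI).
#' * `fp_perturbative`: requires `context$green` (a [fp_green_kernel()])
#'   and `context$p1_isi`, the per-ISI first-order correction (see
#'   [fit_perturbation()] which assembles it).
#' * `rate_model`: requires `context$tables` ([build_lnexp_tables()]) and
#'   `context$mu_series`/`context$t_grid` for the full-recording rate.
#'
#' Densities are floored at `1e-12`/ms inside the logarithm.
#'
#' @param spikes spike times (vector, single-train [spike_data()], or a
#'   censored `isi_sample` from [censor_isis()] for renewal methods)
#' @param theta named list of parameter values (`mu`, `sigma`, ...)
#' @param spec a [fit_spec()]
#' @param params [neuron_params()]
#' @param grid [fp_grid()] (renewal methods); defaults to a grid spanning
#'   the largest ISI
#' @param context method-specific precomputed objects, see Details
#' @return log-likelihood (scalar)
#' @export
spike_train_loglik <- function(spikes, theta, spec, params, grid = NULL,
                               context = list()) {
  isis <- .isis_of(spikes)
  if (!is.null(theta$tau_m)) params$tau_m <- theta$tau_m
  if (spec$method == "fp_full") {
    if (!is.null(context$table)) {
      dens <- isi_table_density(context$table, theta$mu, isis,
                                w0 = context$w0)
    } else {
      stopifnot(length(theta$mu) == 1)
      if (is.null(grid))
        grid <- fp_grid(s_max = max(isis) * 1.02 + 1)
      d <- solve_isi_density(params, theta$mu, theta$sigma, grid)
      dens <- .interp_density(d$s, d$density, isis)
    }
    sum(log(pmax(dens, .DENSITY_FLOOR)))
  } else if (spec$method == "fp_perturbative") {
    gk <- context$green
    if (is.null(gk)) stop("fp_perturbative requires context$green")
    p0 <- .interp_density(gk$p0$s, gk$p0$density, isis)
    p1 <- context$p1_isi
    if (is.null(p1)) p1 <- 0
    sum(log(pmax(p0 + theta$J * p1, .DENSITY_FLOOR)))
  } else {
    tr <- .as_train(spikes)
    rate <- integrate_rate(context$tables, context$mu_series,
                           context$t_grid)
    as.numeric(poisson_loglik(tr, rate))
  }
}

#' Maximum-likelihood fit of an integrate-and-fire model
#'
#' Derivative-free simplex (Nelder-Mead) maximization of the spike-train
#' log-likelihood over the free parameters in `spec`, with log transforms
#' for positive-constrained parameters and a quadratic penalty outside the
#' plausible limits. For the leaky model with free background parameters
#' the likelihood landscape is free of local maxima, so a single start
#' from a moment-matched guess suffices.
#'
#' @inheritParams spike_train_loglik
#' @param start optional named list of starting values (defaults to a
#'   moment-matched guess for `mu`/`sigma`, mid-bounds otherwise)
#' @param control passed to [stats::optim()] (reltol etc.)
#' @return an object of class `fit_result`: `estimates`, `loglik`,
#'   `n_isi`, `aic`, `convergence`, `method`
#' @examples
#' \donttest{
#' sd <- simulate_neuron(neuron_params(), input_model(1.75, 2.5),
#'                       duration = 20000, seed = 7)
#' fit_spike_train(sd, fit_spec("fp_full", free = c("mu", "sigma")),
#'                 neuron_params())
#' }
#' @export
fit_spike_train <- function(spikes, spec, params, grid = NULL,
                            context = list(), start = NULL,
                            control = list()) {
  stopifnot(inherits(spec, "fit_spec"))
  isis <- .isis_of(spikes)
  if (is.null(grid))
    grid <- fp_grid(s_max = max(isis) * 1.02 + 1)
  if (is.null(start)) start <- list()
  theta0 <- .default_start(isis, spec, params, start)
  obj <- function(x) {
    th <- .from_internal(x, spec$free)
    theta <- utils::modifyList(theta0, th)
    pen <- .bounds_penalty(th, spec$bounds)
    ll <- tryCatch(
      spike_train_loglik(isis_as_sample(isis), theta, spec, params, grid,
                         context),
      error = function(e) -Inf)
    if (!is.finite(ll)) ll <- -1e12
    -(ll - pen)
  }
  x0 <- .to_internal(theta0, spec$free)
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-6), control)
  if (length(x0) == 1) {
    opt <- stats::optim(x0, obj, method = "Brent",
                        lower = x0 - 5, upper = x0 + 5)
  } else {
    opt <- stats::optim(x0, obj, method = "Nelder-Mead", control = ctl)
  }
  est <- .from_internal(opt$par, spec$free)
  theta_hat <- utils::modifyList(theta0, est)
  ll_hat <- -opt$value - 0  # penalty is ~0 at an interior optimum
  n_theta <- length(spec$free)
  structure(list(estimates = est, theta = theta_hat, loglik = ll_hat,
                 n_isi = length(isis), aic = 2 * n_theta - 2 * ll_hat,
                 convergence = opt$convergence, counts = opt$counts,
                 method = spec$method, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> method %s, %d ISIs, logL = %.2f, AIC = %.2f\n",
              x$method, x$n_isi, x$loglik, x$aic))
  for (nm in names(x$estimates))
    cat(sprintf("  %-8s %.4g\n", nm, x$estimates[[nm]]))
  if (x$convergence != 0)
    cat("  (optimizer did not report convergence; best iterate returned)\n")
  invisible(x)
}

# moment-matched start: mu from the observed rate through the stationary
# rate curve (at a provisional sigma), sigma refined from the ISI CV
.default_start <- function(isis, spec, params, start) {
  theta <- list(mu = 1.5, sigma = 2, tau_m = params$tau_m, J = 0,
                tau = 10, d = 1, Delta_w = 0.2, tau_w = 100)
  if (all(c("mu", "sigma") %in% spec$free) || "mu" %in% spec$free) {
    r_obs <- 1 / mean(isis)  # 1/ms
    sig0 <- if (!is.null(start$sigma)) start$sigma else 2
    mu_try <- seq(.default_bounds$mu[1] + 0.05, .default_bounds$mu[2] - 0.05,
                  length.out = 25)
    rr <- .rinf_curve(params, mu_try, sig0, n_V = 400)
    theta$mu <- stats::approx(rr, mu_try, xout = r_obs, rule = 2,
                              ties = "ordered")$y
    theta$sigma <- sig0
  }
  theta <- utils::modifyList(theta, as.list(start))
  theta <- utils::modifyList(theta, spec$fixed)
  for (nm in names(spec$bounds)) {
    b <- spec$bounds[[nm]]
    theta[[nm]] <- min(max(theta[[nm]], b[1] + 1e-6), b[2] - 1e-6)
  }
  theta
}

#' Censored ISI sample
#'
#' Wraps a vector of ISIs for use with renewal likelihoods.
#' @param isis numeric vector of ISIs, ms
#' @return an object of class `isi_sample`
#' @export
isis_as_sample <- function(isis) {
  structure(as.numeric(isis), class = "isi_sample")
}

#' Censor inter-spike intervals
#'
#' Keeps the central `central` fraction of ISIs (by percentile window) that
#' are also longer than `min_isi`. Used to exclude onset transients and
#' spike-sorting artifacts before renewal fits.
#'
#' @param spikes spike times (vector or single-train [spike_data()])
#' @param central central fraction kept, in `(0, 1]` (e.g. 0.9 keeps the
#'   5th-95th percentile window)
#' @param min_isi minimum ISI length kept, ms
#' @return an `isi_sample` (vector of retained ISIs) with attribute
#'   `"n_dropped"`
#' @export
censor_isis <- function(spikes, central = 0.9, min_isi = 5) {
  stopifnot(central > 0, central <= 1, min_isi >= 0)
  isis <- .isis_of(spikes)
  keep <- isis > min_isi
  if (central < 1) {
    qs <- stats::quantile(isis, c((1 - central) / 2, 1 - (1 - central) / 2),
                          names = FALSE, type = 7)
    keep <- keep & isis >= qs[1] & isis <= qs[2]
  }
  out <- isis[keep]
  if (!length(out)) stop("censoring removed all ISIs")
  res <- isis_as_sample(out)
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Constant-rate Poisson baseline fit
#'
#' Reference model for AIC comparison: a homogeneous Poisson process whose
#' single parameter (the rate) is fitted by maximum likelihood,
#' `r = (K-1)/sum(ISIs)`.
#'
#' @param spikes spike times (vector, [spike_data()], or `isi_sample`)
#' @return a `fit_result` with `N_theta = 1`
#' @export
fit_poisson_baseline <- function(spikes) {
  isis <- .isis_of(spikes)
  r <- length(isis) / sum(isis)
  ll <- length(isis) * log(r) - r * sum(isis)
  structure(list(estimates = list(rate = r), loglik = ll,
                 n_isi = length(isis), aic = 2 * 1 - 2 * ll,
                 convergence = 0L, method = "poisson"),
            class = "fit_result")
}

#' Compare fitted models by AIC
#'
#' @param fits named list of `fit_result` objects fitted on identical data
#' @return data.frame with `model`, `n_param`, `loglik`, `aic`,
#'   `delta_aic` (relative to the best), ordered best first
#' @export
aic_compare <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  n_isi <- vapply(fits, function(f) f$n_isi, numeric(1))
  if (length(unique(n_isi)) != 1)
    stop("fits were not computed on identical data (ISI counts differ)")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  df <- data.frame(
    model = nm,
    n_param = vapply(fits, function(f) (f$aic + 2 * f$loglik) / 2,
                     numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)))
  df <- df[order(df$aic), ]
  df$delta_aic <- df$aic - df$aic[1]
  rownames(df) <- NULL
  df
}

#' Fisher information per ISI and Cramer-Rao bound
#'
#' Entries are computed by numerical quadrature of
#' \eqn{-\int p_{ISI}\,\partial^2 \log p_{ISI}/\partial\theta_i\partial\theta_j\,ds}
#' with second derivatives from central finite differences of the
#' Fokker-Planck density (relative step `h_rel`). The Cramer-Rao variance
#' bound for `K` observed spikes is `solve(I)[i,i]/(K-1)`.
#'
#' @param theta named list with the evaluation point (needs `mu`, `sigma`)
#' @param params [neuron_params()]
#' @param free parameters the information is computed for
#' @param grid [fp_grid()]; `s_max` should cover essentially all ISI mass
#' @param h_rel relative finite-difference step
#' @return an object of class `fisher_info` with fields `matrix` (per
#'   ISI), `free`
#' @export
fisher_information <- function(theta, params, free = c("mu", "sigma"),
                               grid = NULL, h_rel = 1e-3) {
  if (is.null(grid)) {
    r0 <- steady_state(params, theta$mu, theta$sigma)$r_inf
    grid <- fp_grid(s_max = max(12 / r0, 200))
  }
  dens_at <- function(th) {
    d <- solve_isi_density(params, th$mu, th$sigma, grid)
    pmax(d$density, .DENSITY_FLOOR)
  }
  p0 <- dens_at(theta)
  h <- vapply(free, function(nm) h_rel * max(abs(theta[[nm]]), 1),
              numeric(1))
  shift <- function(nm, by) {
    th <- theta
    th[[nm]] <- th[[nm]] + by
    th
  }
  lp <- function(th) log(dens_at(th))
  np <- length(free)
  lp0 <- log(p0)
  I <- matrix(0, np, np, dimnames = list(free, free))
  lp_plus <- lapply(seq_len(np), function(i) lp(shift(free[i], h[i])))
  lp_minus <- lapply(seq_len(np), function(i) lp(shift(free[i], -h[i])))
  ds <- grid$dt
  w <- p0 * ds
  for (i in seq_len(np)) {
    d2 <- (lp_plus[[i]] - 2 * lp0 + lp_minus[[i]]) / h[i]^2
    I[i, i] <- -sum(w * d2)
    if (i < np) for (j in (i + 1):np) {
      thpp <- shift(free[j], h[j]); thpp[[free[i]]] <- thpp[[free[i]]] + h[i]
      thpm <- shift(free[j], -h[j]); thpm[[free[i]]] <- thpm[[free[i]]] + h[i]
      thmp <- shift(free[j], h[j]); thmp[[free[i]]] <- thmp[[free[i]]] - h[i]
      thmm <- shift(free[j], -h[j]); thmm[[free[i]]] <- thmm[[free[i]]] - h[i]
      d2ij <- (lp(thpp) - lp(thpm) - lp(thmp) + lp(thmm)) /
        (4 * h[i] * h[j])
      I[i, j] <- I[j, i] <- -sum(w * d2ij)
    }
  }
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev))))
    warning("Fisher information has a negative eigenvalue; ",
            "consider adjusting h_rel or the grid")
  structure(list(matrix = I, free = free, theta = theta, h = h),
            class = "fisher_info")
}

#' @rdname fisher_information
#' @param info a `fisher_info` object
#' @param K number of observed spikes
#' @return `crb_sd`: named vector of Cramer-Rao standard-deviation bounds
#'   for estimates from `K`-spike trains
#' @export
crb_sd <- function(info, K) {
  stopifnot(inherits(info, "fisher_info"), K >= 2)
  v <- diag(solve(info$matrix)) / (K - 1)
  sqrt(pmax(v, 0))
}

#' Background-input fit (convenience wrapper)
#'
#' Fits `(mu, sigma)` of the stationary background input with the full
#' Fokker-Planck likelihood, membrane time constant fixed.
#'
#' @inheritParams fit_spike_train
#' @param free free parameters (default `c("mu", "sigma")`; add `"tau_m"`
#'   to estimate the membrane time constant as well)
#' @param censor optional list with `central` and `min_isi` passed to
#'   [censor_isis()]
#' @return a `fit_result`
#' @export
fit_background <- function(spikes, params = neuron_params(),
                           free = c("mu", "sigma"), censor = NULL,
                           grid = NULL, control = list()) {
  data <- if (!is.null(censor))
    censor_isis(spikes, censor$central, censor$min_isi)
  else isis_as_sample(.isis_of(spikes))
  fit_spike_train(data, fit_spec("fp_full", free = free), params,
                  grid = grid, control = control)
}
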