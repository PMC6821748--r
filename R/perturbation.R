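# Inference of input perturbations triggered at known times:
# mu(t) = mu0 + J mu1(t), with mu1 a superposition of alpha kernels
# (time constant tau) or delayed delta pulses (delay d).

#' Perturbation kernel
#'
#' @param kind `"alpha"` (normalized so an isolated kernel peaks at 1) or
#'   `"delta"` (delayed Dirac pulses of unit time-integral)
#' @param tau alpha time constant, ms
#' @param d delay, ms (delta kind)
#' @param triggers increasing event (onset) times, ms
#' @return an object of class `perturbation_kernel`
#' @export
perturbation_kernel <- function(kind = c("alpha", "delta"), tau = NULL,
                                d = NULL, triggers = numeric(0)) {
  kind <- match.arg(kind)
  if (kind == "alpha") stopifnot(!is.null(tau), tau > 0)
  if (kind == "delta") stopifnot(!is.null(d), d >= 0)
  if (length(triggers) > 1) stopifnot(!is.unsorted(triggers, strictly = TRUE))
  structure(list(kind = kind, tau = tau, d = d, triggers = triggers),
            class = "perturbation_kernel")
}

#' Evaluate the unit perturbation trajectory
#'
#' For alpha kernels,
#' \deqn{\mu_1(t) = \sum_l H(t - \tilde t_l)\frac{t - \tilde t_l}{\tau}
#'       \exp(1 - (t - \tilde t_l)/\tau),}
#' so an isolated kernel attains 1 at one time constant after its trigger.
#' Delta kernels are Dirac pulses at `triggers + d`; pointwise evaluation
#' returns `Inf` at the pulse times and 0 elsewhere (they enter
#' likelihoods through their unit time-integral).
#'
#' @param t evaluation times, ms
#' @param kernel a [perturbation_kernel()]
#' @return numeric vector of `mu1` values
#' @export
mu1_kernel <- function(t, kernel) {
  stopifnot(inherits(kernel, "perturbation_kernel"))
  if (kernel$kind == "delta") {
    pulses <- kernel$triggers + kernel$d
    return(ifelse(t %in% pulses, Inf, 0))
  }
  out <- numeric(length(t))
  for (tt in kernel$triggers) {
    x <- (t - tt) / kernel$tau
    idx <- x > 0
    out[idx] <- out[idx] + x[idx] * exp(1 - x[idx])
  }
  out
}

# alpha-kernel mu1 sampled on a uniform grid via the exact two-state
# recursion (triggers snapped to the grid)
.mu1_alpha_series <- function(triggers, n, dt, tau) {
  idx <- as.integer(round(triggers / dt))
  idx <- sort(idx[idx >= 0 & idx < n])
  as.numeric(alpha_series_cpp(idx, as.integer(n), dt, tau))
}

# bilinear lookup in a Green kernel: values G(s, t_p) at paired queries
.green_at <- function(gk, s_q, tp_q) {
  ds <- gk$s[2] - gk$s[1]
  htp <- if (length(gk$t_p) > 1) gk$t_p[2] - gk$t_p[1] else 1
  ns <- length(gk$s); ntp <- length(gk$t_p)
  si <- (s_q - gk$s[1]) / ds + 1
  tj <- (tp_q - gk$t_p[1]) / htp + 1
  i0 <- pmin(pmax(floor(si), 1), ns - 1); fi <- si - i0
  j0 <- pmin(pmax(floor(tj), 1), ntp - 1); fj <- tj - j0
  fi <- pmin(pmax(fi, 0), 1); fj <- pmin(pmax(fj, 0), 1)
  g00 <- gk$G[cbind(i0, j0)]; g10 <- gk$G[cbind(i0 + 1, j0)]
  g01 <- gk$G[cbind(i0, j0 + 1)]; g11 <- gk$G[cbind(i0 + 1, j0 + 1)]
  (1 - fi) * (1 - fj) * g00 + fi * (1 - fj) * g10 +
    (1 - fi) * fj * g01 + fi * fj * g11
}

# per-ISI first-order corrections for delta pulses at absolute times
# `pulses` given spike times `tr`.  Pulses well inside the ISI use the
# bilinear Green table; pulses within one table stride of the spike use
# the full-resolution prompt-response band (scaled by the unperturbed
# flux at the pulse time), which carries the "pulse fires the neuron
# promptly" likelihood mass.
.p1_delta_isi <- function(gk, tr, pulses) {
  K <- length(tr)
  isis <- diff(tr)
  p1 <- numeric(K - 1)
  k_of <- findInterval(pulses, tr)
  inside <- k_of >= 1 & k_of <= K - 1
  if (!any(inside)) return(p1)
  k_of <- k_of[inside]
  off <- pulses[inside] - tr[k_of]
  u <- isis[k_of] - off                 # time from pulse to next spike
  val <- numeric(length(off))
  far <- u > gk$band
  if (any(far))
    val[far] <- .green_at(gk, isis[k_of][far], off[far])
  if (any(!far)) {
    # exact prompt band, bilinear in (pulse step, steps to spike).  The
    # continuum response rises like 1/sqrt(u) toward zero lag; the
    # discrete band resolves that rise down to one solver step, which
    # acts as the regularization scale of the likelihood
    dt <- gk$grid$dt
    t_ref <- gk$params$t_ref
    nr <- nrow(gk$H); nc <- ncol(gk$H)
    ci <- (off[!far] - t_ref) / dt
    ri <- u[!far] / dt + 1
    c0 <- pmin(pmax(floor(ci), 1), nc - 1); fc <- pmin(pmax(ci - c0, 0), 1)
    r0 <- pmin(pmax(floor(ri), 1), nr - 1); fr <- pmin(pmax(ri - r0, 0), 1)
    val[!far] <-
      (1 - fr) * ((1 - fc) * gk$H[cbind(r0, c0)] +
                    fc * gk$H[cbind(r0, c0 + 1)]) +
      fr * ((1 - fc) * gk$H[cbind(r0 + 1, c0)] +
              fc * gk$H[cbind(r0 + 1, c0 + 1)])
  }
  val[off >= isis[k_of]] <- 0
  val[off < 0] <- 0
  agg <- rowsum(val, group = k_of)
  p1[as.integer(rownames(agg))] <- agg[, 1]
  p1
}

# per-ISI corrections for an alpha trajectory: quadrature of the Green
# rows against the global mu1 series at the pulse-time nodes.  The
# (tau-independent) absolute-time index matrix is precomputed once.
.p1_alpha_prep <- function(gk, tr) {
  htp <- gk$t_p[2] - gk$t_p[1]
  t_end <- max(tr) + 1
  n <- as.integer(ceiling(t_end / htp)) + 2L
  tk <- tr[-length(tr)]
  idx <- outer(tk, gk$t_p, "+") / htp + 1
  idx <- matrix(pmin(pmax(round(idx), 1), n), nrow = length(tk))
  list(idx = idx, htp = htp, n = n)
}

.p1_alpha_isi <- function(gk, rows, tr, tau, trig, prep = NULL) {
  if (is.null(prep)) prep <- .p1_alpha_prep(gk, tr)
  series <- .mu1_alpha_series(trig, prep$n, prep$htp, tau)
  U <- matrix(series[prep$idx], nrow = nrow(prep$idx))
  out <- rowSums(rows * U) * prep$htp
  # same-step boundary term: the absorbed flux responds instantaneously
  # to the mean input at the spike time
  isis <- diff(tr)
  i_spk <- pmin(pmax(round(tr[-1] / prep$htp) + 1, 1), prep$n)
  out + gk$dflux_ratio *
    .interp_density(gk$p0$s, gk$p0$density, isis) * series[i_spk]
}

#' Fit an input perturbation triggered at known times
#'
#' Estimates the perturbation strength `J` together with the kernel shape
#' parameter (`tau` for alpha kernels, delay `d` for delta pulses) from a
#' spike train and the trigger times.
#'
#' Two likelihood routes are available. `fp_perturbative`
#' expands each conditioned spike-time likelihood to first order in `J`,
#' using a precomputed delta-pulse Green kernel of the Fokker-Planck
#' system at the background parameters; alpha trajectories are handled by
#' linearity (quadrature of the kernel against `mu1`). `rate_model`
#' evaluates the inhomogeneous-Poisson likelihood with the cascade rate
#' model integrated over the whole recording.
#'
#' The background `(mu0, sigma)` is held fixed during the perturbation
#' fit: pass it in `background`, or it is first estimated from the same
#' spike train with the renewal likelihood (the perturbation contributes
#' little bias to that step when |J| is small).
#'
#' @param spikes spike times (vector or single-train [spike_data()])
#' @param triggers perturbation onset times, ms
#' @param kernel_kind `"alpha"` or `"delta"`
#' @param method `"fp_perturbative"` or `"rate_model"`
#' @param params [neuron_params()]
#' @param background optional list with `mu0` and `sigma`
#' @param grid optional [fp_grid()] for the Fokker-Planck solves
#' @param tp_step pulse-time spacing of the Green table, ms
#' @param tables optional [build_lnexp_tables()] for `rate_model`
#' @param green optional precomputed [fp_green_kernel()] at the background
#'   parameters (shared across fits in simulation protocols)
#' @param rate_dt rate-model integration step, ms
#' @param start,control optimizer settings
#' @return a `fit_result` with estimates `J` and `tau` (or `d`), the
#'   background used, and the log-likelihood gain over `J = 0`
#' @export
fit_perturbation <- function(spikes, triggers,
                             kernel_kind = c("alpha", "delta"),
                             method = c("fp_perturbative", "rate_model"),
                             params = neuron_params(), background = NULL,
                             grid = NULL, tp_step = NULL, tables = NULL,
                             green = NULL, rate_dt = 0.2, start = list(),
                             control = list()) {
  kernel_kind <- match.arg(kernel_kind)
  method <- match.arg(method)
  tr <- .as_train(spikes)
  stopifnot(length(tr) >= 3, length(triggers) >= 1)
  if (is.null(background)) {
    bg <- fit_background(tr, params)
    background <- list(mu0 = bg$estimates$mu, sigma = bg$estimates$sigma)
  }
  isis <- diff(tr)
  if (method == "fp_perturbative") {
    if (is.null(grid))
      grid <- fp_grid(s_max = min(max(isis) * 1.02 + 1, 800), dt = 0.05)
    if (is.null(tp_step))
      tp_step <- if (kernel_kind == "alpha") 0.2 else 0.25
    gk <- if (!is.null(green)) green else
      fp_green_kernel(params, background$mu0, background$sigma, grid,
                      tp_step = tp_step)
    p0 <- .interp_density(gk$p0$s, gk$p0$density, isis)
    p0 <- pmax(p0, .DENSITY_FLOOR)
    if (kernel_kind == "alpha") {
      rows <- .green_rows(gk, isis)
      prep <- .p1_alpha_prep(gk, tr)
      # profile likelihood in J per shape parameter (concave hybrid link)
      prof <- function(p1) {
        pr <- .fit_J_profile(p0, p1)
        list(J = pr$J, nll = -sum(log(p0)) - pr$gain)
      }
      nll <- function(x) {
        tau <- exp(x[1])
        if (tau < 2 || tau > 50) return(1e10)
        p1 <- .p1_alpha_isi(gk, rows, tr, tau, triggers, prep)
        prof(p1)$nll
      }
      x0 <- log(if (!is.null(start$tau)) start$tau else 10)
      shape_from <- function(x) list(tau = exp(x[1]))
      p1_of <- function(shape) .p1_alpha_isi(gk, rows, tr, shape$tau,
                                             triggers, prep)
    } else {
      prof <- function(p1) {
        pr <- .fit_J_profile(p0, p1)
        list(J = pr$J, nll = -sum(log(p0)) - pr$gain)
      }
      nll <- function(x) {
        d <- x[1]
        if (d < 0.05 || d > 20) return(1e10)
        prof(.p1_delta_isi(gk, tr, triggers + d))$nll
      }
      x0 <- if (!is.null(start$d)) start$d else 1
      shape_from <- function(x) list(d = x[1])
      p1_of <- function(shape) .p1_delta_isi(gk, tr, triggers + shape$d)
    }
    ll0 <- sum(log(p0))
    # 1-D search over the shape parameter with J profiled out
    if (kernel_kind == "delta") {
      dg <- seq(0.1, 10, by = 0.1)
      nv <- vapply(dg, function(d) nll(d), numeric(1))
      i0 <- which.min(nv)
      o <- stats::optimize(nll, c(dg[max(1, i0 - 1)],
                                  dg[min(length(dg), i0 + 1)]),
                           tol = 1e-3)
    } else {
      o <- stats::optimize(nll, log(c(2, 50)), tol = 2e-3)
    }
    shape <- shape_from(o$minimum)
    pj <- prof(p1_of(shape))
    est <- c(list(J = pj$J), shape)
    ll <- -pj$nll
    return(structure(list(estimates = est, loglik = ll,
                          n_isi = length(isis),
                          aic = 2 * 2 - 2 * ll,
                          convergence = 0L, method = method,
                          kernel_kind = kernel_kind,
                          background = background,
                          loglik_gain = ll - ll0),
                     class = "fit_result"))
  } else {
    t_end <- max(c(tr, triggers)) + 20
    t_grid <- seq(0, t_end, by = rate_dt)
    if (is.null(tables)) {
      mu_lo <- min(background$mu0 - 1.5, -0.5)
      mu_hi <- background$mu0 + 2.5
      tables <- build_lnexp_tables(params, background$sigma,
                                   seq(mu_lo, mu_hi, by = 0.1))
    }
    n <- length(t_grid)
    rate_ll <- function(mu_series) {
      r <- integrate_rate(tables, mu_series, t_grid)
      as.numeric(poisson_loglik(tr, r))
    }
    if (kernel_kind == "alpha") {
      nll <- function(x) {
        J <- x[1]; tau <- exp(x[2])
        if (tau < 2 || tau > 50) return(1e10)
        mu1 <- .mu1_alpha_series(triggers, n, rate_dt, tau)
        tryCatch(-rate_ll(background$mu0 + J * mu1),
                 error = function(e) 1e10)
      }
      x0 <- c(if (!is.null(start$J)) start$J else 0,
              log(if (!is.null(start$tau)) start$tau else 10))
    } else {
      nll <- function(x) {
        J <- x[1]; d <- x[2]
        if (d < 0.05 || d > 20) return(1e10)
        idx <- round((triggers + d) / rate_dt) + 1
        mu1 <- numeric(n)
        tb <- tabulate(idx[idx >= 1 & idx <= n], nbins = n)
        mu1 <- tb / rate_dt
        tryCatch(-rate_ll(background$mu0 + J * mu1),
                 error = function(e) 1e10)
      }
      x0 <- c(if (!is.null(start$J)) start$J else 0,
              if (!is.null(start$d)) start$d else 1)
    }
    ll0 <- rate_ll(rep(background$mu0, n))
  }
  ctl <- utils::modifyList(list(maxit = 300, reltol = 1e-6), control)
  opt <- stats::optim(x0, nll, method = "Nelder-Mead", control = ctl)
  est <- list(J = opt$par[1])
  if (kernel_kind == "alpha") est$tau <- exp(opt$par[2])
  else est$d <- opt$par[2]
  ll <- -opt$value
  structure(list(estimates = est, loglik = ll, n_isi = length(isis),
                 aic = 2 * 2 - 2 * ll, convergence = opt$convergence,
                 counts = opt$counts, method = method,
                 kernel_kind = kernel_kind, background = background,
                 loglik_gain = ll - ll0),
            class = "fit_result")
}

#' Trigger-aligned spike density (cross-correlogram)
#'
#' Gaussian-kernel density of spike-minus-trigger lags within a window,
#' normalized to unit integral over the window (truncation with
#' renormalization at the edges). Significance of the extremum is
#' assessed against surrogate curves, either supplied (`null_curves`) or
#' generated by uniformly jittering the triggers.
#'
#' @param spikes spike times (vector or single-train [spike_data()])
#' @param triggers event times, ms (at least 20 recommended)
#' @param kernel_sd Gaussian smoothing kernel width, ms
#' @param window lag window `c(lo, hi)`, ms, in which extrema are assessed
#' @param n_null number of jitter surrogates (ignored when `null_curves`
#'   is given)
#' @param jitter_width half-width of the uniform trigger jitter, ms
#' @param null_curves optional matrix of null curves (rows = surrogates)
#'   on the same lag grid
#' @param lag_step lag grid resolution, ms
#' @param seed RNG seed for the jitter surrogates
#' @return an object of class `trigger_ccg`: `lags`, `curve`, `extremum`,
#'   `extremum_lag`, `thresholds` (5th/95th percentile curves of the
#'   null extrema), `significant` (logical, two-sided), `z`
#' @export
trigger_ccg <- function(spikes, triggers, kernel_sd = 3,
                        window = c(0, 100), n_null = 100,
                        jitter_width = 100, null_curves = NULL,
                        lag_step = 1, seed = 1) {
  tr <- .as_train(spikes)
  if (length(triggers) < 20)
    message("fewer than 20 triggers; the CCG estimate will be noisy")
  lags <- seq(window[1], window[2], by = lag_step)
  # binned lag counts convolved with a Gaussian kernel (bin width well
  # below the kernel sd, so the approximation error is negligible)
  bin <- kernel_sd / 6
  pad <- 4 * kernel_sd
  edges <- seq(window[1] - pad, window[2] + pad + bin, by = bin)
  kern_x <- seq(-pad, pad, by = bin)
  kern <- stats::dnorm(kern_x, sd = kernel_sd)
  centers <- edges[-length(edges)] + bin / 2
  curve_of <- function(trig) {
    d <- outer(tr, trig, "-")
    d <- d[d >= window[1] - pad & d <= window[2] + pad]
    if (!length(d)) return(rep(0, length(lags)))
    counts <- tabulate(findInterval(d, edges), nbins = length(centers))
    sm <- stats::convolve(counts, rev(kern), type = "open")
    off <- (length(kern) - 1) / 2
    sm_c <- sm[(off + 1):(off + length(centers))]
    cv <- stats::approx(centers, sm_c, xout = lags, rule = 2)$y
    cv <- pmax(cv, 0)
    area <- sum(cv) * lag_step
    if (area > 0) cv / area else cv
  }
  curve <- curve_of(triggers)
  if (is.null(null_curves)) {
    set.seed(seed)
    null_curves <- t(vapply(seq_len(n_null), function(i) {
      jt <- sort(triggers + stats::runif(length(triggers), -jitter_width,
                                         jitter_width))
      curve_of(jt)
    }, numeric(length(lags))))
  }
  null_max <- apply(null_curves, 1, max)
  null_min <- apply(null_curves, 1, min)
  thr_hi <- stats::quantile(null_max, 0.95, names = FALSE)
  thr_lo <- stats::quantile(null_min, 0.05, names = FALSE)
  ext_idx <- which.max(abs(curve - mean(curve)))
  extremum <- curve[ext_idx]
  significant <- max(curve) > thr_hi || min(curve) < thr_lo
  z <- if (max(curve) >= 2 * mean(curve) - min(curve)) {
    (max(curve) - mean(null_max)) / stats::sd(null_max)
  } else {
    (min(curve) - mean(null_min)) / stats::sd(null_min)
  }
  structure(list(lags = lags, curve = curve, extremum = extremum,
                 extremum_lag = lags[ext_idx],
                 thresholds = c(lo = thr_lo, hi = thr_hi),
                 significant = significant, z = z,
                 n_triggers = length(triggers)),
            class = "trigger_ccg")
}

#' Detection sensitivity for weak input perturbations
#'
#' Simulation protocol: for each perturbation strength `J`, `n_rep_model`
#' spike trains are simulated with alpha-kernel perturbations at random
#' trigger times; `J` is re-estimated by the model-based methods, and
#' sensitivity is the fraction of estimates beyond the 95th (J > 0) or
#' below the 5th (J < 0) percentile of estimates obtained from matched
#' unperturbed simulations. The model-free reference computes
#' trigger-aligned CCGs from `n_rep_ccg` realizations and compares their
#' extrema in the `[0, 100]` ms window against unperturbed realizations.
#' The background parameters are treated as known (fixed at the simulated
#' truth), isolating the detection step.
#'
#' @param scenario list with the simulation settings: `params`
#'   ([neuron_params()]), `mu0`, `sigma`, `duration` (ms), `tau` (alpha
#'   time constant, ms), `trigger_mean_gap`, `trigger_sd_gap` (ms)
#' @param J_values nonzero perturbation strengths to probe, mV/ms
#' @param methods subset of `c("fp_perturbative", "rate_model", "ccg")`
#' @param n_rep_model realizations per J for the model-based methods
#' @param n_rep_ccg realizations per J for the CCG method
#' @param seed integer RNG seed
#' @param sim_dt simulation step, ms
#' @return data.frame with columns `J`, `method`, `sensitivity` (plus the
#'   `J = 0` null rows giving the realized false-positive fraction)
#' @export
detection_sensitivity <- function(scenario, J_values,
                                  methods = c("fp_perturbative",
                                              "rate_model", "ccg"),
                                  n_rep_model = 50, n_rep_ccg = 300,
                                  seed = 1, sim_dt = 0.02) {
  sc <- utils::modifyList(
    list(params = neuron_params(), mu0 = 1.75, sigma = 2.5,
         duration = 1e5, tau = 10, trigger_mean_gap = 200,
         trigger_sd_gap = 50), scenario)
  stopifnot(all(J_values != 0))
  base_seed <- seed
  sim_cache <- new.env(parent = emptyenv())
  sim_one <- function(J, rep_seed) {
    key <- sprintf("%g_%d", J, rep_seed)
    if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
    trig <- generate_trigger_times(sc$duration, sc$trigger_mean_gap,
                                   sc$trigger_sd_gap, seed = rep_seed)
    n_steps <- ceiling(sc$duration / sim_dt)
    mu1 <- if (J != 0)
      .mu1_alpha_series(trig, n_steps, sim_dt, sc$tau) else NULL
    mu_series <- if (is.null(mu1)) NULL else sc$mu0 + J * mu1
    sdat <- simulate_neuron(sc$params, input_model(sc$mu0, sc$sigma),
                            sc$duration, dt = sim_dt, seed = rep_seed + 1,
                            mu_series = mu_series)
    out <- list(spikes = sdat$trains[[1]], triggers = trig)
    sim_cache[[key]] <- out
    out
  }
  model_methods <- intersect(methods, c("fp_perturbative", "rate_model"))
  out <- list()
  if (length(model_methods)) {
    # shared precomputations at the true background
    grid <- fp_grid(s_max = 250, dt = 0.05)
    gk <- if ("fp_perturbative" %in% model_methods)
      fp_green_kernel(sc$params, sc$mu0, sc$sigma, grid, tp_step = 0.4)
    tabs <- if ("rate_model" %in% model_methods)
      build_lnexp_tables(sc$params, sc$sigma,
                         seq(min(sc$mu0 - 1.5, -0.5), sc$mu0 + 2.5,
                             by = 0.1))
    est_J <- function(dat, method) {
      f <- fit_perturbation(dat$spikes, dat$triggers, "alpha", method,
                            sc$params,
                            background = list(mu0 = sc$mu0,
                                              sigma = sc$sigma),
                            tables = tabs, green = gk,
                            control = list(reltol = 1e-4, maxit = 120))
      f$estimates$J
    }
    for (method in model_methods) {
      nulls <- vapply(seq_len(n_rep_model), function(i)
        est_J(sim_one(0, base_seed + 97L * i), method), numeric(1))
      qs <- stats::quantile(nulls, c(0.05, 0.95), names = FALSE)
      for (J in c(0, J_values)) {
        ests <- if (J == 0) {
          vapply(seq_len(n_rep_model), function(i)
            est_J(sim_one(0, base_seed + 131L * i + 7L), method),
            numeric(1))
        } else {
          vapply(seq_len(n_rep_model), function(i)
            est_J(sim_one(J, base_seed + 211L * i + round(1000 * abs(J))),
                  method), numeric(1))
        }
        sens <- if (J > 0) mean(ests > qs[2])
        else if (J < 0) mean(ests < qs[1])
        else mean(ests > qs[2] | ests < qs[1]) / 2 + 0  # two one-sided
        out[[length(out) + 1]] <-
          data.frame(J = J, method = method, sensitivity = sens)
      }
    }
  }
  if ("ccg" %in% methods) {
    lags <- seq(0, 100, by = 1)
    curve_of <- function(dat) {
      cc <- trigger_ccg(dat$spikes, dat$triggers, kernel_sd = 3,
                        window = c(0, 100),
                        null_curves = matrix(0, 2, length(lags)))
      cc$curve
    }
    null_curves <- t(vapply(seq_len(n_rep_ccg), function(i)
      curve_of(sim_one(0, base_seed + 301L * i)), numeric(length(lags))))
    hi <- stats::quantile(apply(null_curves, 1, max), 0.95, names = FALSE)
    lo <- stats::quantile(apply(null_curves, 1, min), 0.05, names = FALSE)
    for (J in c(0, J_values)) {
      curves <- t(vapply(seq_len(n_rep_ccg), function(i)
        curve_of(sim_one(J, base_seed + 401L * i + round(1000 * abs(J)))),
        numeric(length(lags))))
      sens <- if (J > 0) mean(apply(curves, 1, max) > hi)
      else if (J < 0) mean(apply(curves, 1, min) < lo)
      else (mean(apply(curves, 1, max) > hi) +
              mean(apply(curves, 1, min) < lo)) / 2
      out[[length(out) + 1]] <-
        data.frame(J = J, method = "ccg", sensitivity = sens)
    }
  }
  do.call(rbind, out)
}

#' Cross-validated detection time for a synaptic-style perturbation
#'
#' Splits the recording into `folds` contiguous blocks; for increasing
#' total data length, the perturbed (`J` free) and unperturbed (`J = 0`)
#' models are fitted on the training blocks and compared by their summed
#' log-likelihood ratio on the held-out blocks. The detection time is the
#' smallest length with a positive test log-likelihood ratio; `NA` (a
#' miss) if none is positive.
#'
#' @param post_spikes postsynaptic spike times, ms
#' @param triggers presynaptic spike / event times, ms
#' @param kernel_kind,method,params as in [fit_perturbation()]
#' @param folds number of contiguous cross-validation blocks
#' @param segment_grid increasing data lengths to evaluate, ms
#' @return list with `detection_time` (ms or `NA`), and a data.frame
#'   `llr` (length, summed test log-likelihood ratio)
#' @export
detection_time <- function(post_spikes, triggers,
                           kernel_kind = c("delta", "alpha"),
                           method = c("fp_perturbative", "rate_model"),
                           params = neuron_params(), folds = 10,
                           segment_grid = NULL) {
  kernel_kind <- match.arg(kernel_kind)
  method <- match.arg(method)
  tr <- .as_train(post_spikes)
  t_end <- max(tr)
  if (is.null(segment_grid))
    segment_grid <- seq(t_end / 5, t_end, length.out = 5)
  res <- lapply(segment_grid, function(L) {
    tr_L <- tr[tr <= L]
    trig_L <- triggers[triggers <= L]
    if (length(tr_L) < 5 * folds) return(c(L, NA))
    edges <- seq(0, L, length.out = folds + 1)
    llr <- 0
    for (f in seq_len(folds)) {
      test_win <- edges[c(f, f + 1)]
      train_tr <- tr_L[tr_L < test_win[1] | tr_L > test_win[2]]
      test_tr <- tr_L[tr_L >= test_win[1] & tr_L <= test_win[2]]
      if (length(test_tr) < 3 || length(train_tr) < 10) next
      # the train data have a hole at the test block; cap the solver
      # horizon so the hole-spanning ISI does not blow up the grids
      isis_tr <- diff(train_tr)
      s_cap <- min(max(isis_tr) * 1.02 + 1,
                   stats::quantile(isis_tr, 0.99) * 2 + 50)
      grid_tr <- fp_grid(s_max = s_cap, dt = 0.05)
      bg <- fit_background(isis_as_sample(isis_tr[isis_tr < s_cap]),
                           params, grid = grid_tr)
      bgl <- list(mu0 = bg$estimates$mu, sigma = bg$estimates$sigma)
      fitJ <- fit_perturbation(train_tr, trig_L, kernel_kind, method,
                               params, background = bgl, grid = grid_tr,
                               control = list(reltol = 1e-4, maxit = 150))
      # evaluate both models on the held-out block
      isis_test <- diff(test_tr)
      grid <- fp_grid(s_max = min(max(isis_test) * 1.02 + 1, s_cap + 100),
                      dt = 0.05)
      gk <- fp_green_kernel(params, bgl$mu0, bgl$sigma, grid,
                            tp_step = 0.5)
      p0 <- pmax(.interp_density(gk$p0$s, gk$p0$density, isis_test),
                 .DENSITY_FLOOR)
      p1 <- if (kernel_kind == "delta")
        .p1_delta_isi(gk, test_tr, trig_L + fitJ$estimates$d)
      else .p1_alpha_isi(gk, .green_rows(gk, isis_test), test_tr,
                         fitJ$estimates$tau, trig_L)
      llr <- llr +
        sum(log(pmax(p0 + fitJ$estimates$J * p1, .DENSITY_FLOOR))) -
        sum(log(p0))
    }
    c(L, llr)
  })
  df <- as.data.frame(do.call(rbind, res))
  names(df) <- c("length_ms", "llr")
  pos <- which(is.finite(df$llr) & df$llr > 0)
  list(detection_time = if (length(pos)) df$length_ms[min(pos)] else NA,
       llr = df)
}
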