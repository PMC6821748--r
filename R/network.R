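# Pairwise synaptic-coupling inference for (sub)sampled networks.
#
# Two-step procedure justified by weak coupling: background input
# statistics are first estimated for every neuron in isolation (all
# couplings zero), then the strength and delay of each ordered pair are
# estimated with the first-order (perturbative) likelihood, holding the
# backgrounds fixed. Presynaptic spikes act as delayed delta-pulse
# perturbation triggers for the postsynaptic neuron.

#' Estimate background inputs for every neuron
#'
#' Constant mode fits `(mu, sigma)` per neuron with the renewal
#' Fokker-Planck likelihood. Time-varying mode follows the three-step
#' in-vivo procedure: the instantaneous spike rate is estimated by
#' Gaussian kernel density estimation (width `sigma_G`, reflected at the
#' recording edges), inverted through the stationary rate curve to a
#' per-ISI mean input (evaluated at the center between consecutive
#' spikes), and the noise amplitude is then fitted by likelihood
#' maximization given that mean-input track.
#'
#' @param data [spike_data()] with one train per neuron
#' @param mode `"constant"` or `"time_varying"`
#' @param sigma_G rate-smoothing kernel width, seconds (time-varying mode;
#'   the protocol variants use 0.1, 0.5 or 1 s)
#' @param params [neuron_params()]
#' @param min_isis minimum number of ISIs required per neuron
#' @return list of background tracks, one per neuron: `mu` (scalar or
#'   per-ISI vector), `sigma`, `loglik`
#' @export
fit_backgrounds <- function(data, mode = c("constant", "time_varying"),
                            sigma_G = 0.5, params = neuron_params(),
                            min_isis = 50) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "spike_data"))
  lapply(data$trains, function(tr) {
    if (length(tr) - 1 < min_isis)
      stop(sprintf("a train has fewer than %d ISIs", min_isis))
    if (mode == "constant") {
      f <- fit_background(tr, params)
      list(mu = f$estimates$mu, sigma = f$estimates$sigma,
           loglik = f$loglik, mode = mode)
    } else {
      .fit_background_track(tr, data$t_span, sigma_G * 1000, params)
    }
  })
}

# time-varying background: KDE rate inversion + sigma likelihood fit
.fit_background_track <- function(tr, t_span, bw_ms, params) {
  isis <- diff(tr)
  centers <- (tr[-1] + tr[-length(tr)]) / 2
  # Gaussian KDE with boundary reflection
  T0 <- t_span[1]; T1 <- t_span[2]
  aug <- c(tr, 2 * T0 - tr, 2 * T1 - tr)
  rate_at <- vapply(centers, function(tt)
    sum(stats::dnorm(tt - aug, sd = bw_ms)), numeric(1))  # spikes/ms
  mu_try <- seq(-0.9, 4.9, length.out = 40)
  nll_sigma <- function(lsig) {
    sig <- exp(lsig)
    rr <- .rinf_curve(params, mu_try, sig, n_V = 400)
    mu_k <- stats::approx(rr, mu_try, xout = rate_at, rule = 2,
                          ties = "ordered")$y
    tab <- precompute_isi_tables(params, sig,
                                 seq(min(mu_k) - 0.05, max(mu_k) + 0.05,
                                     length.out = 12),
                                 fp_grid(s_max = max(isis) * 1.02 + 1,
                                         dt = 0.1, n_V = 200))
    dens <- isi_table_density(tab, mu_k, isis)
    list(nll = -sum(log(pmax(dens, .DENSITY_FLOOR))), mu_k = mu_k)
  }
  opt <- stats::optimize(function(x) nll_sigma(x)$nll, log(c(0.3, 5.5)))
  best <- nll_sigma(opt$minimum)
  list(mu = best$mu_k, sigma = exp(opt$minimum), loglik = -best$nll,
       rate = rate_at, mode = "time_varying", sigma_G = bw_ms / 1000)
}

# Green-kernel context for one postsynaptic neuron: for constant
# backgrounds a single kernel; for a per-ISI mean-input track, kernels at
# a few quantile nodes of mu with linear interpolation between them
.coupling_context <- function(post_tr, background, params, grid, tp_step) {
  isis <- diff(post_tr)
  if (length(background$mu) == 1) {
    gk <- fp_green_kernel(params, background$mu, background$sigma, grid,
                          tp_step = tp_step)
    p0 <- pmax(.interp_density(gk$p0$s, gk$p0$density, isis),
               .DENSITY_FLOOR)
    list(kernels = list(gk), weights = matrix(1, length(isis), 1),
         idx = matrix(1L, length(isis), 2), p0 = p0)
  } else {
    mu_k <- background$mu
    nodes <- unique(stats::quantile(mu_k, c(0.05, 0.3, 0.5, 0.7, 0.95),
                                    names = FALSE))
    kernels <- lapply(nodes, function(m)
      fp_green_kernel(params, m, background$sigma, grid,
                      tp_step = tp_step))
    j <- pmin(pmax(findInterval(mu_k, nodes), 1L),
              max(length(nodes) - 1L, 1L))
    hi <- pmin(j + 1L, length(nodes))
    u <- if (length(nodes) > 1)
      (mu_k - nodes[j]) / pmax(nodes[hi] - nodes[j], 1e-12) else
        rep(0, length(mu_k))
    u <- pmin(pmax(u, 0), 1)
    p0_nodes <- vapply(kernels, function(gk)
      .interp_density(gk$p0$s, gk$p0$density, isis),
      numeric(length(isis)))
    if (!is.matrix(p0_nodes)) p0_nodes <- matrix(p0_nodes, nrow = length(isis))
    k <- seq_along(isis)
    p0 <- (1 - u) * p0_nodes[cbind(k, j)] + u * p0_nodes[cbind(k, hi)]
    list(kernels = kernels, weights = cbind(1 - u, u),
         idx = cbind(j, hi), p0 = pmax(p0, .DENSITY_FLOOR))
  }
}

# per-ISI delta-pulse correction under a coupling context
.p1_delta_ctx <- function(ctx, post_tr, pulses) {
  if (length(ctx$kernels) == 1)
    return(.p1_delta_isi(ctx$kernels[[1]], post_tr, pulses))
  vals <- vapply(ctx$kernels, function(gk)
    .p1_delta_isi(gk, post_tr, pulses), numeric(length(post_tr) - 1))
  k <- seq_len(length(post_tr) - 1)
  ctx$weights[, 1] * vals[cbind(k, ctx$idx[, 1])] +
    ctx$weights[, 2] * vals[cbind(k, ctx$idx[, 2])]
}

#' Fit the coupling strength and delay of one ordered pair
#'
#' Maximizes the first-order pairwise likelihood over `(J, d)`: each
#' presynaptic spike adds a delayed delta-pulse perturbation to the
#' postsynaptic mean input, whose first-order effect on every conditioned
#' spike-time likelihood is read from a precomputed Green kernel. The
#' delay is profiled on a grid (`d_range`, step `d_step`) with the
#' strength optimized per delay, followed by a local refinement.
#'
#' @param post_spikes,pre_spikes spike times of the postsynaptic and
#'   presynaptic neuron, ms
#' @param background background track of the postsynaptic neuron (an
#'   element of [fit_backgrounds()] output)
#' @param params [neuron_params()]
#' @param d_range delay search interval, ms
#' @param d_step profiling step, ms
#' @param grid optional [fp_grid()]
#' @param tp_step Green-kernel pulse-time spacing, ms
#' @param context optional precomputed coupling context (shared across
#'   pairs with the same postsynaptic neuron)
#' @return an object of class `coupling_estimate`: `J_hat`, `d_hat`,
#'   `loglik_gain` (coupled minus uncoupled log-likelihood)
#' @export
fit_coupling_pair <- function(post_spikes, pre_spikes, background,
                              params = neuron_params(),
                              d_range = c(0.1, 10), d_step = 0.1,
                              grid = NULL, tp_step = 0.25,
                              context = NULL) {
  post_tr <- .as_train(post_spikes)
  pre_tr <- .as_train(pre_spikes)
  isis <- diff(post_tr)
  if (is.null(grid))
    grid <- fp_grid(s_max = max(isis) * 1.02 + 1, dt = 0.05)
  if (is.null(context))
    context <- .coupling_context(post_tr, background, params, grid,
                                 tp_step)
  p0 <- context$p0
  ll0 <- sum(log(p0))
  prof_J <- function(d) {
    q <- .p1_delta_ctx(context, post_tr, pre_tr + d)
    pr <- .fit_J_profile(p0, q)
    list(J = pr$J, ll = ll0 + pr$gain)
  }
  d_grid <- seq(d_range[1], d_range[2], by = d_step)
  prof <- lapply(d_grid, prof_J)
  lls <- vapply(prof, function(p) p$ll, numeric(1))
  i_best <- which.max(lls)
  # local refinement of the delay around the best grid node
  d_lo <- d_grid[max(1, i_best - 1)]
  d_hi <- d_grid[min(length(d_grid), i_best + 1)]
  o_d <- stats::optimize(function(d) -prof_J(d)$ll, c(d_lo, d_hi),
                         tol = 1e-3)
  best <- prof_J(o_d$minimum)
  structure(list(J_hat = best$J, d_hat = o_d$minimum,
                 loglik_gain = best$ll - ll0,
                 loglik = best$ll, n_isi = length(isis)),
            class = "coupling_estimate")
}

#' Infer all pairwise couplings of a recorded population
#'
#' Two-step estimation: [fit_backgrounds()] per neuron, then
#' [fit_coupling_pair()] for every ordered pair (2 N^2 parameters in
#' total for N neurons). Results are independent of the order in which
#' pairs are processed.
#'
#' @param data [spike_data()] with one train per neuron
#' @param mode background mode, see [fit_backgrounds()]
#' @param params [neuron_params()]
#' @param sigma_G rate-smoothing width, s (time-varying mode)
#' @param d_range,d_step delay search settings
#' @param tp_step Green-kernel pulse-time spacing, ms
#' @param backgrounds optional precomputed [fit_backgrounds()] output
#' @return an object of class `network_fit`: matrices `J` and `d`
#'   (row = postsynaptic, column = presynaptic, diagonal `NA`),
#'   `backgrounds`, and the per-pair `loglik_gain` matrix
#' @export
infer_network <- function(data, mode = "constant",
                          params = neuron_params(), sigma_G = 0.5,
                          d_range = c(0.1, 10), d_step = 0.1,
                          tp_step = 0.25, backgrounds = NULL) {
  stopifnot(inherits(data, "spike_data"))
  N <- length(data$trains)
  stopifnot(N >= 2)
  if (is.null(backgrounds))
    backgrounds <- fit_backgrounds(data, mode, sigma_G, params)
  J <- matrix(NA_real_, N, N); d <- matrix(NA_real_, N, N)
  gain <- matrix(NA_real_, N, N)
  failures <- list()
  for (i in seq_len(N)) {
    post_tr <- data$trains[[i]]
    grid <- fp_grid(s_max = max(diff(post_tr)) * 1.02 + 1, dt = 0.05)
    ctx <- .coupling_context(post_tr, backgrounds[[i]], params, grid,
                             tp_step)
    for (j in seq_len(N)[-i]) {
      res <- tryCatch(
        fit_coupling_pair(post_tr, data$trains[[j]], backgrounds[[i]],
                          params, d_range, d_step, grid, tp_step,
                          context = ctx),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[sprintf("%d<-%d", i, j)]] <- conditionMessage(res)
      } else {
        J[i, j] <- res$J_hat; d[i, j] <- res$d_hat
        gain[i, j] <- res$loglik_gain
      }
    }
  }
  structure(list(J = J, d = d, loglik_gain = gain,
                 backgrounds = backgrounds, mode = mode,
                 failures = failures, data = data, params = params,
                 d_range = d_range, d_step = d_step, tp_step = tp_step),
            class = "network_fit")
}

# re-estimate all couplings with jittered presynaptic spike times,
# reusing the fitted backgrounds; returns the matrix of jitter estimates
.jitter_reestimate <- function(fit, jitter) {
  data <- fit$data; N <- length(data$trains)
  Jm <- matrix(NA_real_, N, N)
  for (i in seq_len(N)) {
    post_tr <- data$trains[[i]]
    grid <- fp_grid(s_max = max(diff(post_tr)) * 1.02 + 1, dt = 0.05)
    ctx <- .coupling_context(post_tr, fit$backgrounds[[i]], fit$params,
                             grid, fit$tp_step)
    for (j in seq_len(N)[-i]) {
      pre <- sort(data$trains[[j]] +
                    stats::runif(length(data$trains[[j]]), -jitter,
                                 jitter))
      res <- tryCatch(
        fit_coupling_pair(post_tr, pre, fit$backgrounds[[i]], fit$params,
                          fit$d_range, fit$d_step, grid, fit$tp_step,
                          context = ctx),
        error = function(e) NULL)
      if (!is.null(res)) Jm[i, j] <- res$J_hat
    }
  }
  Jm
}

#' Jitter-based bias correction of coupling estimates
#'
#' Presynaptic spike times are perturbed by a uniform temporal jitter
#' (default +-10 ms), masking transient synaptic effects while preserving
#' slower co-modulation; couplings are re-estimated on the surrogates and
#' the network-wide average of the surrogate estimates (a single scalar)
#' is subtracted from every original estimate.
#'
#' @param fit a `network_fit` from [infer_network()]
#' @param jitter jitter half-width, ms
#' @param n_rep number of surrogate realizations
#' @param seed integer RNG seed
#' @return the `network_fit` with corrected `J`, plus fields `bias` and
#'   `J_raw`
#' @export
bias_correct <- function(fit, jitter = 10, n_rep = 3, seed = 1) {
  stopifnot(inherits(fit, "network_fit"))
  set.seed(seed)
  reps <- lapply(seq_len(n_rep), function(r) .jitter_reestimate(fit, jitter))
  bias <- mean(unlist(lapply(reps, function(m) m[is.finite(m)])))
  fit$J_raw <- fit$J
  fit$J <- fit$J - bias
  fit$bias <- bias
  fit
}

#' Coupling-strength z-scores from jitter surrogates
#'
#' For each ordered pair, the presynaptic spike times are jittered
#' (default +-5 ms, the in-vivo protocol; use +-10 ms elsewhere) and the
#' coupling re-estimated `n_rep` times;
#' `z = (J_hat - mean(null)) / sd(null)`.
#'
#' @inheritParams bias_correct
#' @param jitter jitter half-width, ms
#' @param n_rep surrogate realizations per pair
#' @return matrix of z-scores (`NA` diagonal); pairs with zero surrogate
#'   spread yield `NA` with a warning
#' @export
coupling_zscores <- function(fit, jitter = 5, n_rep = 100, seed = 1) {
  stopifnot(inherits(fit, "network_fit"))
  set.seed(seed)
  reps <- lapply(seq_len(n_rep), function(r) .jitter_reestimate(fit, jitter))
  arr <- simplify2array(reps)          # N x N x n_rep
  mu_null <- apply(arr, c(1, 2), mean)
  sd_null <- apply(arr, c(1, 2), stats::sd)
  z <- (fit$J - mu_null) / sd_null
  if (any(sd_null[is.finite(sd_null)] == 0))
    warning("zero surrogate spread for some pair(s); z set to NA")
  z[!is.finite(z)] <- NA_real_
  diag(z) <- NA_real_
  z
}

#' Cross-correlogram z-score baseline for connection detection
#'
#' For each ordered pair, the spike-train cross-correlogram (counts of
#' postsynaptic-minus-presynaptic lags in bins over `(0, lag_max]`) is
#' compared with surrogates obtained by jittering the presynaptic train;
#' the reported score is the z-score of the bin deviating most strongly
#' from its surrogate distribution (signed, so excitatory and inhibitory
#' connections give opposite signs).
#'
#' @param data [spike_data()]
#' @param jitter jitter half-width, ms
#' @param n_rep surrogate realizations
#' @param lag_max maximal positive lag, ms
#' @param bin bin width, ms
#' @param seed integer RNG seed
#' @return matrix of z-scores (`NA` diagonal)
#' @export
ccg_zscore_baseline <- function(data, jitter = 10, n_rep = 100,
                                lag_max = 10, bin = 0.5, seed = 1) {
  stopifnot(inherits(data, "spike_data"))
  N <- length(data$trains)
  breaks <- seq(0, lag_max, by = bin)
  counts_of <- function(post, pre) {
    idx <- findInterval(post, pre)       # last pre spike before each post
    out <- numeric(length(breaks) - 1)
    # accumulate lags to the few preceding presynaptic spikes
    for (back in 0:3) {
      ii <- idx - back
      ok <- ii >= 1
      if (!any(ok)) break
      lag <- post[ok] - pre[ii[ok]]
      keep <- lag > 0 & lag <= lag_max
      if (any(keep))
        out <- out + tabulate(findInterval(lag[keep], breaks,
                                           rightmost.closed = TRUE),
                              nbins = length(out))
    }
    out
  }
  set.seed(seed)
  z <- matrix(NA_real_, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)[-i]) {
    post <- data$trains[[i]]; pre <- data$trains[[j]]
    obs <- counts_of(post, pre)
    nulls <- vapply(seq_len(n_rep), function(r)
      counts_of(post, sort(pre + stats::runif(length(pre), -jitter,
                                              jitter))),
      numeric(length(obs)))
    mu0 <- rowMeans(nulls)
    sd0 <- apply(nulls, 1, stats::sd)
    sd0[sd0 == 0] <- NA
    zb <- (obs - mu0) / sd0
    z[i, j] <- zb[which.max(abs(zb))]
  }
  z
}

#' Connection-detection metrics against ground truth
#'
#' Sweeps a discrimination threshold over |score| (estimated strength or
#' z-score): a pair is called connected when its absolute score exceeds
#' the threshold. Reports the ROC curve and the maxima of accuracy and
#' balanced accuracy.
#'
#' @param scores matrix of estimated strengths or z-scores (diagonal
#'   ignored)
#' @param truth_J true coupling matrix (nonzero = connection present)
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`, `acc`,
#'   `bacc`), `auc`, `max_acc`, `max_bacc` and the achieving thresholds
#' @export
detection_metrics <- function(scores, truth_J) {
  stopifnot(all(dim(scores) == dim(truth_J)))
  off <- row(scores) != col(scores)
  s <- abs(scores[off]); lab <- truth_J[off] != 0
  ok <- is.finite(s)
  s <- s[ok]; lab <- lab[ok]
  P <- sum(lab); Ng <- sum(!lab)
  if (P == 0 || Ng == 0)
    stop("both connected and unconnected pairs are required")
  thr <- c(sort(unique(s)) - 1e-12, max(s) + 1)
  roc <- do.call(rbind, lapply(thr, function(th) {
    TP <- sum(s > th & lab); TN <- sum(s <= th & !lab)
    data.frame(threshold = th, fpr = (Ng - TN) / Ng, tpr = TP / P,
               acc = (TP + TN) / (P + Ng),
               bacc = (TP / P + TN / Ng) / 2)
  }))
  roc <- roc[order(roc$fpr, roc$tpr), ]
  auc <- sum(diff(c(0, roc$fpr, 1)) *
               (c(roc$tpr, 1) + c(0, roc$tpr)) / 2)
  list(roc = roc, auc = auc,
       max_acc = max(roc$acc),
       max_bacc = max(roc$bacc),
       thr_acc = roc$threshold[which.max(roc$acc)],
       thr_bacc = roc$threshold[which.max(roc$bacc)])
}
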