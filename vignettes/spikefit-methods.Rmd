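---
title: "Likelihood-based inference for integrate-and-fire circuits: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based inference for integrate-and-fire circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and the inference problem

spikefit estimates mechanistic spiking-neuron models from nothing but
observed spike times. The generative model is the leaky
integrate-and-fire (I&F) neuron driven by Gaussian white noise,

$$\frac{dV}{dt} = -\frac{V}{\tau_m} + \mu(t) + \sigma\,\xi(t), \qquad
V \ge V_s \;\Rightarrow\; V \leftarrow V_r,$$

with membrane time constant $\tau_m$, threshold $V_s$, reset $V_r$, mean
input $\mu(t)$ (mV/ms) and noise amplitude $\sigma$ (mV/$\sqrt{\mathrm{ms}}$).
An exponential spike-initiation term
$\Delta_T \exp((V-V_T)/\Delta_T)/\tau_m$ can be added. Because a common
shift/scaling of $(V_s, V_r)$ can be absorbed exactly into $(\mu, \sigma)$
(a linear change of variables of $V$), threshold and reset are fixed
conventions ($V_s = 30$ mV, $V_r = 0$) and only the input statistics and,
optionally, $\tau_m$ are estimated. Units are ms, mV, mV/ms and
mV/$\sqrt{\mathrm{ms}}$ throughout; rates are spikes/ms internally and
spikes/s in printed output.

For constant input statistics, spiking is a renewal process, and the
likelihood of a spike train $t_1 < \dots < t_K$ factorizes over
inter-spike intervals (ISIs) into conditioned spike-time likelihoods.
Each factor is the first-passage-time density of the voltage from reset
to threshold, which we compute by solving the Fokker-Planck equation for
the voltage density with an absorbing boundary at $V_s$: the ISI density
is the absorbed probability flux. Maximizing the resulting log-likelihood
(Nelder-Mead simplex, log-transform for positivity-constrained
parameters) yields the estimates; for the leaky model with free
$(\mu, \sigma)$ the landscape is known to be free of local maxima, so a
single moment-matched start suffices.

Three likelihood routes are implemented:

* **Full Fokker-Planck** (`fit_background()`, `spike_train_loglik()` with
  method `fp_full`): one density solve per parameter vector, evaluated at
  every observed ISI. Used for background-input and adaptation inference.
* **First-order perturbative** (`fp_perturbative`): for
  $\mu(t) = \mu_0 + J\mu_1(t)$ with weak $|J|$, each factor is expanded
  as $p_0 + J p_1$. Used for perturbation and coupling inference
  (the perturbative route below).
* **Cascade rate model** (`rate_model`): the spike train is approximated
  by an inhomogeneous Poisson process whose rate comes from a
  linear-nonlinear reduction of the Fokker-Planck system.

# Numerics of the first-passage solver

The solver (`solve_isi_density()`) uses an exponentially fitted
finite-volume discretization (Scharfetter-Gummel / Chang-Cooper fluxes)
on a truncated domain $[V_{lb}, V_s]$ with backward-Euler time stepping.
This combination is robust in the drift-dominated cells near threshold
and unconditionally stable next to the absorbing boundary. Key choices:

* **Conservation by construction.** Interface fluxes telescope, so the
  interior mass lost per step equals the recorded absorbed flux exactly
  (up to round-off); a residual beyond $10^{-6}$ raises an error rather
  than a warning.
* **Boundary placement.** The absorbing condition is imposed *at* the top
  interface: the outflow flux uses half the cell spacing (last center to
  interface). With the naive ghost-cell form the boundary is effectively
  felt half a cell beyond threshold, which biases mean ISIs by
  $\sim 1\%$ at default resolution; with the half-spacing form the bias
  is $\sim 0.2\%$. Likewise the reset delta is split over the two cells
  bracketing $V_r$ so its mean position is exact.
* **Domain truncation.** $V_{lb} = V_r - \max(6\sigma\sqrt{\tau_m/2},\,
  40\,\mathrm{mV})$, i.e. at least six stationary standard deviations
  below reset, with a reflecting lower boundary approximating the
  zero-flux condition at $-\infty$.
* **Refractory period.** The density is shifted: $p(s) = 0$ for
  $s < t_{ref}$ and the solver clock starts at $t_{ref}$.
* **Default resolution.** 256 cells and $\Delta s = 0.05$ ms for renewal
  fits; 200 cells and $\Delta s = 0.1$ ms inside the (much more
  expensive) adaptive fits. At these settings the stationary rate matches
  independent Siegert quadrature to $<1\%$ across the plausible
  $(\mu, \sigma)$ range and halving both steps changes densities by
  $<0.5\%$ in $L_1$ — small against the sampling noise of a few hundred
  ISIs.
* **Subnormal flushing.** Large parts of the voltage domain hold density
  values below $10^{-250}$; the compiled solvers enable
  flush-to-zero/denormals-are-zero locally (and restore the FP
  environment on exit) because subnormal arithmetic dominates the runtime
  otherwise.

The stationary solution with reinjection at reset is computed separately
(`steady_state()`) by backward "threshold integration" of the stationary
flux relation from $V_s$ with an exponential integrating factor per step;
the rate follows from normalization. This route is discretization-wise
independent of the time-dependent solver, which the test suite exploits.

# The perturbative likelihood

The first-order correction $p_1$ is computed from a linearized
Fokker-Planck solve driven by $\mu_1(s)$, with the *discrete* derivative
of the scheme's fluxes with respect to the drift as the source term, so
that $p_1$ is the exact derivative of the discretized $p_0$ with respect
to $J$ (the test suite checks it against central differencing of the
full solver to $\sim 10^{-4}$ relative). Differencing two nonlinear
solves is deliberately reserved as the independent oracle.

For inference the corrections are not recomputed per ISI. For a constant
background, the correction responds linearly to the perturbation
trajectory, so a table of delta-pulse responses acts as a Green kernel
(`fp_green_kernel()`):

* columns at a 0.2-0.5 ms pulse-time spacing cover pulses well inside the
  ISI (bilinear interpolation);
* the response within one column spacing of the *next spike* — where a
  pulse can fire the neuron within a fraction of a millisecond and the
  kernel varies too steeply to interpolate — is computed exactly for
  every solver step (`fp_band_cpp`), including the same-step boundary
  term (the instantaneous response of the absorbed flux to the mean
  input). Omitting this prompt-response mass visibly biases coupling
  estimates downward, because the "presynaptic pulse precedes the
  postsynaptic spike by under a millisecond" events carry much of the
  signal;
* alpha-kernel trajectories are handled by quadrature of the kernel
  against $\mu_1$, plus the same-step term.

Given per-ISI corrections $q_k$, the profile likelihood in $J$,
$\sum_k \log(p_{0,k} + J q_k)$, is strictly concave on the interval
where every expanded density stays positive, with infinite walls at the
edges; `spikefit` maximizes it there by golden-section search, and
profiles the remaining shape parameter (alpha time constant $\tau$, or
delay $d$ on a 0.1 ms grid with local refinement — the delay profile is
sharp on a sub-millisecond scale, so coarser grids can miss the peak).

# The cascade rate model

`build_lnexp_tables()` tabulates, per mean-input node, the stationary
rate $r_\infty(\mu)$ and an adaptive exponential filter constant
$\tau_\mu(\mu)$; the rate model is
$d\mu_f/dt = (\mu - \mu_f)/\tau_\mu(\mu_f)$, $r(t) = r_\infty(\mu_f)$.
$\tau_\mu$ is extracted by a least-squares exponential fit to the full
time-dependent Fokker-Planck rate response to a small step
($\Delta\mu = 0.1$ mV/ms) at the operating point. Both endpoints of the
normalized transient are taken from the finite-volume discretization
itself (after settling it onto its own fixed point), not from the
independent stationary solver — otherwise the $\sim 1\%$ discretization
mismatch between the two routes corrupts the fitted time constant. A
frequency-domain extraction of the filter would be an alternative; the
step-response fit is retained because it is validated directly by the
step-response oracle in the tests (peak error $< 15\%$ against the full
solve at default parameters). The spike-train likelihood is then the
inhomogeneous-Poisson form, with the rate floored at $10^{-10}$/ms
inside logarithms.

# Adaptation

The adaptive model adds a current $w$ (mV/ms) incremented by $\Delta w$
at spikes, decaying with $\tau_w$, and subtracting from the mean input.
Spiking is then non-renewal, but given the observed spikes the
adaptation state at each ISI onset, $w_0^{(k)}$, is an exact function of
the spike times and $(\Delta w, \tau_w)$ (computed recursively, assuming
$w = 0$ just before the first spike — the increment at a spike is
applied before the decay across the following ISI). Each ISI factor is a
first-passage density under $\mu - w_0^{(k)} e^{-s/\tau_w}$; the
likelihood is evaluated from densities solved at 6-8 adaptation-state
nodes spanning the realized $w_0$ range (cubic interpolation in $w_0$,
which reproduces direct per-ISI solves to $10^{-3}$ relative; a denser
logarithmic node set was considered and rejected as the interpolation
error is already far below sampling noise). With $\Delta w = 0$ the code
path reduces exactly to the renewal likelihood.

The joint $(\mu, \sigma, \Delta w, \tau_w)$ landscape has a flat ridge —
$\mu$ trades off against the mean adaptation level
$\Delta w\, \tau_w\, r$ — so the simplex search starts from a
moment-matched guess (renewal fit plus the implied mean adaptation) and
is restarted once from its own optimum; the restart repairs degenerate
simplices on the ridge and measurably stabilizes the estimates.

# Network inference

Coupling inference for $N$ observed neurons follows a two-step pairwise
scheme justified by weak coupling: (1) background parameters
$(\mu_i, \sigma_i)$ per neuron with all couplings zero — the effect of
both observed and unobserved neurons is absorbed here; (2) for each
ordered pair, strength and delay $(J_{ij}, d_{ij})$ by the perturbative
likelihood with the presynaptic spikes as delayed delta-pulse triggers
($2N^2$ parameters in total). Pairs can be processed in any order;
per-pair failures are isolated.

Because step (1) absorbs coupling-induced deviations of the ISI density
into a renewal model that cannot represent them exactly, all pairwise
estimates of a network share a small common offset. This is removed by
the jitter bias correction (`bias_correct()`): presynaptic spikes are
jittered uniformly by $\pm 10$ ms — destroying spike-aligned synaptic
structure while preserving slow co-modulation — couplings are
re-estimated, and the network-wide average of the surrogate estimates (a
single scalar) is subtracted. The correction is part of the standard
pipeline even for uncorrelated external drive. Pair-level significance
uses the same surrogates at $\pm 5$ ms with per-pair z-scores
(`coupling_zscores()`).

For nonstationary recordings the background mean is tracked per ISI
(`fit_backgrounds(mode = "time_varying")`): a Gaussian-kernel rate
estimate (width $\sigma_G \in \{0.1, 0.5, 1\}$ s, reflected at the
recording edges) is inverted through $r_\infty(\mu)$ at the centers
between consecutive spikes, and $\sigma$ is then fitted by likelihood
maximization given the track. The three timescale variants are exposed
separately and never aggregated. Rates outside the invertible range are
clamped to the table edge. The model-free baseline
(`ccg_zscore_baseline()`) scores each ordered pair by the most deviant
positive-lag cross-correlogram bin against jitter surrogates, and
`detection_metrics()` computes ROC curves with maximal accuracy and
balanced accuracy.

# Synthetic data and what the tests do (and do not) show

All evaluation data are generated by the package's own simulators:
Euler-Maruyama integration (default step 0.01 ms; threshold crossings
registered at the first grid point with $V \ge V_s$, no sub-step
interpolation), delayed delta-pulse coupling applied at the grid point
nearest to spike time plus delay, spike-triggered adaptation, shared
external noise with correlation $c$, exact-discretization
Ornstein-Uhlenbeck currents, and truncated-Gaussian trigger gaps
(200 ± 50 ms, floored at 1 ms). All simulators take a mandatory seed and
are bit-reproducible. The grid-crossing convention biases simulated ISIs
slightly upward ($O(\sigma\sqrt{dt})$ barrier effect), which is why the
default simulation step is 0.01 ms rather than the solver's 0.05 ms;
the Monte-Carlo oracle comparisons use 0.0025 ms.

The packaged studies (`run_scenario()`, `scenario_*()`) use these
conditions: background recovery from 100 trains of 50 spikes at
$\mu = 1.75$, $\sigma = 2.5$; Cramer-Rao comparison at $K = 400$;
perturbation detection on 100 s trains with alpha kernels
($\tau = 10$ ms) and the background treated as known, which isolates the
detection step; network recovery at $N = 10$, 5 minute recordings,
couplings uniform on $[-0.75, 0.75]$ mV, global delay 1 ms; adaptation
recovery from 50 trains of 500 spikes at $\Delta w = 0.4$ mV/ms,
$\tau_w = 100$ ms — an increment and timescale in the range reported for
cortical pyramidal cells, with $\tau_w \gg \tau_m$ so that adaptation
clearly lengthens ISIs. Study sizes are the package's declared
evaluation scale; the scenario functions accept larger values.

Passing these studies shows that the estimators recover the parameters
of data generated by the matching model class. Real recordings violate
the model in known ways — conductance (not current) synapses, multiple
adaptation timescales, colored noise, rate nonstationarity beyond the
tracked timescales, spike-sorting errors — and the synthetic studies say
nothing about robustness to those; the censoring helpers
(`censor_isis()`, central-percentile and minimum-length filters) and the
AIC machinery are provided for exactly that boundary.

# Known limitations

* The perturbative likelihood degrades as $|J|$ grows (it is a
  first-order expansion); at $|J| \approx 0.7$ mV coupling strengths are
  recovered with $\sim 10\%$ distortion, and the delay profile can lock
  onto spurious structure for very weak pairs.
* The perturbative and cascade likelihoods are not offered for
  adaptation inference: the
  accumulated adaptation current violates the weak-variation assumption,
  and adapting spike trains deviate strongly from Poisson.
* The two-dimensional (voltage × adaptation) Fokker-Planck problem and
  colored-noise input are out of scope; a single adaptation timescale is
  assumed.
* Pairwise coupling estimation ignores joint effects of multiple
  connections; no joint refinement pass is attempted.
* The exponential-I&F variant registers spikes at the numerical ceiling
  $V_s$, with $(\Delta_T, V_T)$ shaping the soft threshold — a local
  convention, validated against the solver with the same convention
  rather than against an external reference.
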