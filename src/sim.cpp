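// Euler-Maruyama simulation of leaky / exponential integrate-and-fire
// dynamics, with optional spike-triggered adaptation, and of delta-pulse
// coupled networks.  All randomness is drawn from R's RNG so that set.seed()
// at the R level makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {
inline double drift_f(double V, double tau_m, int nonlin, double Delta_T,
                      double V_T) {
  double f = -V / tau_m;
  if (nonlin == 1) f += Delta_T * std::exp((V - V_T) / Delta_T) / tau_m;
  return f;
}
}

// Single neuron; mu is length 1 or n_steps.  Spike registered at the first
// grid point with V >= V_s; V clamped at V_r for t_ref thereafter.  If
// max_spikes > 0, integration stops once that many spikes were emitted.
// Adaptation: w decays with tau_w, incremented by Delta_w at spikes and
// subtracted from the mean input (Delta_w = 0 disables it and the w updates
// then leave the trajectory identical to the non-adaptive one).
// [[Rcpp::export]]
List sim_if_cpp(NumericVector mu, double sigma, double V_s, double V_r,
                double tau_m, int nonlin, double Delta_T, double V_T,
                double t_ref, double dt, int n_steps, int max_spikes = 0,
                double Delta_w = 0.0, double tau_w = 1.0, double V0 = NA_REAL,
                bool keep_v = false, bool keep_w = false) {
  double V = ISNA(V0) ? V_r : V0;
  double w = 0.0;
  double sq = sigma * std::sqrt(dt);
  double decay_w = std::exp(-dt / tau_w);
  int ref_steps = (int)std::lround(t_ref / dt);
  int ref_count = 0;
  bool mu_const = (mu.size() == 1);
  std::vector<double> spikes;
  NumericVector Vtr, wtr;
  if (keep_v) Vtr = NumericVector(n_steps + 1);
  if (keep_w) wtr = NumericVector(n_steps + 1);
  if (keep_v) Vtr[0] = V;
  if (keep_w) wtr[0] = w;
  int m = 0;
  for (; m < n_steps; ++m) {
    double mu_m = mu_const ? mu[0] : mu[m];
    if (ref_count > 0) {
      --ref_count;
      V = V_r;
    } else {
      V += dt * (drift_f(V, tau_m, nonlin, Delta_T, V_T) + mu_m - w)
           + sq * norm_rand();
    }
    w *= decay_w;
    if (ref_count == 0 && V >= V_s) {
      spikes.push_back((m + 1) * dt);
      V = V_r;
      w += Delta_w;
      ref_count = ref_steps;
    }
    if (keep_v) Vtr[m + 1] = V;
    if (keep_w) wtr[m + 1] = w;
    if (max_spikes > 0 && (int)spikes.size() >= max_spikes) { ++m; break; }
  }
  List out = List::create(
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["t_end"] = m * dt);
  if (keep_v) out["V"] = Vtr[Range(0, m)];
  if (keep_w) out["w"] = wtr[Range(0, m)];
  return out;
}

// Network of leaky I&F neurons with delayed delta-pulse coupling
// (presynaptic spike of j adds J(i,j) mV to V_i after delay d(i,j)) and
// external white-noise drive with shared component sqrt(c)*xi_c.
// [[Rcpp::export]]
List sim_net_cpp(NumericMatrix J, NumericMatrix d, NumericVector mu,
                 NumericVector sigma, double c, double V_s, double V_r,
                 double tau_m, double t_ref, double dt, int n_steps) {
  int N = J.nrow();
  if (J.ncol() != N || d.nrow() != N || d.ncol() != N)
    stop("J and d must be square matrices of equal size");
  // pending delayed pulses in a ring buffer over delay steps
  int max_del = 2;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (J(i, j) != 0.0) {
        int ds = (int)std::lround(d(i, j) / dt);
        if (ds < 1) ds = 1;            // strictly positive delays
        if (ds + 1 > max_del) max_del = ds + 1;
      }
  std::vector< std::vector<double> > ring(max_del,
                                          std::vector<double>(N, 0.0));
  // per presynaptic neuron: postsyn targets and delay steps (sparse)
  std::vector< std::vector<int> > tgt(N);
  std::vector< std::vector<double> > tgtJ(N);
  std::vector< std::vector<int> > tgtD(N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (J(i, j) != 0.0) {
        int ds = (int)std::lround(d(i, j) / dt);
        if (ds < 1) ds = 1;
        tgt[j].push_back(i);
        tgtJ[j].push_back(J(i, j));
        tgtD[j].push_back(ds);
      }
  std::vector<double> V(N, V_r);
  std::vector<int> ref_count(N, 0);
  int ref_steps = (int)std::lround(t_ref / dt);
  double sc = std::sqrt(c), si = std::sqrt(1.0 - c);
  std::vector< std::vector<double> > spikes(N);
  for (int m = 0; m < n_steps; ++m) {
    int slot = m % max_del;
    double xc = norm_rand();
    for (int i = 0; i < N; ++i) {
      if (ref_count[i] > 0) {
        --ref_count[i];
        V[i] = V_r;
        continue;
      }
      double eta = si * norm_rand() + sc * xc;
      V[i] += dt * (-V[i] / tau_m + mu[i]) + sigma[i] * std::sqrt(dt) * eta
              + ring[slot][i];
    }
    for (int i = 0; i < N; ++i) ring[slot][i] = 0.0;
    for (int j = 0; j < N; ++j) {
      if (ref_count[j] == 0 && V[j] >= V_s) {
        spikes[j].push_back((m + 1) * dt);
        V[j] = V_r;
        ref_count[j] = ref_steps;
        for (size_t l = 0; l < tgt[j].size(); ++l) {
          int fut = (m + tgtD[j][l]) % max_del;
          ring[fut][tgt[j][l]] += tgtJ[j][l];
        }
      }
    }
  }
  List out(N);
  for (int i = 0; i < N; ++i)
    out[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return out;
}

// Superposition of alpha kernels (t/tau) exp(1 - t/tau) triggered at the
// given grid indices, sampled on a uniform grid of n points with step dt.
// Exact recursion for the sampled continuous kernel; triggers snapped to
// the grid.
// [[Rcpp::export]]
NumericVector alpha_series_cpp(IntegerVector trig_idx, int n, double dt,
                               double tau) {
  NumericVector out(n);
  double a = 0.0, b = 0.0;       // a: sum exp terms, b: sum (t/tau) exp
  double rho = std::exp(-dt / tau);
  int nt = trig_idx.size(), next = 0;
  const double e1 = std::exp(1.0);
  for (int m = 0; m < n; ++m) {
    b = (b + a * dt / tau) * rho;
    a *= rho;
    while (next < nt && trig_idx[next] == m) { a += 1.0; ++next; }
    out[m] = e1 * b;   // value at time m*dt; a trigger at m contributes 0
  }
  return out;
}

// Linear-nonlinear cascade rate model: integrate
//   d mu_f / dt = (mu(t) - mu_f) / tau_mu(mu_f),  r(t) = r_inf(mu_f)
// with explicit midpoint stepping and linear table lookups.
// [[Rcpp::export]]
NumericVector lnexp_integrate_cpp(NumericVector mu, double dt,
                                  NumericVector mu_grid,
                                  NumericVector r_inf_tab,
                                  NumericVector tau_mu_tab, double mu_f0) {
  int n = mu.size();
  int ng = mu_grid.size();
  double lo = mu_grid[0], hi = mu_grid[ng - 1];
  double step = (hi - lo) / (ng - 1);        // grid must be uniform
  auto look = [&](const NumericVector& tab, double x) {
    if (x <= lo) return tab[0];
    if (x >= hi) return tab[ng - 1];
    double u = (x - lo) / step;
    int k = (int)u;
    if (k >= ng - 1) k = ng - 2;
    double f = u - k;
    return tab[k] * (1.0 - f) + tab[k + 1] * f;
  };
  NumericVector r(n);
  double mu_f = mu_f0;
  for (int m = 0; m < n; ++m) {
    double mu_now = mu[m];
    double mu_next = (m + 1 < n) ? mu[m + 1] : mu[m];
    double mu_half = 0.5 * (mu_now + mu_next);
    double k1 = (mu_now - mu_f) / look(tau_mu_tab, mu_f);
    double mid = mu_f + 0.5 * dt * k1;
    double k2 = (mu_half - mid) / look(tau_mu_tab, mid);
    mu_f += dt * k2;
    r[m] = look(r_inf_tab, mu_f);
  }
  return r;
}
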