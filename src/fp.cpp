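// Finite-volume Fokker-Planck solvers for integrate-and-fire first-passage
// problems on a truncated voltage domain [V_lb, V_s].
//
// Discretization: n_V cells of width dV, cell centers V_i; Scharfetter-Gummel
// (exponential-fitting) interface fluxes, backward-Euler time stepping.  The
// scheme is conservative: interior mass loss per step equals the absorbed
// flux at V_s exactly (up to round-off), which is what the ISI density needs.
//
// Interface flux between cells i-1 and i:
//   q_i = (D/dV) * ( B(-w_i) p_{i-1} - B(w_i) p_i ),  w_i = A_i dV / D,
// with Bernoulli function B(x) = x/(e^x - 1), drift A = f(V) + mu(s) and
// D = sigma^2/2.  Top interface is absorbing (ghost density 0), bottom is
// reflecting (zero flux), approximating the no-flux condition at -infinity.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

namespace {

// The density underflows to subnormal values over most of the voltage
// domain, which cripples the tridiagonal sweeps on x86; treat those values
// as zero while a solver is running and restore the FP environment after.
struct FlushToZeroGuard {
#ifdef __SSE2__
  unsigned int csr;
  FlushToZeroGuard() : csr(_mm_getcsr()) {
    _mm_setcsr(csr | 0x8040);   // FTZ | DAZ
  }
  ~FlushToZeroGuard() { _mm_setcsr(csr); }
#endif
};

inline double bernoulli_fn(double x) {
  // x / (exp(x) - 1), stable near 0
  if (std::fabs(x) < 1e-8) return 1.0 - 0.5 * x;
  if (x > 700.0) return 0.0;
  if (x < -700.0) return -x;
  return x / (std::expm1(x));
}

inline double bernoulli_deriv(double x) {
  // d/dx [x/(e^x - 1)], stable near 0 and at the tails
  if (std::fabs(x) < 1e-5) return -0.5 + x / 6.0;
  if (x > 40.0) return 0.0;
  if (x < -40.0) return -1.0;
  double em1 = std::expm1(x);
  return (em1 - x * (em1 + 1.0)) / (em1 * em1);
}

struct FPOperator {
  int n;
  double dV, dt, D;
  double V_lb, V_s, tau_m;
  int nonlin;            // 0 = leaky, 1 = exponential
  double Delta_T, V_T;
  std::vector<double> Vif;   // interface positions, size n+1
  std::vector<double> fV;    // f(V) at interfaces
  // backward-Euler tridiagonal system (I + dt L) p_new = p_old
  std::vector<double> lo, di, up;      // assembled coefficients
  std::vector<double> cp;              // Thomas forward-sweep upper coefs
  std::vector<double> dinv;            // pivots for back substitution
  std::vector<double> dBm, dBp;        // dB(-w)/dmu, dB(w)/dmu per interface
  double flux_coef;                    // q_top = flux_coef * p_{n-1}
  double dflux_coef;                   // d q_top / d mu, applied to p_{n-1}
  double mu_cached;
  bool have_coef;

  FPOperator(int n_, double V_lb_, double V_s_, double sigma, double dt_,
             double tau_m_, int nonlin_, double Delta_T_, double V_T_)
    : n(n_), dt(dt_), V_lb(V_lb_), V_s(V_s_), tau_m(tau_m_),
      nonlin(nonlin_), Delta_T(Delta_T_), V_T(V_T_),
      mu_cached(NA_REAL), have_coef(false) {
    dV = (V_s - V_lb) / n;
    D = 0.5 * sigma * sigma;
    Vif.resize(n + 1);
    fV.resize(n + 1);
    for (int j = 0; j <= n; ++j) {
      Vif[j] = V_lb + j * dV;
      double f = -Vif[j] / tau_m;
      if (nonlin == 1)
        f += Delta_T * std::exp((Vif[j] - V_T) / Delta_T) / tau_m;
      fV[j] = f;
    }
    lo.assign(n, 0.0); di.assign(n, 0.0); up.assign(n, 0.0);
    cp.assign(n, 0.0); dinv.assign(n, 0.0);
    dBm.assign(n + 1, 0.0); dBp.assign(n + 1, 0.0);
    flux_coef = 0.0; dflux_coef = 0.0;
  }

  void assemble(double mu) {
    if (have_coef && mu == mu_cached) return;
    const double g = dt / dV * D / dV;   // dt*D/dV^2
    // Bernoulli weights at interior interfaces 1..n
    // cell i: lower = -g*B(-w_i); upper = -g*B(w_{i+1});
    //         diag  = 1 + g*(B(-w_{i+1}) + B(w_i))  [boundary-adjusted]
    double Bm_prev = 0.0, Bp_prev = 0.0;   // interface 0: zero flux
    for (int i = 0; i < n; ++i) {
      double Bm_next, Bp_next;
      // the absorbing condition holds AT the top interface, half a cell
      // from the last center, so the top flux uses half spacing (with
      // full spacing the boundary is effectively half a cell too high)
      double h = (i == n - 1) ? 0.5 * dV : dV;
      double w = (fV[i + 1] + mu) * h / D;
      Bp_next = bernoulli_fn(w);            // B(w_{i+1})
      Bm_next = bernoulli_fn(-w);           // B(-w_{i+1})
      // drift derivatives: dw/dmu = h/D
      dBp[i + 1] = bernoulli_deriv(w) * h / D;
      dBm[i + 1] = -bernoulli_deriv(-w) * h / D;
      double gh = dt / dV * D / h;
      lo[i] = (i == 0) ? 0.0 : -g * Bm_prev;
      up[i] = (i == n - 1) ? 0.0 : -g * Bp_next;
      double diag = 1.0 + gh * Bm_next;     // outflow through interface i+1
      if (i > 0) diag += g * Bp_prev;       // outflow through interface i
      di[i] = diag;
      Bm_prev = Bm_next; Bp_prev = Bp_next;
    }
    // absorbed flux (per ms) out of the top interface given solved p_{n-1}
    flux_coef = (D / (0.5 * dV)) * Bm_prev;
    dflux_coef = (D / (0.5 * dV)) * dBm[n];
    // Thomas factorization (matrix is diagonally dominant)
    cp[0] = up[0] / di[0];
    dinv[0] = 1.0 / di[0];
    for (int i = 1; i < n; ++i) {
      double m = di[i] - lo[i] * cp[i - 1];
      dinv[i] = 1.0 / m;
      cp[i] = up[i] * dinv[i];
    }
    mu_cached = mu;
    have_coef = true;
  }

  // solve (I + dt L) x = rhs in place
  void solve(std::vector<double>& x) const {
    x[0] *= dinv[0];
    for (int i = 1; i < n; ++i)
      x[i] = (x[i] - lo[i] * x[i - 1]) * dinv[i];
    for (int i = n - 2; i >= 0; --i)
      x[i] -= cp[i] * x[i + 1];
  }

  int cell_of(double V) const {
    int i = (int)std::floor((V - V_lb) / dV);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }

  // place a unit delta at V as cell densities with the exact mean
  // position (split over the two centers bracketing V)
  void place_delta(double V, std::vector<double>& p) const {
    double x = (V - V_lb) / dV - 0.5;    // in units of centers
    int i0 = (int)std::floor(x);
    double f = x - i0;
    if (i0 < 0) { i0 = 0; f = 0.0; }
    if (i0 >= n - 1) { i0 = n - 2; f = 1.0; }
    p[i0] += (1.0 - f) / dV;
    p[i0 + 1] += f / dV;
  }

  // action of the drift-derivative of the discrete operator:
  // out_i = (d q_{i+1}/d mu - d q_i/d mu) / dV for the assembled mu,
  // with d q_j/d mu = (D/dV) (dBm_j p_{j-1} - dBp_j p_j); this makes the
  // linearized solve the exact derivative of the discrete scheme.
  void dmu_apply(const std::vector<double>& p, std::vector<double>& out)
      const {
    double dq_prev = 0.0;   // interface 0: zero flux, no mu dependence
    const double c = D / dV;
    const double c_top = D / (0.5 * dV);
    for (int i = 0; i < n; ++i) {
      double dq_next;
      if (i == n - 1) {
        dq_next = c_top * dBm[n] * p[n - 1];       // absorbing interface
      } else {
        dq_next = c * (dBm[i + 1] * p[i] - dBp[i + 1] * p[i + 1]);
      }
      out[i] = (dq_next - dq_prev) / dV;
      dq_prev = dq_next;
    }
  }
};

} // namespace

// First-passage (ISI density) solve: initial delta at V_r, absorbing at V_s.
// mu may be length 1 (constant) or length n_steps (mu at each step).
// coef_tol > 0 allows reuse of the factorized operator while |mu - mu_cached|
// <= coef_tol (used for slowly varying within-ISI mean input).
// [[Rcpp::export]]
List fp_isi_cpp(NumericVector mu, double sigma, double V_s, double V_r,
                double tau_m, int nonlin, double Delta_T, double V_T,
                double V_lb, int n_V, double dt, int n_steps,
                double coef_tol = 0.0, bool keep_pv = false) {
  FlushToZeroGuard ftz_guard;
  FPOperator op(n_V, V_lb, V_s, sigma, dt, tau_m, nonlin, Delta_T, V_T);
  std::vector<double> p(n_V, 0.0);
  op.place_delta(V_r, p);
  NumericVector flux(n_steps);
  NumericMatrix PV;
  if (keep_pv) PV = NumericMatrix(n_V, n_steps);
  bool mu_const = (mu.size() == 1);
  for (int m = 0; m < n_steps; ++m) {
    double mu_m = mu_const ? mu[0] : mu[m];
    if (!op.have_coef || std::fabs(mu_m - op.mu_cached) > coef_tol)
      op.assemble(mu_m);
    op.solve(p);
    flux[m] = op.flux_coef * p[n_V - 1];
    if (keep_pv)
      for (int i = 0; i < n_V; ++i) PV(i, m) = p[i];
  }
  double mass = 0.0;
  for (int i = 0; i < n_V; ++i) mass += p[i];
  mass *= op.dV;
  List out = List::create(_["flux"] = flux, _["mass"] = mass,
                          _["p_V"] = NumericVector(p.begin(), p.end()),
                          _["dV"] = op.dV,
                          _["flux_coef"] = op.flux_coef,
                          _["dflux_coef"] = op.dflux_coef);
  if (keep_pv) out["P_V"] = PV;
  return out;
}

// Coupled solve of the unperturbed density p0 and the first-order correction
// v for mean-input perturbation mu(s) = mu0(s) + J*mu1(s):
//   dv/ds = L[mu0] v + mu1(s) * (-d p0 / dV),
// both with absorbing top boundary; returns the two flux traces.
// [[Rcpp::export]]
List fp_isi_p1_cpp(NumericVector mu0, NumericVector mu1, double sigma,
                   double V_s, double V_r, double tau_m, int nonlin,
                   double Delta_T, double V_T, double V_lb, int n_V,
                   double dt, int n_steps, double coef_tol = 0.0) {
  FlushToZeroGuard ftz_guard;
  FPOperator op(n_V, V_lb, V_s, sigma, dt, tau_m, nonlin, Delta_T, V_T);
  std::vector<double> p(n_V, 0.0), v(n_V, 0.0), src(n_V, 0.0);
  op.place_delta(V_r, p);
  NumericVector flux0(n_steps), flux1(n_steps);
  bool mu_const = (mu0.size() == 1);
  for (int m = 0; m < n_steps; ++m) {
    double mu_m = mu_const ? mu0[0] : mu0[m];
    if (!op.have_coef || std::fabs(mu_m - op.mu_cached) > coef_tol)
      op.assemble(mu_m);
    op.solve(p);
    flux0[m] = op.flux_coef * p[n_V - 1];
    double m1 = mu1[mu1.size() == 1 ? 0 : m];
    if (m1 != 0.0) {
      op.dmu_apply(p, src);
      for (int i = 0; i < n_V; ++i) v[i] -= dt * m1 * src[i];
    }
    op.solve(v);
    flux1[m] = op.flux_coef * v[n_V - 1] + m1 * op.dflux_coef * p[n_V - 1];
  }
  return List::create(_["flux0"] = flux0, _["flux1"] = flux1);
}

// Green-kernel table for delta-pulse perturbations at constant background
// mean input: column l holds the first-order flux correction P1(s | pulse at
// t_p = tp_idx[l]*dt), i.e. the response to an instantaneous unit shift of
// the mean input (a delta pulse of unit time-integral) applied at t_p.
// [[Rcpp::export]]
NumericMatrix fp_green_cpp(double mu0, double sigma, double V_s, double V_r,
                           double tau_m, int nonlin, double Delta_T,
                           double V_T, double V_lb, int n_V, double dt,
                           int n_steps, IntegerVector tp_idx) {
  FlushToZeroGuard ftz_guard;
  FPOperator op(n_V, V_lb, V_s, sigma, dt, tau_m, nonlin, Delta_T, V_T);
  op.assemble(mu0);
  // forward solve of p0 storing the density at every step
  std::vector<double> p(n_V, 0.0);
  op.place_delta(V_r, p);
  std::vector< std::vector<double> > P0(n_steps);
  for (int m = 0; m < n_steps; ++m) {
    op.solve(p);
    P0[m] = p;
  }
  int n_tp = tp_idx.size();
  NumericMatrix G(n_steps, n_tp);
  std::vector<double> v(n_V);
  for (int l = 0; l < n_tp; ++l) {
    int m0 = tp_idx[l];          // pulse applied at step m0 (0-based)
    if (m0 < 0 || m0 >= n_steps) stop("tp index out of range");
    // impulse response: a unit-integral pulse perturbs the density by
    // minus the drift-derivative of the discrete operator applied to p0
    // (the discrete analog of -d p0/dV)
    op.dmu_apply(P0[m0], v);
    for (int i = 0; i < op.n; ++i) v[i] = -v[i];
    for (int m = m0 + 1; m < n_steps; ++m) {
      op.solve(v);
      G(m, l) = op.flux_coef * v[n_V - 1];
    }
  }
  return G;
}

// Prompt-response band: exact first-order flux response H(j, m) at j
// steps after a unit delta pulse applied in step m (0-based), for every
// step of the horizon.  Row 0 holds the same-step response including the
// instantaneous boundary term.  Complements the coarse pulse-time table
// for pulses that land within a fraction of a millisecond of the next
// spike, where the response varies too steeply for interpolation.
// [[Rcpp::export]]
NumericMatrix fp_band_cpp(double mu0, double sigma, double V_s, double V_r,
                          double tau_m, int nonlin, double Delta_T,
                          double V_T, double V_lb, int n_V, double dt,
                          int n_steps, int band_steps) {
  FlushToZeroGuard ftz_guard;
  FPOperator op(n_V, V_lb, V_s, sigma, dt, tau_m, nonlin, Delta_T, V_T);
  op.assemble(mu0);
  std::vector<double> p(n_V, 0.0), v(n_V), src(n_V);
  op.place_delta(V_r, p);
  NumericMatrix H(band_steps + 1, n_steps);
  for (int m = 0; m < n_steps; ++m) {
    op.solve(p);
    op.dmu_apply(p, src);
    for (int i = 0; i < n_V; ++i) v[i] = -src[i];
    op.solve(v);
    H(0, m) = op.flux_coef * v[n_V - 1]
              + (1.0 / dt) * op.dflux_coef * p[n_V - 1];
    int jmax = std::min(band_steps, n_steps - 1 - m);
    for (int j = 1; j <= jmax; ++j) {
      op.solve(v);
      H(j, m) = op.flux_coef * v[n_V - 1];
    }
  }
  return H;
}

// Time-dependent Fokker-Planck solve with reinjection of the absorbed flux
// at the reset voltage (membrane-voltage density of the free model; the
// instantaneous spike rate is the absorbed flux).  p_init: initial density at
// cell centers (length n_V), or length 0 for a delta at V_r.  t_ref delays
// reinjection by round(t_ref/dt) steps.
// [[Rcpp::export]]
List fp_rate_cpp(NumericVector mu, double sigma, double V_s, double V_r,
                 double tau_m, int nonlin, double Delta_T, double V_T,
                 double V_lb, int n_V, double dt, int n_steps,
                 NumericVector p_init, double t_ref = 0.0,
                 double coef_tol = 0.0) {
  FlushToZeroGuard ftz_guard;
  FPOperator op(n_V, V_lb, V_s, sigma, dt, tau_m, nonlin, Delta_T, V_T);
  std::vector<double> p(n_V, 0.0);
  if (p_init.size() == (R_xlen_t)n_V) {
    for (int i = 0; i < n_V; ++i) p[i] = p_init[i];
  } else {
    p[op.cell_of(V_r)] = 1.0 / op.dV;
  }
  int ref_steps = (int)std::lround(t_ref / dt);
  std::vector<double> queue(ref_steps + 1, 0.0);
  int qpos = 0;
  int i_r = op.cell_of(V_r);
  NumericVector rate(n_steps);
  bool mu_const = (mu.size() == 1);
  for (int m = 0; m < n_steps; ++m) {
    double mu_m = mu_const ? mu[0] : mu[m];
    if (!op.have_coef || std::fabs(mu_m - op.mu_cached) > coef_tol)
      op.assemble(mu_m);
    op.solve(p);
    double r = op.flux_coef * p[n_V - 1];
    rate[m] = r;
    // reinjection, delayed by the refractory period
    queue[qpos] = r * dt;
    qpos = (qpos + 1) % (ref_steps + 1);
    p[i_r] += queue[qpos] / op.dV;
    queue[qpos] = 0.0;
  }
  return List::create(_["rate"] = rate,
                      _["p_V"] = NumericVector(p.begin(), p.end()),
                      _["dV"] = op.dV);
}
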