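# Independent oracles used across tests.

# Siegert formula: stationary rate of the leaky I&F model with white-noise
# input, by quadrature of the error-function integral (independent of the
# package's Fokker-Planck solvers)
siegert_rate <- function(mu, sigma, tau_m = 20, V_s = 30, V_r = 0,
                         t_ref = 0) {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  lo <- (V_r - mu * tau_m) / (sigma * sqrt(tau_m))
  hi <- (V_s - mu * tau_m) / (sigma * sqrt(tau_m))
  if (hi > 8) return(0)    # mean first-passage time beyond ~exp(64): no rate
  # exp(u^2) (1 + erf(u)) written through the scaled complementary error
  # function, stable for large |u| (asymptotic series beyond x = 6, where
  # the direct product under/overflows)
  erfcx <- function(x) {
    # erfc through the accurate normal tail; asymptotic series once
    # exp(x^2) would overflow
    ifelse(x > 25,
           (1 - 0.5 / x^2 + 0.75 / x^4) / (x * sqrt(pi)),
           exp(pmin(x^2, 700)) * 2 * stats::pnorm(-x * sqrt(2)))
  }
  integrand <- function(u) {
    ifelse(u < 0, erfcx(-u), 2 * exp(u^2) - erfcx(u))
  }
  Tm <- tau_m * sqrt(pi) *
    stats::integrate(integrand, lo, hi, rel.tol = 1e-8,
                     subdivisions = 500L)$value
  1 / (t_ref + Tm)
}

# noise-free ISI of the leaky model for suprathreshold constant drive
noise_free_isi <- function(mu, tau_m = 20, V_s = 30, V_r = 0) {
  stopifnot(mu * tau_m > V_s)
  tau_m * log((mu * tau_m - V_r) / (mu * tau_m - V_s))
}

default_params <- function() neuron_params()

# small deterministic spike train used by bookkeeping tests
toy_train <- function() c(10, 52, 80.5, 131, 160, 215.25, 240)
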