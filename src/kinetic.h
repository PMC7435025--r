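#pragma once
#include <RcppArmadillo.h>

// Adiabatic tissue-homogeneity impulse retention function, internal s^-1.
// F is supplied in ml.min^-1.100g^-1 and converted via F/6000 (unit tissue
// density). Plateau branch holds at exactly t = t0; exponential branch holds
// at exactly t = t0 + minTT.
inline double ath_irf(double t, double F, double t0, double minTT,
                      double E, double k) {
  if (t < t0) return 0.0;
  const double Fsi = F / 6000.0;
  if (t < t0 + minTT) return Fsi;
  return Fsi * E * std::exp(-k * (t - t0 - minTT));
}

// IRF sampled at lags 0, dt, 2*dt, ... (n values).
inline void ath_irf_lags(arma::vec& out, int n, double dt, double F,
                         double t0, double minTT, double E, double k) {
  for (int l = 0; l < n; ++l) out[l] = ath_irf(l * dt, F, t0, minTT, E, k);
}

// Causal rectangle-rule convolution: tc[i] = dt * sum_j aif[j] * irf[i-j].
inline void causal_conv(arma::vec& tc, const arma::vec& aif,
                        const arma::vec& irf, double dt) {
  const int n = aif.n_elem;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j <= i; ++j) acc += aif[j] * irf[i - j];
    tc[i] = dt * acc;
  }
}

// Partial derivatives of the IRF at one lag with respect to (F, t0, minTT,
// E, k), in the almost-everywhere sense (breakpoint motion contributes
// measure-zero jumps that the accept-only optimizer tolerates).
inline void ath_irf_grad(double t, double F, double t0, double minTT,
                         double E, double k, double* g) {
  if (t < t0) { g[0] = g[1] = g[2] = g[3] = g[4] = 0.0; return; }
  const double Fsi = F / 6000.0;
  if (t < t0 + minTT) {
    g[0] = 1.0 / 6000.0;
    g[1] = g[2] = g[3] = g[4] = 0.0;
    return;
  }
  const double u = t - t0 - minTT;
  const double ex = std::exp(-k * u);
  const double v = Fsi * E * ex;
  g[0] = E * ex / 6000.0; // dF
  g[1] = k * v;           // dt0
  g[2] = k * v;           // dminTT
  g[3] = Fsi * ex;        // dE
  g[4] = -u * v;          // dk
}
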