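#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout shared with R: v0, v, S, n, K, D, mu, Q, m, eta
enum { P_V0, P_V, P_S, P_N, P_K, P_D, P_MU, P_Q, P_M, P_ETA };

// Hill-feedback drift of the efflux pair and its production channels.
// a = v0 + v * (S x)^n / ((S x)^n + w^n) with shared sink term w = D(E+F)+K;
// drift f = a - mu * x.
static inline void efflux_drift(double E, double F, const double* p,
                                double& fE, double& fF, double& aE, double& aF) {
  const double w = p[P_D] * (E + F) + p[P_K];
  const double wn = std::pow(w, p[P_N]);
  const double uE = E > 0.0 ? std::pow(p[P_S] * E, p[P_N]) : 0.0;
  const double uF = F > 0.0 ? std::pow(p[P_S] * F, p[P_N]) : 0.0;
  const double dE = uE + wn, dF = uF + wn;
  const double hE = dE > 0.0 ? uE / dE : 0.0;
  const double hF = dF > 0.0 ? uF / dF : 0.0;
  aE = p[P_V0] + p[P_V] * hE;
  aF = p[P_V0] + p[P_V] * hF;
  fE = aE - p[P_MU] * E;
  fF = aF - p[P_MU] * F;
}

// 2x2 Jacobian of the efflux drift, analytic.
static inline void efflux_jac(double E, double F, const double* p, double J[4]) {
  const double n = p[P_N], S = p[P_S], D = p[P_D], v = p[P_V];
  const double w = D * (E + F) + p[P_K];
  const double wn = std::pow(w, n);
  const double dwn = w > 0.0 ? n * std::pow(w, n - 1.0) * D : 0.0;
  const double uE = E > 0.0 ? std::pow(S * E, n) : 0.0;
  const double uF = F > 0.0 ? std::pow(S * F, n) : 0.0;
  const double duE = E > 0.0 ? n * S * std::pow(S * E, n - 1.0) : (n == 1.0 ? S : 0.0);
  const double duF = F > 0.0 ? n * S * std::pow(S * F, n - 1.0) : (n == 1.0 ? S : 0.0);
  const double qE = uE + wn, qF = uF + wn;
  // d/dE of uE/(uE+wn) = (duE * wn - uE * dwn) / q^2 ; d/dF = -uE * dwn / q^2
  double hE_E = 0.0, hE_F = 0.0, hF_E = 0.0, hF_F = 0.0;
  if (qE > 0.0) {
    hE_E = (duE * wn - uE * dwn) / (qE * qE);
    hE_F = (-uE * dwn) / (qE * qE);
  }
  if (qF > 0.0) {
    hF_F = (duF * wn - uF * dwn) / (qF * qF);
    hF_E = (-uF * dwn) / (qF * qF);
  }
  J[0] = v * hE_E - p[P_MU]; // d fE / dE
  J[1] = v * hE_F;           // d fE / dF
  J[2] = v * hF_E;           // d fF / dE
  J[3] = v * hF_F - p[P_MU]; // d fF / dF
}

// Drift-implicit (semi-implicit) Euler-Maruyama path for (E, F, N, M).
// Noise enters the efflux pair only, as chemical-Langevin increments with
// production channel a and decay channel b = mu*x, both evaluated at the
// step's starting state: dE += eta * (sqrt(a) z1 - sqrt(b) z2) * sqrt(dt).
// The implicit drift solve uses damped Newton on the efflux pair; bud
// lengths N, M integrate the growth Hill of the solved efflux explicitly.
// noise: steps x 4 standard normals (zaE, zbE, zaF, zbF); may have 0 rows
// when eta == 0.
// [[Rcpp::export(name = ".sde_path")]]
List sde_path(NumericVector params, NumericVector init, double t_end, double dt,
              NumericMatrix noise, int save_every) {
  const double* p = REAL(params);
  const int steps = (int)std::lround(t_end / dt);
  const bool stoch = p[P_ETA] > 0.0 && noise.nrow() >= steps;
  const double sdt = std::sqrt(dt);
  const int nsave = steps / save_every + 1;

  NumericVector Ts(nsave), Es(nsave), Fs(nsave), Ns(nsave), Ms(nsave);
  double E = init[0], F = init[1], N = init[2], M = init[3];
  int clamps = 0, isave = 0;
  bool ok = true;
  double fail_time = NA_REAL;

  Ts[0] = 0.0; Es[0] = E; Fs[0] = F; Ns[0] = N; Ms[0] = M; isave = 1;

  for (int k = 0; k < steps; ++k) {
    double fE, fF, aE, aF;
    efflux_drift(E, F, p, fE, fF, aE, aF);
    double nE = 0.0, nF = 0.0;
    if (stoch) {
      const double bE = p[P_MU] * E, bF = p[P_MU] * F;
      nE = p[P_ETA] * (std::sqrt(std::max(aE, 0.0)) * noise(k, 0) -
                       std::sqrt(std::max(bE, 0.0)) * noise(k, 1)) * sdt;
      nF = p[P_ETA] * (std::sqrt(std::max(aF, 0.0)) * noise(k, 2) -
                       std::sqrt(std::max(bF, 0.0)) * noise(k, 3)) * sdt;
    }
    // target: x - x0 - dt * f(x) - n = 0; predictor = explicit Euler step
    const double tE = E + nE, tF = F + nF;
    double xE = E + fE * dt + nE, xF = F + fF * dt + nF;
    if (xE < 0.0) xE = 0.0;
    if (xF < 0.0) xF = 0.0;
    double gE, gF;
    for (int it = 0; it < 50; ++it) {
      double dfE, dfF, a1, a2, J[4];
      efflux_drift(xE, xF, p, dfE, dfF, a1, a2);
      gE = xE - tE - dt * dfE;
      gF = xF - tF - dt * dfF;
      const double res = std::fabs(gE) + std::fabs(gF);
      if (res < 1e-13) break;
      efflux_jac(xE, xF, p, J);
      // solve (I - dt J) d = g
      const double m11 = 1.0 - dt * J[0], m12 = -dt * J[1];
      const double m21 = -dt * J[2], m22 = 1.0 - dt * J[3];
      const double det = m11 * m22 - m12 * m21;
      if (det == 0.0 || !std::isfinite(det)) { ok = false; break; }
      double dE = (m22 * gE - m12 * gF) / det;
      double dF = (m11 * gF - m21 * gE) / det;
      double damp = 1.0;
      while ((xE - damp * dE < -1e-12 || xF - damp * dF < -1e-12) && damp > 1e-8)
        damp *= 0.5;
      xE -= damp * dE;
      xF -= damp * dF;
      if (xE < 0.0) xE = 0.0;
      if (xF < 0.0) xF = 0.0;
    }
    if (!ok || !std::isfinite(xE) || !std::isfinite(xF)) {
      ok = false; fail_time = (k + 1) * dt; break;
    }
    if (xE < 0.0) { xE = 0.0; ++clamps; }
    if (xF < 0.0) { xF = 0.0; ++clamps; }
    E = xE; F = xF;
    // growth (no noise), explicit in the solved efflux
    const double Qm = std::pow(p[P_Q], p[P_M]);
    const double gem = E > 0.0 ? std::pow(E, p[P_M]) : 0.0;
    const double gfm = F > 0.0 ? std::pow(F, p[P_M]) : 0.0;
    N += dt * (gem / (Qm + gem));
    M += dt * (gfm / (Qm + gfm));
    if ((k + 1) % save_every == 0) {
      Ts[isave] = (k + 1) * dt;
      Es[isave] = E; Fs[isave] = F; Ns[isave] = N; Ms[isave] = M;
      ++isave;
    }
  }
  if (isave < nsave) { // failed early: truncate
    Ts = head(Ts, isave); Es = head(Es, isave); Fs = head(Fs, isave);
    Ns = head(Ns, isave); Ms = head(Ms, isave);
  }
  return List::create(_["t"] = Ts, _["E"] = Es, _["F"] = Fs,
                      _["N"] = Ns, _["M"] = Ms, _["clamps"] = clamps,
                      _["ok"] = ok, _["fail_time"] = fail_time);
}
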