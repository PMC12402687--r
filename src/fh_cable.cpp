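// McNeal-style myelinated axon: active nodes of Ranvier with
// Frankenhaeuser-Huxley kinetics, perfectly insulating internodes.
// The cable reduces to a chain of nodal compartments coupled by the
// internodal axial conductance and driven by the extracellular potential
// sampled at the node positions (quasi-static separation: spatial field
// times a rectangular pulse waveform).
//
// Units inside the solver: mV (membrane potential, deviation from rest),
// ms, uF, uA, mS, cm2.  Ionic current densities are mA/cm2 and are
// converted to uA via the nodal area.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double FARADAY = 96485.332;   // C/mol
const double GAS_R   = 8.314462;    // J/(mol K)

// FH permeabilities (cm/s), leak (mS/cm2), concentrations (mM)
const double P_NA = 8.0e-3;
const double P_K  = 1.2e-3;
const double P_P  = 0.54e-3;
const double G_L  = 30.3;
const double NA_O = 114.5, NA_I = 13.7;
const double K_O  = 2.5,   K_I  = 120.0;

// u / (1 - exp(-u)) with the removable singularity at u = 0 filled in
inline double trap(double u) {
  if (std::fabs(u) < 1e-7) return 1.0 + 0.5 * u + u * u / 12.0;
  return u / (1.0 - std::exp(-u));
}

struct Rates {
  double am, bm, ah, bh, an, bn, ap, bp;
};

// FH rate constants (1/ms) at membrane deviation V (mV), scaled from the
// reference temperature 20 C by per-rate Q10 factors.
inline Rates fh_rates(double V, double q10m_a, double q10m_b,
                      double q10h_a, double q10h_b,
                      double q10n_a, double q10n_b) {
  Rates r;
  r.am = q10m_a * 0.36 * 3.0  * trap((V - 22.0) / 3.0);
  r.bm = q10m_b * 0.4  * 20.0 * trap((13.0 - V) / 20.0);
  r.ah = q10h_a * 0.1  * 6.0  * trap((-10.0 - V) / 6.0);
  r.bh = q10h_b * 4.5 / (1.0 + std::exp((45.0 - V) / 10.0));
  r.an = q10n_a * 0.02 * 10.0 * trap((V - 35.0) / 10.0);
  r.bn = q10n_b * 0.05 * 10.0 * trap((10.0 - V) / 10.0);
  r.ap = q10m_a * 0.006 * 10.0 * trap((V - 40.0) / 10.0);
  r.bp = q10m_b * 0.09  * 20.0 * trap((-25.0 - V) / 20.0);
  return r;
}

// Goldman-Hodgkin-Katz current density, A/cm2; co, ci in mM.
inline double ghk(double perm, double co, double ci, double e_abs_volt,
                  double f_rt) {
  double x = e_abs_volt * f_rt;
  if (std::fabs(x) < 1e-9) x = (x >= 0 ? 1e-9 : -1e-9);
  // asymptotic branches keep the flux finite under extreme passive
  // polarisation near a source (exp would overflow otherwise)
  if (x > 200.0) return perm * FARADAY * x * ci * 1e-6;
  if (x < -200.0) return perm * FARADAY * x * co * 1e-6;
  double ex = std::exp(x);
  return perm * FARADAY * x * (co * 1e-6 - ci * 1e-6 * ex) / (1.0 - ex);
}

// total ionic current density (mA/cm2) at deviation V given gates
inline double ionic_density(double V, double m, double h, double n, double p,
                            double vrest, double f_rt, double gl_rev) {
  double e_abs = (V + vrest) * 1e-3;  // volts
  double iNa = m * m * h * ghk(P_NA, NA_O, NA_I, e_abs, f_rt) * 1e3;
  double iK  = n * n * ghk(P_K, K_O, K_I, e_abs, f_rt) * 1e3;
  double iP  = p * p * ghk(P_P, NA_O, NA_I, e_abs, f_rt) * 1e3;
  double iL  = G_L * (V - gl_rev) * 1e-3; // mS/cm2 * mV = uA/cm2 -> mA/cm2
  return iNa + iK + iP + iL;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".fh_cable_sim")]]
List fh_cable_sim(NumericVector ve_spatial_mv,
                  double dt_ms,
                  double sim_window_ms,
                  double t_on_ms,
                  double t_off_ms,
                  double area_cm2,
                  double cm_uf_cm2,
                  double ga_ms,
                  double temp_c,
                  double vrest_mv,
                  double detect_mv_abs,
                  double blowup_mv_abs) {
  const int n = ve_spatial_mv.size();
  if (n < 2) stop("axon needs at least 2 nodes");
  const int nsteps = (int)std::ceil(sim_window_ms / dt_ms);
  const double t_kelvin = temp_c + 273.15;
  const double f_rt = FARADAY / (GAS_R * t_kelvin);
  const double q = (temp_c - 20.0) / 10.0;
  const double q10m_a = std::pow(1.8, q), q10m_b = std::pow(1.7, q);
  const double q10h_a = std::pow(2.8, q), q10h_b = std::pow(2.9, q);
  const double q10n_a = std::pow(3.2, q), q10n_b = std::pow(2.8, q);

  // steady-state gates at rest (V = 0 deviation)
  Rates r0 = fh_rates(0.0, q10m_a, q10m_b, q10h_a, q10h_b, q10n_a, q10n_b);
  std::vector<double> m(n, r0.am / (r0.am + r0.bm));
  std::vector<double> h(n, r0.ah / (r0.ah + r0.bh));
  std::vector<double> gn(n, r0.an / (r0.an + r0.bn));
  std::vector<double> gp(n, r0.ap / (r0.ap + r0.bp));

  // leak reversal chosen so the total ionic current vanishes at rest
  double i0 = ionic_density(0.0, m[0], h[0], gn[0], gp[0], vrest_mv, f_rt, 0.0);
  const double gl_rev = i0 / (G_L * 1e-3); // mV

  const double c_node = cm_uf_cm2 * area_cm2;      // uF
  const double cdt = c_node / dt_ms;               // uA/mV
  const double dv_detect = detect_mv_abs - vrest_mv;
  const double dv_blow = blowup_mv_abs - vrest_mv;

  std::vector<double> V(n, 0.0), dV(n), rhs(n), diag(n), sub(n), sup(n);
  std::vector<double> gion(n), i_now(n);

  bool activated = false, blowup = false;
  double peak = 0.0; int peak_node = 0;
  double t_detect = NA_REAL; int detect_node = -1;
  int init_node = -1;  // first node anywhere to cross the detection level
  double max_dev = 0.0;

  for (int s = 0; s < nsteps; ++s) {
    double t0 = s * dt_ms, t1 = (s + 1) * dt_ms;
    double w0 = (t0 >= t_on_ms && t0 < t_off_ms) ? 1.0 : 0.0;
    double w1 = (t1 >= t_on_ms && t1 < t_off_ms) ? 1.0 : 0.0;

    // gate update: exponential Euler at the current voltage
    for (int i = 0; i < n; ++i) {
      Rates r = fh_rates(V[i], q10m_a, q10m_b, q10h_a, q10h_b, q10n_a, q10n_b);
      double tm = r.am + r.bm, th = r.ah + r.bh,
             tn = r.an + r.bn, tp = r.ap + r.bp;
      m[i]  = r.am / tm + (m[i]  - r.am / tm) * std::exp(-dt_ms * tm);
      h[i]  = r.ah / th + (h[i]  - r.ah / th) * std::exp(-dt_ms * th);
      gn[i] = r.an / tn + (gn[i] - r.an / tn) * std::exp(-dt_ms * tn);
      gp[i] = r.ap / tp + (gp[i] - r.ap / tp) * std::exp(-dt_ms * tp);
    }

    // ionic current (uA) and local slope conductance (uA/mV), linearized
    for (int i = 0; i < n; ++i) {
      double id0 = ionic_density(V[i], m[i], h[i], gn[i], gp[i],
                                 vrest_mv, f_rt, gl_rev);
      double id1 = ionic_density(V[i] + 0.01, m[i], h[i], gn[i], gp[i],
                                 vrest_mv, f_rt, gl_rev);
      i_now[i] = id0 * area_cm2 * 1e3;                   // uA
      double g = (id1 - id0) / 0.01 * area_cm2 * 1e3;    // uA/mV
      gion[i] = (g > 0.0) ? g : 0.0; // keep the step matrix diagonally dominant
    }

    // Crank-Nicolson on the axial term, implicit on the linearized ionic term.
    // Axial operator L(u)_i = ga * (u_{i-1} - 2 u_i + u_{i+1}), sealed ends.
    for (int i = 0; i < n; ++i) {
      double lu = 0.0, lv = 0.0; // L(V), L(Ve-average)
      double vem = 0.0, ve0 = ve_spatial_mv[i] * 0.5 * (w0 + w1), vep = 0.0;
      if (i > 0) {
        lu += ga_ms * (V[i - 1] - V[i]);
        vem = ve_spatial_mv[i - 1] * 0.5 * (w0 + w1);
        lv += ga_ms * (vem - ve0);
      }
      if (i < n - 1) {
        lu += ga_ms * (V[i + 1] - V[i]);
        vep = ve_spatial_mv[i + 1] * 0.5 * (w0 + w1);
        lv += ga_ms * (vep - ve0);
      }
      rhs[i] = lu + lv - i_now[i];
      double nadj = ((i > 0) ? 1.0 : 0.0) + ((i < n - 1) ? 1.0 : 0.0);
      diag[i] = cdt + gion[i] + 0.5 * ga_ms * nadj;
      sub[i] = sup[i] = -0.5 * ga_ms;
    }

    // Thomas algorithm for the tridiagonal system in dV
    {
      std::vector<double> cp(n), dp(n);
      cp[0] = sup[0] / diag[0];
      dp[0] = rhs[0] / diag[0];
      for (int i = 1; i < n; ++i) {
        double mlt = diag[i] - sub[i] * cp[i - 1];
        cp[i] = sup[i] / mlt;
        dp[i] = (rhs[i] - sub[i] * dp[i - 1]) / mlt;
      }
      dV[n - 1] = dp[n - 1];
      for (int i = n - 2; i >= 0; --i) dV[i] = dp[i] - cp[i] * dV[i + 1];
    }

    for (int i = 0; i < n; ++i) {
      V[i] += dV[i];
      double ad = std::fabs(V[i]);
      if (ad > max_dev) max_dev = ad;
      if (V[i] > peak) { peak = V[i]; peak_node = i; }
      if (ad > dv_blow || !std::isfinite(V[i])) blowup = true;
      if (init_node < 0 && V[i] >= dv_detect) init_node = i;
    }
    if (blowup) break;
    if (!activated) {
      if (V[0] >= dv_detect) {
        activated = true; detect_node = 0; t_detect = t1;
      } else if (V[n - 1] >= dv_detect) {
        activated = true; detect_node = n - 1; t_detect = t1;
      }
    }
  }

  return List::create(
    _["activated"] = activated && !blowup,
    _["peak_vm_mv"] = peak + vrest_mv,
    _["peak_node"] = peak_node + 1,
    _["detect_node"] = (detect_node >= 0) ? IntegerVector::create(detect_node + 1)
                                          : IntegerVector::create(NA_INTEGER),
    _["t_detect_ms"] = t_detect,
    _["init_node"] = (init_node >= 0) ? IntegerVector::create(init_node + 1)
                                      : IntegerVector::create(NA_INTEGER),
    _["max_deviation_mv"] = max_dev,
    _["blowup"] = blowup);
}
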