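#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Branched-cable integrator (backward Euler, Hines elimination).
//
// Units: mV, ms, nA, uS, nF; channel densities S/cm2; calcium nM.
// Compartments must be topologically ordered (parent index < child index,
// root = 0 with parent -1); the builder in R/compartmental.R guarantees this.
//
// The N-type calcium channel is an m^2 Hodgkin-Huxley style activation with
// ohmic driving force; gating is advanced explicitly (tau_m = 1 ms), the
// resulting conductance enters the implicit voltage solve. The per-
// compartment calcium pool relaxes to ca_rest with time constant ca_tau and
// is driven by the inward calcium current density.
//
// syn_g: matrix (n_tg x n_syn) of synaptic conductances (uS) sampled at
// dt_g; linearly interpolated onto solver steps. inj_*: step current
// injections. Voltage and calcium are recorded at rec_idx every out_dt.

// [[Rcpp::export]]
List sim_cable_cpp(IntegerVector parent, NumericVector g_axial,
                   NumericVector cap, NumericVector g_pas,
                   NumericVector area_cm2, double e_rev,
                   NumericVector g_can, double can_vhalf, double can_slope,
                   double can_taum, double e_ca,
                   double ca_tau, double ca_rest, double ca_scale,
                   IntegerVector syn_idx, NumericMatrix syn_g, double dt_g,
                   double e_syn,
                   IntegerVector inj_idx, NumericVector inj_amp,
                   double inj_t0, double inj_t1,
                   double t_stop, double dt,
                   IntegerVector rec_idx, double out_dt) {
  const int n = parent.size();
  const int n_syn = syn_idx.size();
  const int n_tg = syn_g.nrow();
  const int n_rec = rec_idx.size();
  const int n_steps = (int)std::round(t_stop / dt);
  const int out_every = std::max(1, (int)std::round(out_dt / dt));
  const int n_out = n_steps / out_every + 1;

  std::vector<double> v(n, e_rev), ca(n, ca_rest), m(n, 0.0);
  std::vector<double> d(n), rhs(n), gsyn(n);
  bool has_can = false;
  for (int i = 0; i < n; ++i) if (g_can[i] > 0.0) { has_can = true; break; }

  // m_inf lookup table (linear interpolation) over -120..60 mV
  const double v_lo = -120.0, v_hi = 60.0, v_step = 0.05;
  const int n_tab = (int)((v_hi - v_lo) / v_step) + 2;
  std::vector<double> minf_tab(n_tab);
  for (int k = 0; k < n_tab; ++k) {
    double vv = v_lo + k * v_step;
    minf_tab[k] = 1.0 / (1.0 + std::exp(-(vv - can_vhalf) / can_slope));
  }
  auto minf = [&](double vv) {
    if (vv <= v_lo) return minf_tab[0];
    if (vv >= v_hi) return minf_tab[n_tab - 2];
    double u = (vv - v_lo) / v_step;
    int k = (int)u;
    double w = u - k;
    return (1.0 - w) * minf_tab[k] + w * minf_tab[k + 1];
  };
  // steady-state gating at rest
  for (int i = 0; i < n; ++i) m[i] = minf(v[i]);

  NumericMatrix out_v(n_out, n_rec), out_ca(n_out, n_rec);
  NumericVector out_t(n_out);
  int out_row = 0;
  for (int r = 0; r < n_rec; ++r) {
    out_v(0, r) = v[rec_idx[r]];
    out_ca(0, r) = ca[rec_idx[r]];
  }
  out_t[0] = 0.0;
  out_row = 1;

  for (int s = 1; s <= n_steps; ++s) {
    double t = s * dt;
    // synaptic conductances at time t (linear interpolation)
    std::fill(gsyn.begin(), gsyn.end(), 0.0);
    if (n_syn > 0) {
      double u = t / dt_g;
      int k = (int)std::floor(u);
      double w = u - k;
      if (k >= n_tg - 1) { k = n_tg - 1; w = 0.0; }
      for (int j = 0; j < n_syn; ++j) {
        double g = (w > 0.0) ? (1.0 - w) * syn_g(k, j) + w * syn_g(k + 1, j)
                             : syn_g(k, j);
        gsyn[syn_idx[j]] += g;
      }
    }
    bool injecting = (t > inj_t0 && t <= inj_t1);

    // explicit gating update, then conductances for the implicit solve
    if (has_can) {
      for (int i = 0; i < n; ++i) {
        m[i] += dt * (minf(v[i]) - m[i]) / can_taum;
        double gca = g_can[i] * m[i] * m[i] * area_cm2[i] * 1e6;  // uS
        d[i] = cap[i] / dt + g_pas[i] + gsyn[i] + gca;
        rhs[i] = cap[i] / dt * v[i] + g_pas[i] * e_rev + gsyn[i] * e_syn +
                 gca * e_ca;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        d[i] = cap[i] / dt + g_pas[i] + gsyn[i];
        rhs[i] = cap[i] / dt * v[i] + g_pas[i] * e_rev + gsyn[i] * e_syn;
      }
    }
    if (injecting)
      for (int j = 0; j < inj_idx.size(); ++j) rhs[inj_idx[j]] += inj_amp[j];
    for (int i = 1; i < n; ++i) {
      d[i] += g_axial[i];
      d[parent[i]] += g_axial[i];
    }
    // Hines elimination: leaves to root, then forward substitution
    for (int i = n - 1; i >= 1; --i) {
      double f = g_axial[i] / d[i];
      d[parent[i]] -= f * g_axial[i];
      rhs[parent[i]] += f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) v[i] = (rhs[i] + g_axial[i] * v[parent[i]]) / d[i];

    // calcium pool driven by inward calcium current density (mA/cm2)
    if (has_can) {
      for (int i = 0; i < n; ++i) {
        double ica = g_can[i] * m[i] * m[i] * (v[i] - e_ca);  // mA/cm2
        double influx = ica < 0.0 ? -ica : 0.0;
        ca[i] += dt * (-(ca[i] - ca_rest) / ca_tau + ca_scale * influx);
        if (ca[i] < 0.0) ca[i] = 0.0;
      }
    }

    if (std::abs(v[0]) > 200.0 || !std::isfinite(v[0]))
      stop("cable integration unstable (|V| > 200 mV or non-finite)");

    if (s % out_every == 0 && out_row < n_out) {
      for (int r = 0; r < n_rec; ++r) {
        out_v(out_row, r) = v[rec_idx[r]];
        out_ca(out_row, r) = ca[rec_idx[r]];
      }
      out_t[out_row] = t;
      ++out_row;
    }
  }
  return List::create(_["t"] = out_t, _["v"] = out_v, _["ca"] = out_ca);
}
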