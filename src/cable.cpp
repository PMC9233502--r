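// Semi-implicit compartmental cable integrator with NMDA/AMPA synapses,
// a distance-graded Ih conductance, and an adaptive-exponential spiking
// mechanism at the soma. Units: ms, mV, nS, pF, pA. The tree matrix is
// solved each step with a Hines-ordered elimination (parents precede
// children), O(n) per step. Membrane conductances are treated implicitly
// (added to the diagonal) with gating evaluated at the previous voltage;
// the AdEx exponential term and adaptation current are explicit.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// parent: 0-based (-1 for root); cap pF; g_leak, g_ax, g_h nS; e_leak mV;
// ih: list(e, v_half, k, tau); adex: list(enabled, delta_t, v_t, v_reset,
// a_w, b_w, tau_w); syn_comp 0-based; ev_time ms sorted; ev_syn 0-based;
// i_inj pA into the soma per step (length 0 or n_steps).
// [[Rcpp::export]]
List simulate_cable_cpp(IntegerVector parent, NumericVector cap,
                        NumericVector g_leak, double e_leak,
                        NumericVector g_ax, NumericVector g_h, List ih,
                        List adex, IntegerVector syn_comp,
                        NumericVector syn_g_ampa, NumericVector syn_g_nmda,
                        NumericVector ev_time, IntegerVector ev_syn,
                        NumericVector i_inj, double duration, double dt,
                        double v0, bool record_all, int record_every) {
  const int n = parent.size();
  const int n_syn = syn_comp.size();
  const int n_steps = (int)std::round(duration / dt);

  const double ih_e = ih["e"], ih_vh = ih["v_half"], ih_k = ih["k"],
               ih_tau = ih["tau"];
  const bool adex_on = as<bool>(adex["enabled"]);
  const double delta_t = adex["delta_t"], v_t = adex["v_t"],
               v_reset = adex["v_reset"], a_w = adex["a_w"],
               b_w = adex["b_w"], tau_w = adex["tau_w"],
               t_ref = adex["t_ref"];

  const double dec_a = std::exp(-dt / 0.5);   // AMPA decay, tau 0.5 ms
  const double dec_nd = std::exp(-dt / 70.0); // NMDA decay
  const double dec_nr = std::exp(-dt / 3.0);  // NMDA rise

  std::vector<double> v(n, v0), m(n);
  for (int i = 0; i < n; ++i) {               // Ih gate at steady state
    m[i] = 1.0 / (1.0 + std::exp((v0 - ih_vh) / ih_k));
  }
  std::vector<double> sa(n_syn, 0.0), sd(n_syn, 0.0), sr(n_syn, 0.0);
  std::vector<double> diag(n), rhs(n);
  double w = 0.0;                             // AdEx adaptation, pA

  std::vector<double> spikes;
  int n_rec = n_steps / record_every + 1;
  NumericVector t_rec(n_rec), v_soma(n_rec);
  NumericMatrix v_all;
  if (record_all) v_all = NumericMatrix(n_rec, n);

  int ev_ptr = 0, rec_i = 0;
  double ref_until = -1.0;

  for (int s = 0; s <= n_steps; ++s) {
    double t = s * dt;
    if (s % record_every == 0 && rec_i < n_rec) {
      t_rec[rec_i] = t;
      v_soma[rec_i] = v[0];
      if (record_all) for (int i = 0; i < n; ++i) v_all(rec_i, i) = v[i];
      ++rec_i;
    }
    if (s == n_steps) break;

    // deliver events in [t, t+dt)
    while (ev_ptr < ev_time.size() && ev_time[ev_ptr] < t + dt) {
      int k = ev_syn[ev_ptr];
      sa[k] += 1.0; sd[k] += 1.0; sr[k] += 1.0;
      ++ev_ptr;
    }

    // assemble diagonal and rhs
    for (int i = 0; i < n; ++i) {
      diag[i] = cap[i] / dt + g_leak[i];
      rhs[i] = cap[i] / dt * v[i] + g_leak[i] * e_leak;
      if (g_h[i] > 0.0) {
        double minf = 1.0 / (1.0 + std::exp((v[i] - ih_vh) / ih_k));
        m[i] += dt * (minf - m[i]) / ih_tau;
        diag[i] += g_h[i] * m[i];
        rhs[i] += g_h[i] * m[i] * ih_e;
      }
    }
    for (int i = 1; i < n; ++i) {
      diag[i] += g_ax[i];
      diag[parent[i]] += g_ax[i];
    }
    // synaptic conductances (reversal 0 mV: nothing on rhs); each synapse
    // saturates at its maximum conductance under repeated activation
    for (int k = 0; k < n_syn; ++k) {
      double g = 0.0;
      if (sa[k] > 1e-12) g += syn_g_ampa[k] * std::min(sa[k], 1.0);
      double nm = sd[k] - sr[k];
      if (nm > 1e-12) {
        int c = syn_comp[k];
        if (nm > 1.0) nm = 1.0;
        g += syn_g_nmda[k] * nm /
             (1.0 + 0.3 * std::exp(-0.08 * v[c]));
      }
      if (g > 0.0) diag[syn_comp[k]] += g;
    }
    // soma: AdEx explicit terms and injected current
    if (adex_on && t >= ref_until) {
      double ex = (v[0] - v_t) / delta_t;
      if (ex > 10.0) ex = 10.0;               // overflow guard before reset
      rhs[0] += g_leak[0] * delta_t * std::exp(ex) - w;
    }
    if (i_inj.size() > s) rhs[0] += i_inj[s];

    // Hines elimination (children have larger indices than parents)
    for (int i = n - 1; i >= 1; --i) {
      double f = g_ax[i] / diag[i];
      diag[parent[i]] -= g_ax[i] * f;
      rhs[parent[i]] += rhs[i] * f;
    }
    double v_soma_old = v[0];
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      v[i] = (rhs[i] + g_ax[i] * v[parent[i]]) / diag[i];
    }

    // AdEx adaptation, spike-reset, absolute refractory
    if (adex_on) {
      w += dt * (a_w * (v_soma_old - e_leak) - w) / tau_w;
      if (t + dt < ref_until) {
        v[0] = v_reset;
      } else if (v[0] > 0.0) {
        spikes.push_back(t + dt);
        w += b_w;
        v[0] = v_reset;
        ref_until = t + dt + t_ref;
      }
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 200.0) {
        stop("numerical blow-up: |v| > 200 mV at t = %f ms in compartment %d",
             t, i + 1);
      }
    }

    // synapse state decay
    for (int k = 0; k < n_syn; ++k) {
      sa[k] *= dec_a; sd[k] *= dec_nd; sr[k] *= dec_nr;
    }
  }

  List out = List::create(_["t"] = t_rec, _["v_soma"] = v_soma,
                          _["spikes"] = NumericVector(spikes.begin(),
                                                      spikes.end()));
  if (record_all) out["v_all"] = v_all;
  return out;
}
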