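#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Build the pixel -> receptive-field membership map in CSR form.
// x0, y0, size: per-RF bounding boxes (0-based anchors). Returns ptr of
// length W*H+1 (0-based offsets into ids) and ids (1-based RF ids), pixels
// indexed as y*W + x.
// [[Rcpp::export]]
List cpp_pixel_map(IntegerVector x0, IntegerVector y0, IntegerVector size,
                   int width, int height) {
  const int n_rf = x0.size();
  const int n_px = width * height;
  std::vector<int> cnt(n_px, 0);
  for (int i = 0; i < n_rf; ++i) {
    for (int yy = y0[i]; yy < y0[i] + size[i]; ++yy)
      for (int xx = x0[i]; xx < x0[i] + size[i]; ++xx)
        cnt[yy * width + xx]++;
  }
  IntegerVector ptr(n_px + 1);
  for (int p = 0; p < n_px; ++p) ptr[p + 1] = ptr[p] + cnt[p];
  IntegerVector ids(ptr[n_px]);
  std::vector<int> fill(n_px, 0);
  for (int i = 0; i < n_rf; ++i) {
    for (int yy = y0[i]; yy < y0[i] + size[i]; ++yy)
      for (int xx = x0[i]; xx < x0[i] + size[i]; ++xx) {
        int p = yy * width + xx;
        ids[ptr[p] + fill[p]++] = i + 1;
      }
  }
  return List::create(_["ptr"] = ptr, _["ids"] = ids);
}

// Event-driven leaky integration of an event stream into per-RF spike
// trains: on each event falling inside an RF, M <- M*exp(-dt/tau) + 1/rnf;
// when M >= threshold the RF emits a spike at the event time and resets to 0.
// ev_t must be sorted ascending; ev_px is y*W+x (0-based).
// [[Rcpp::export]]
List cpp_rf_integrate(NumericVector ev_t, IntegerVector ev_px,
                      IntegerVector ptr, IntegerVector ids,
                      NumericVector rnf, double tau, double threshold) {
  const int n_ev = ev_t.size();
  const int n_rf = rnf.size();
  std::vector<double> M(n_rf, 0.0), t_last(n_rf, 0.0);
  std::vector<int> out_rf;
  std::vector<double> out_t;
  for (int e = 0; e < n_ev; ++e) {
    const double t = ev_t[e];
    const int p = ev_px[e];
    for (int k = ptr[p]; k < ptr[p + 1]; ++k) {
      const int r = ids[k] - 1;
      const double dt = t - t_last[r];
      M[r] = M[r] * std::exp(-dt / tau) + 1.0 / rnf[r];
      t_last[r] = t;
      if (M[r] >= threshold) {
        out_rf.push_back(r + 1);
        out_t.push_back(t);
        M[r] = 0.0;
      }
    }
  }
  return List::create(_["rf"] = wrap(out_rf), _["t"] = wrap(out_t));
}

// ---- TDE neuron -----------------------------------------------------------
// Fixed-step simulation of the time-difference-encoder unit: a facilitator
// spike (after its wiring delay) sets a gain trace to 1, decaying with
// tau_gain; a trigger spike injects a conductance-based EPSC of amplitude
// w_syn * gain(t) with reversal e_ex, decaying with tau_ex; a current-free
// LIF soma integrates it. Input spikes are quantized to the simulation tick
// (floor), and within a tick triggers are processed before facilitators, so
// coincident inputs do not drive the unit. Membrane threshold crossings are
// located in closed form inside the step, so the spike count is essentially
// step-size independent.
struct TdeParams {
  double w_syn, tau_ex, tau_gain, c_m, tau_m, tau_refrac;
  double v_reset, v_rest, v_thresh, e_ex, fac_delay, dt;
};

static void tde_unit(const double* fac, int nf, const double* trig, int nt,
                     const TdeParams& P, std::vector<double>& out) {
  if (nt == 0) return;
  const double dt = P.dt;
  const double g_leak = P.c_m / P.tau_m;  // nF/ms = uS
  // delivery ticks
  std::vector<double> fd(nf), td(nt);
  for (int i = 0; i < nf; ++i) fd[i] = std::floor((fac[i] + P.fac_delay) / dt) * dt;
  for (int i = 0; i < nt; ++i) td[i] = std::floor(trig[i] / dt) * dt;
  double t0 = td[0];
  if (nf > 0) t0 = std::min(t0, fd[0]);
  const double t_end = td[nt - 1] + 200.0;
  double gain_t = -1e300;       // delivery time of most recent facilitator
  bool have_fac = false;
  double gsyn = 0.0, V = P.v_rest, refrac_until = -1e300;
  int i_f = 0, i_t = 0;
  const double dec_ex = std::exp(-dt / P.tau_ex);
  double t = t0;
  while (t < t_end) {
    // idle fast-forward to the next input once the EPSC has died away
    // (membrane relaxation over the gap is applied in closed form)
    if (gsyn < 1e-9 && refrac_until <= t) {
      if (i_t >= nt) break;  // no trigger left, so no further spike possible
      double tn = td[i_t];
      if (i_f < nf && fd[i_f] < tn) tn = fd[i_f];
      const double tj = std::floor(tn / dt) * dt;
      if (tj >= t + dt) {
        V = P.v_rest + (V - P.v_rest) * std::exp(-(tj - t) / P.tau_m);
        gsyn *= std::exp(-(tj - t) / P.tau_ex);
        t = tj;
        continue;
      }
    }
    const double t_next = t + dt;
    // deliver this tick's inputs: triggers first, then facilitators
    while (i_t < nt && td[i_t] < t_next - 1e-9) {
      const double g = have_fac ? std::exp(-(td[i_t] - gain_t) / P.tau_gain) : 0.0;
      if (g > 0) gsyn += P.w_syn * g;
      ++i_t;
    }
    while (i_f < nf && fd[i_f] < t_next - 1e-9) {
      gain_t = fd[i_f];
      have_fac = true;
      ++i_f;
    }
    // integrate [t, t+dt) with the conductance frozen at its tick value
    double s = t;
    while (s < t_next - 1e-12) {
      if (refrac_until > s) {
        V = P.v_reset;
        s = std::min(t_next, refrac_until);
        continue;
      }
      const double g_tot = g_leak + gsyn;
      const double v_inf = (g_leak * P.v_rest + gsyn * P.e_ex) / g_tot;
      const double tau_eff = P.c_m / g_tot;
      if (v_inf >= P.v_thresh && V < P.v_thresh) {
        const double t_cross = s + tau_eff * std::log((v_inf - V) / (v_inf - P.v_thresh));
        if (t_cross <= t_next) {
          out.push_back(t_cross);
          V = P.v_reset;
          refrac_until = t_cross + P.tau_refrac;
          s = t_cross;
          continue;
        }
      }
      V = v_inf + (V - v_inf) * std::exp(-(t_next - s) / tau_eff);
      if (V > P.v_thresh) V = P.v_thresh;  // guard (crossing handled above)
      s = t_next;
    }
    gsyn *= dec_ex;
    t = t_next;
  }
}

static TdeParams unpack_params(List params) {
  TdeParams P;
  P.w_syn = as<double>(params["w_syn"]);
  P.tau_ex = as<double>(params["tau_ex_ms"]);
  P.tau_gain = as<double>(params["tau_gain_ms"]);
  P.c_m = as<double>(params["c_m_nf"]);
  P.tau_m = as<double>(params["tau_m_ms"]);
  P.tau_refrac = as<double>(params["tau_refrac_ms"]);
  P.v_reset = as<double>(params["v_reset_mv"]);
  P.v_rest = as<double>(params["v_rest_mv"]);
  P.v_thresh = as<double>(params["v_thresh_mv"]);
  P.e_ex = as<double>(params["e_ex_mv"]);
  P.fac_delay = as<double>(params["fac_delay_ms"]);
  P.dt = as<double>(params["dt_sim_ms"]);
  return P;
}

// Single TDE unit: returns output spike times (ms).
// [[Rcpp::export]]
NumericVector cpp_tde_response(NumericVector fac, NumericVector trig,
                               List params) {
  TdeParams P = unpack_params(params);
  std::vector<double> out;
  tde_unit(fac.begin(), fac.size(), trig.begin(), trig.size(), P, out);
  return wrap(out);
}

// Simulate a whole direction population. sp_t holds all RF spike times
// grouped by RF id (rf_ptr: 0-based CSR offsets, length n_rf+1, times sorted
// within each RF); fac_rf / trig_rf give each unit's input RFs (1-based).
// [[Rcpp::export]]
List cpp_tde_population(NumericVector sp_t, IntegerVector rf_ptr,
                        IntegerVector fac_rf, IntegerVector trig_rf,
                        List params) {
  TdeParams P = unpack_params(params);
  const int n_units = fac_rf.size();
  std::vector<int> out_unit;
  std::vector<double> out_t, buf;
  for (int u = 0; u < n_units; ++u) {
    const int f = fac_rf[u] - 1, g = trig_rf[u] - 1;
    const int nf = rf_ptr[f + 1] - rf_ptr[f];
    const int nt = rf_ptr[g + 1] - rf_ptr[g];
    if (nt == 0 || nf == 0) continue;
    buf.clear();
    tde_unit(sp_t.begin() + rf_ptr[f], nf, sp_t.begin() + rf_ptr[g], nt, P, buf);
    for (size_t k = 0; k < buf.size(); ++k) {
      out_unit.push_back(u + 1);
      out_t.push_back(buf[k]);
    }
  }
  return List::create(_["unit"] = wrap(out_unit), _["t"] = wrap(out_t));
}
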