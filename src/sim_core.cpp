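// Time-stepped integrator for the lamellar network.
//
// Units: ms, mV, nS, pF, pA. Conductance-based leaky integrate-and-fire
// cells with a spike-triggered adaptation conductance; synapses are
// single-exponential conductances with per-class decay, delay and reversal,
// and Tsodyks-Markram-style facilitation (utilisation u rises toward 1 with
// each presynaptic spike and relaxes with tau_facil; the per-spike
// conductance increment is weight * u / U, so an isolated spike delivers
// exactly `weight`). All randomness lives on the R side: given identical
// arguments this routine is bit-reproducible.
//
// Unit indexing: units 0 .. n_pp-1 are perforant-path spike sources with
// prescribed spike times; units n_pp .. n_pp+n_cells-1 are integrated cells.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

struct Delivery {
  int post;
  int cls;
  double amt;
};

// [[Rcpp::export]]
List sim_core(int n_pp,
              int n_cells,
              IntegerVector cell_type,       // n_cells, 0-based type index
              NumericMatrix type_params,     // n_types x 10: C gL EL Vth Vreset tref b tau_w E_adapt Vinit
              NumericVector cell_vth,        // n_cells, per-cell spike threshold (mV)
              IntegerVector edge_ptr,        // n_units+1 CSR offsets (by pre unit)
              IntegerVector edge_post,       // 0-based cell index
              IntegerVector edge_class,      // 0-based class index
              NumericVector edge_weight,     // nS
              NumericVector cls_tau,         // ms, decay > 0
              NumericVector cls_tau_facil,   // ms, 0 disables facilitation
              NumericVector cls_U,           // baseline utilisation in (0,1]
              NumericVector cls_delay,       // ms
              NumericVector cls_erev,        // mV
              List pp_spikes,                // n_pp sorted spike-time vectors (ms)
              NumericMatrix inj,             // k x 4: cell(0-based) start dur amp(pA)
              IntegerVector clamp_cells,     // 0-based cells held at clamp_v
              double clamp_v,
              bool record_probe,
              NumericVector noise_sd,        // n_types, pA * sqrt(ms)
              int noise_seed,
              double dt,
              double duration) {
  const int n_units = n_pp + n_cells;
  const int n_cls = cls_tau.size();
  const int n_steps = (int)std::ceil(duration / dt);

  // per-class decay factors and delay steps
  std::vector<double> decay(n_cls);
  std::vector<int> dsteps(n_cls);
  int max_d = 1;
  for (int c = 0; c < n_cls; ++c) {
    decay[c] = std::exp(-dt / cls_tau[c]);
    dsteps[c] = std::max(1, (int)std::lround(cls_delay[c] / dt));
    if (dsteps[c] > max_d) max_d = dsteps[c];
  }
  const int H = max_d + 1;
  std::vector< std::vector<Delivery> > sched(H);

  // conductance state, flat [cls][cell]
  std::vector<double> g((size_t)n_cls * n_cells, 0.0);

  // facilitation state per (pre unit, class)
  std::vector<double> fac_u((size_t)n_units * n_cls, 0.0);
  std::vector<double> fac_t((size_t)n_units * n_cls, -1e18);
  std::vector<double> fac_factor((size_t)n_units * n_cls, 1.0);
  std::vector<double> fac_done((size_t)n_units * n_cls, -1e18);

  // unpack type parameters into flat arrays (hot loop)
  const int n_types = type_params.nrow();
  std::vector<double> tp_C(n_types), tp_gL(n_types), tp_EL(n_types),
      tp_Vre(n_types), tp_tref(n_types), tp_b(n_types), tp_Ead(n_types),
      tp_adk(n_types);
  for (int y = 0; y < n_types; ++y) {
    tp_C[y] = type_params(y, 0);
    tp_gL[y] = type_params(y, 1);
    tp_EL[y] = type_params(y, 2);
    tp_Vre[y] = type_params(y, 4);
    tp_tref[y] = type_params(y, 5);
    tp_b[y] = type_params(y, 6);
    tp_Ead[y] = type_params(y, 8);
    tp_adk[y] = std::exp(-dt / type_params(y, 7));
  }

  // membrane state
  std::vector<double> V(n_cells), g_ad(n_cells, 0.0);
  std::vector<int> refr(n_cells, 0);
  std::vector<char> clamped(n_cells, 0);
  for (int i = 0; i < clamp_cells.size(); ++i) clamped[clamp_cells[i]] = 1;
  for (int i = 0; i < n_cells; ++i)
    V[i] = clamped[i] ? clamp_v : type_params(cell_type[i], 9);

  // PP events bucketed by step
  std::vector< std::vector<int> > pp_by_step(n_steps);
  for (int p = 0; p < n_pp; ++p) {
    NumericVector st = pp_spikes[p];
    for (int k = 0; k < st.size(); ++k) {
      int s = (int)std::lround(st[k] / dt);
      if (s >= 0 && s < n_steps) pp_by_step[s].push_back(p);
    }
  }

  const int n_probe = clamp_cells.size();
  NumericMatrix probe_inh(record_probe ? n_steps : 0, record_probe ? n_probe : 0);
  NumericMatrix probe_exc(record_probe ? n_steps : 0, record_probe ? n_probe : 0);

  // membrane current noise (white, per cell, amplitude per type)
  bool any_noise = false;
  for (int y = 0; y < n_types; ++y) if (noise_sd[y] > 0) any_noise = true;
  std::mt19937_64 rng((unsigned long long)noise_seed + 0x9e3779b97f4a7c15ULL);
  std::normal_distribution<double> ndist(0.0, 1.0);
  const double inv_sqrt_dt = 1.0 / std::sqrt(dt);

  std::vector<int> out_cell;
  std::vector<double> out_time;
  out_cell.reserve(1024);
  out_time.reserve(1024);

  std::vector<double> I_inj(n_cells, 0.0);
  const int n_inj = inj.nrow();

  // deliver all edges of a spiking unit at time t
  auto fire = [&](int unit, double t, int step) {
    for (int e = edge_ptr[unit]; e < edge_ptr[unit + 1]; ++e) {
      const double w = edge_weight[e];
      if (w == 0.0) continue;
      const int c = edge_class[e];
      const size_t fi = (size_t)unit * n_cls + c;
      if (fac_done[fi] != t) {               // update facilitation once per (unit, class, spike)
        const double tauF = cls_tau_facil[c];
        double factor = 1.0;
        if (tauF > 0.0) {
          double u = fac_u[fi];
          if (fac_t[fi] > -1e17) u *= std::exp(-(t - fac_t[fi]) / tauF);
          u += cls_U[c] * (1.0 - u);
          fac_u[fi] = u;
          fac_t[fi] = t;
          factor = u / cls_U[c];
        }
        fac_factor[fi] = factor;
        fac_done[fi] = t;
      }
      Delivery d;
      d.post = edge_post[e];
      d.cls = c;
      d.amt = w * fac_factor[fi];
      sched[(step + dsteps[c]) % H].push_back(d);
    }
  };

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // apply deliveries scheduled for this step
    std::vector<Delivery>& slot = sched[s % H];
    for (size_t k = 0; k < slot.size(); ++k)
      g[(size_t)slot[k].cls * n_cells + slot[k].post] += slot[k].amt;
    slot.clear();

    // PP input spikes
    const std::vector<int>& pps = pp_by_step[s];
    for (size_t k = 0; k < pps.size(); ++k) fire(pps[k], t, s);

    // current injections
    if (n_inj > 0) {
      std::fill(I_inj.begin(), I_inj.end(), 0.0);
      for (int k = 0; k < n_inj; ++k) {
        if (t >= inj(k, 1) && t < inj(k, 1) + inj(k, 2))
          I_inj[(int)inj(k, 0)] += inj(k, 3);
      }
    }

    // membrane update + spike detection
    for (int i = 0; i < n_cells; ++i) {
      if (clamped[i]) continue;
      const int ty = cell_type[i];
      // noise is drawn unconditionally so the stream depends only on
      // (step, cell), keeping paired runs comparable
      double In = 0.0;
      if (any_noise && noise_sd[ty] > 0)
        In = noise_sd[ty] * ndist(rng) * inv_sqrt_dt;
      if (refr[i] > 0) {
        --refr[i];
        V[i] = tp_Vre[ty];
        g_ad[i] *= tp_adk[ty];
        continue;
      }
      double Isyn = 0.0;
      for (int c = 0; c < n_cls; ++c) {
        const double gc = g[(size_t)c * n_cells + i];
        if (gc > 0.0) Isyn += gc * (cls_erev[c] - V[i]);
      }
      const double Iad = g_ad[i] * (tp_Ead[ty] - V[i]);
      V[i] += dt / tp_C[ty] *
        (tp_gL[ty] * (tp_EL[ty] - V[i]) + Isyn + Iad + In +
         (n_inj ? I_inj[i] : 0.0));
      g_ad[i] *= tp_adk[ty];
      if (V[i] >= cell_vth[i]) {
        out_cell.push_back(i);
        out_time.push_back(t);
        V[i] = tp_Vre[ty];
        refr[i] = std::max(1, (int)std::lround(tp_tref[ty] / dt));
        g_ad[i] += tp_b[ty];
        fire(n_pp + i, t, s);
      }
    }

    // probe currents at the clamp potential (pA; IPSC positive at 0 mV)
    if (record_probe) {
      for (int q = 0; q < n_probe; ++q) {
        const int i = clamp_cells[q];
        double Ii = 0.0, Ie = 0.0;
        for (int c = 0; c < n_cls; ++c) {
          const double cur = g[(size_t)c * n_cells + i] * (clamp_v - cls_erev[c]);
          if (cls_erev[c] < clamp_v) Ii += cur; else Ie += cur;
        }
        probe_inh(s, q) = Ii;
        probe_exc(s, q) = -Ie;
      }
    }

    // conductance decay
    for (int c = 0; c < n_cls; ++c) {
      double* gc = &g[(size_t)c * n_cells];
      const double f = decay[c];
      for (int i = 0; i < n_cells; ++i) gc[i] *= f;
    }
  }

  return List::create(_["spike_cell"] = wrap(out_cell),
                      _["spike_time"] = wrap(out_time),
                      _["probe_ipsc"] = probe_inh,
                      _["probe_epsc"] = probe_exc,
                      _["n_steps"] = n_steps);
}

// Reference update rule for a single Tsodyks-Markram facilitating synapse:
// closed-form between-spike decay, used by tm_synapse_response(). Returns the
// per-spike conductance increments (nS).
// [[Rcpp::export]]
NumericVector tm_increments(NumericVector spike_times, double weight,
                            double tau_facil, double U) {
  const int n = spike_times.size();
  NumericVector inc(n);
  double u = 0.0, tlast = 0.0;
  bool first = true;
  for (int k = 0; k < n; ++k) {
    double factor = 1.0;
    if (tau_facil > 0.0) {
      if (!first) u *= std::exp(-(spike_times[k] - tlast) / tau_facil);
      u += U * (1.0 - u);
      tlast = spike_times[k];
      first = false;
      factor = u / U;
    }
    inc[k] = weight * factor;
  }
  return inc;
}
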