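// Clock-driven Euler-Maruyama integration of conductance-based LIF
// networks: the associative layer (with in-loop pair/triplet STDP and
// LTPi candidate collection) and the two-pool winner-take-all decision
// layer. Weights are in unitless W0 units; `g_unit` converts them to uS
// at spike delivery. There is no hard voltage reset by default: a
// spike-triggered refractory conductance repolarizes the cell, and the
// spike threshold is dynamic (jumps per spike, relaxes to base).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

// xoroshiro128+ with splitmix64 seeding; R's RNG is too slow for the
// tens of millions of draws per trial.
struct FastRng {
  uint64_t s0, s1;
  bool have_spare = false;
  double spare = 0.0;
  explicit FastRng(uint64_t seed) {
    for (int k = 0; k < 2; ++k) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      z = z ^ (z >> 31);
      if (k == 0) s0 = z; else s1 = z;
    }
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

inline double clamp_w(double w, double w0s, double cap, double wmax) {
  double lo = std::max(0.0, (1.0 - cap) * w0s);
  double hi = std::min(wmax, (1.0 + cap) * w0s);
  if (hi < lo) hi = lo;
  return std::min(std::max(w, lo), hi);
}

} // namespace

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(int n_e, int n_i,
                   NumericVector VL, NumericVector taum, NumericVector gL,
                   NumericVector Vthb, NumericVector Vres,
                   NumericVector tres,
                   LogicalMatrix m_in, NumericMatrix w_in_,
                   LogicalMatrix m_ee, NumericMatrix w_ee_,
                   LogicalMatrix m_ie, NumericMatrix w_ie_,
                   LogicalMatrix m_ii, NumericMatrix w_ii,
                   LogicalMatrix m_ei, NumericMatrix w_ei,
                   NumericVector in_t, IntegerVector in_g,
                   List kin, List noisecfg,
                   double dt, double relax_ms, double cue_ms,
                   int rule, List rulecfg, bool ltpi_on, List ltpicfg,
                   double w_max, double trial_cap,
                   IntegerVector record_v, double seed) {
  const int N = n_e + n_i;
  const int G = m_in.nrow();
  NumericMatrix w_inm = clone(w_in_), w_eem = clone(w_ee_),
                w_iem = clone(w_ie_);
  NumericMatrix w_in0 = clone(w_in_), w_ee0 = clone(w_ee_),
                w_ie0 = clone(w_ie_);

  const double E_ampa = kin["E_ampa"], tau_ampa = kin["tau_ampa"];
  const double E_nmda = kin["E_nmda"], tau_nmda = kin["tau_nmda"];
  const double E_gaba = kin["E_gaba"], tau_gaba = kin["tau_gaba"];
  const double mg = kin["mg"], mg_slope = kin["mg_slope"],
               mg_scale = kin["mg_scale"];
  const double dgref = as<double>(kin["delta_gref"]) *
                       as<double>(kin["gref_gain"]);
  const double V_gref = kin["V_gref"];
  const double Vth_max = kin["Vth_max"];
  const double th_inc = kin["th_increment"], th_tau = kin["th_tau"];
  const double g_unit = kin["g_unit"];
  const double nmda_frac = kin["nmda_frac"];
  const bool hard_reset = as<bool>(kin["hard_reset"]);

  const double sigma_v = noisecfg["sigma_v"];
  const double g_noise = noisecfg["g_noise"];

  const double T = relax_ms + cue_ms;
  const int n_steps = (int)std::lround(T / dt);
  const double sqrtdt = std::sqrt(dt);
  const double dA = std::exp(-dt / tau_ampa);
  const double dN = std::exp(-dt / tau_nmda);
  const double dG = std::exp(-dt / tau_gaba);
  const double dTh = std::exp(-dt / th_tau);
  std::vector<double> dRef(N);
  for (int i = 0; i < N; ++i) dRef[i] = std::exp(-dt / tres[i]);

  // pair/triplet STDP trace parameters
  double p_aplus = 0, p_aminus = 0, p_dw = 0;
  double d_pre_f = 1, d_pre_s = 1, d_post_f = 1, d_post_s = 1;
  double a2p = 0, a2m = 0, a3p = 0, a3m = 0;
  if (rule == 1) {
    p_aplus = as<double>(rulecfg["a_plus"]);
    p_aminus = as<double>(rulecfg["a_minus"]);
    p_dw = as<double>(rulecfg["dw"]);
    d_pre_f = std::exp(-dt / as<double>(rulecfg["tau_plus"]));
    d_post_f = std::exp(-dt / as<double>(rulecfg["tau_minus"]));
  } else if (rule == 2) {
    a2p = as<double>(rulecfg["a2_plus"]);
    a2m = as<double>(rulecfg["a2_minus"]);
    a3p = as<double>(rulecfg["a3_plus"]);
    a3m = as<double>(rulecfg["a3_minus"]);
    p_dw = as<double>(rulecfg["dw"]);
    d_pre_f = std::exp(-dt / as<double>(rulecfg["tau2_plus"]));
    d_pre_s = std::exp(-dt / as<double>(rulecfg["tau_x"]));
    d_post_f = std::exp(-dt / as<double>(rulecfg["tau2_minus"]));
    d_post_s = std::exp(-dt / as<double>(rulecfg["tau_y"]));
  }
  const bool plastic = (rule > 0);

  double ltpi_idw = 0, ltpi_veto = 20, ltpi_vthr = -65, ltpi_wmax = w_max;
  if (ltpi_on) {
    ltpi_idw = as<double>(ltpicfg["idw"]);
    ltpi_veto = as<double>(ltpicfg["veto_ms"]);
    ltpi_vthr = as<double>(ltpicfg["v_threshold"]);
    ltpi_wmax = std::min(as<double>(ltpicfg["w_max"]), w_max);
  }

  // state
  std::vector<double> V(VL.begin(), VL.end());
  std::vector<double> gA(N, 0.0), gN(N, 0.0), gGa(N, 0.0), gRef(N, 0.0);
  std::vector<double> Vthd(Vthb.begin(), Vthb.end());
  // STDP traces: presynaptic for E cells and input groups, postsynaptic
  // for E cells (fast = pairing window, slow = triplet booster)
  std::vector<double> preE_f(n_e, 0.0), preE_s(n_e, 0.0);
  std::vector<double> preG_f(G, 0.0), preG_s(G, 0.0);
  std::vector<double> post_f(n_e, 0.0), post_s(n_e, 0.0);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector< std::vector<double> > e_spikes(n_e);
  std::vector<int> cue_count(N, 0);
  std::vector<int> lt_i, lt_j;
  std::vector<double> lt_t;

  const int n_rec = record_v.size();
  NumericMatrix v_rec(n_rec > 0 ? n_steps : 0, n_rec);

  FastRng rng((uint64_t)std::llround(seed));

  int in_ptr = 0;
  const int n_in = in_t.size();
  std::vector<int> spiked; spiked.reserve(64);
  std::vector<int> groups_this; groups_this.reserve(16);

  for (int step = 0; step < n_steps; ++step) {
    const double t = (step + 1) * dt;
    const bool in_cue = t > relax_ms;

    // conductance, threshold and trace decay
    for (int i = 0; i < N; ++i) {
      gA[i] *= dA; gN[i] *= dN; gGa[i] *= dG; gRef[i] *= dRef[i];
      Vthd[i] = Vthb[i] + (Vthd[i] - Vthb[i]) * dTh;
    }
    if (plastic) {
      for (int i = 0; i < n_e; ++i) {
        preE_f[i] *= d_pre_f; preE_s[i] *= d_pre_s;
        post_f[i] *= d_post_f; post_s[i] *= d_post_s;
      }
      for (int g = 0; g < G; ++g) { preG_f[g] *= d_pre_f; preG_s[g] *= d_pre_s; }
    }

    // deliver external input spikes due at this step
    groups_this.clear();
    while (in_ptr < n_in && in_t[in_ptr] + relax_ms <= t) {
      const int g = in_g[in_ptr];
      for (int j = 0; j < N; ++j) {
        if (m_in(g, j)) {
          const double w = w_inm(g, j) * g_unit;
          gA[j] += w; gN[j] += w * nmda_frac;
          if (plastic && in_cue && j < n_e) {
            // input spike as presynaptic event: depression
            double dw;
            if (rule == 1) dw = -p_dw * p_aminus * post_f[j];
            else dw = -p_dw * post_f[j] * (a2m + a3m * preG_s[g]);
            w_inm(g, j) = clamp_w(w_inm(g, j) + dw, w_in0(g, j),
                                  trial_cap, w_max);
          }
        }
      }
      if (plastic && in_cue) groups_this.push_back(g);
      ++in_ptr;
    }
    // input-group trace increments (after all updates of this step)
    for (size_t k = 0; k < groups_this.size(); ++k) {
      preG_f[groups_this[k]] += 1.0; preG_s[groups_this[k]] += 1.0;
    }

    // integrate membrane voltages
    for (int i = 0; i < N; ++i) {
      const double gA_eff = gA[i] + g_noise * rng.unif();
      const double gG_eff = gGa[i] + g_noise * rng.unif();
      const double s_nmda =
        1.0 / (1.0 + mg * std::exp(-mg_slope * V[i]) / mg_scale);
      const double I =
        gL[i] * (VL[i] - V[i]) + gA_eff * (E_ampa - V[i]) +
        gN[i] * s_nmda * (E_nmda - V[i]) + gG_eff * (E_gaba - V[i]) +
        gRef[i] * (V_gref - V[i]);
      V[i] += dt * I / (gL[i] * taum[i]);
      if (sigma_v > 0) V[i] += sigma_v * sqrtdt * rng.norm();
      if (!std::isfinite(V[i]))
        stop("integration fault: non-finite voltage (neuron %d, t = %.2f ms)",
             i + 1, t);
    }
    for (int k = 0; k < n_rec; ++k) v_rec(step, k) = V[record_v[k] - 1];

    // threshold crossings
    spiked.clear();
    for (int i = 0; i < N; ++i) {
      if (V[i] >= Vthd[i]) {
        spiked.push_back(i);
        spike_id.push_back(i + 1);
        spike_t.push_back(t);
        gRef[i] += dgref;
        Vthd[i] = std::min(Vthd[i] + th_inc, Vth_max);
        if (hard_reset) V[i] = Vres[i];
        if (in_cue) ++cue_count[i];
        if (i < n_e) e_spikes[i].push_back(t);
      }
    }

    // propagate recurrent spikes; STDP/LTPi bookkeeping
    for (size_t k = 0; k < spiked.size(); ++k) {
      const int i = spiked[k];
      if (i < n_e) {
        if (plastic && in_cue) {
          // as postsynaptic: potentiation from E->E and input->E
          for (int p = 0; p < n_e; ++p) {
            if (m_ee(p, i)) {
              double dw;
              if (rule == 1) dw = p_dw * p_aplus * preE_f[p];
              else dw = p_dw * preE_f[p] * (a2p + a3p * post_s[i]);
              w_eem(p, i) = clamp_w(w_eem(p, i) + dw, w_ee0(p, i),
                                    trial_cap, w_max);
            }
          }
          for (int g = 0; g < G; ++g) {
            if (m_in(g, i)) {
              double dw;
              if (rule == 1) dw = p_dw * p_aplus * preG_f[g];
              else dw = p_dw * preG_f[g] * (a2p + a3p * post_s[i]);
              w_inm(g, i) = clamp_w(w_inm(g, i) + dw, w_in0(g, i),
                                    trial_cap, w_max);
            }
          }
          // as presynaptic: depression of E->E onto its targets
          for (int j = 0; j < n_e; ++j) {
            if (m_ee(i, j)) {
              double dw;
              if (rule == 1) dw = -p_dw * p_aminus * post_f[j];
              else dw = -p_dw * post_f[j] * (a2m + a3m * preE_s[i]);
              w_eem(i, j) = clamp_w(w_eem(i, j) + dw, w_ee0(i, j),
                                    trial_cap, w_max);
            }
          }
        }
        // conductance jumps: E -> E (and E -> I if recurrent inhibition)
        for (int j = 0; j < n_e; ++j) {
          if (m_ee(i, j)) {
            const double w = w_eem(i, j) * g_unit;
            gA[j] += w; gN[j] += w * nmda_frac;
          }
        }
        if (n_i > 0) {
          for (int j = 0; j < n_i; ++j) {
            if (m_ei(i, j)) {
              const double w = w_ei(i, j) * g_unit;
              gA[n_e + j] += w; gN[n_e + j] += w * nmda_frac;
            }
          }
        }
      } else {
        const int ii = i - n_e;
        for (int j = 0; j < n_e; ++j) {
          if (m_ie(ii, j)) {
            gGa[j] += w_iem(ii, j) * g_unit;
            if (ltpi_on && in_cue && V[j] > ltpi_vthr) {
              lt_i.push_back(ii); lt_j.push_back(j); lt_t.push_back(t);
            }
          }
        }
        for (int j = 0; j < n_i; ++j)
          if (m_ii(ii, j)) gGa[n_e + j] += w_ii(ii, j) * g_unit;
      }
    }
    // trace increments for this step's spikes (after all updates, so
    // simultaneous pre/post spikes contribute nothing to each other)
    if (plastic) {
      for (size_t k = 0; k < spiked.size(); ++k) {
        const int i = spiked[k];
        if (i < n_e) {
          preE_f[i] += 1.0; preE_s[i] += 1.0;
          post_f[i] += 1.0; post_s[i] += 1.0;
        }
      }
    }
  }

  // resolve LTPi candidates: veto if any postsynaptic excitatory spike
  // falls within +/- veto_ms of the inhibitory spike
  int ltpi_applied = 0;
  if (ltpi_on) {
    for (size_t k = 0; k < lt_t.size(); ++k) {
      const std::vector<double>& sp = e_spikes[lt_j[k]];
      const double t0 = lt_t[k];
      bool veto = false;
      std::vector<double>::const_iterator it =
        std::lower_bound(sp.begin(), sp.end(), t0 - ltpi_veto);
      if (it != sp.end() && *it <= t0 + ltpi_veto) veto = true;
      if (!veto) {
        w_iem(lt_i[k], lt_j[k]) =
          clamp_w(w_iem(lt_i[k], lt_j[k]) + ltpi_idw,
                  w_ie0(lt_i[k], lt_j[k]), trial_cap, ltpi_wmax);
        ++ltpi_applied;
      }
    }
  }

  NumericVector rates(N);
  for (int i = 0; i < N; ++i) rates[i] = cue_count[i] * 1000.0 / cue_ms;

  return List::create(
    _["spike_id"] = wrap(spike_id), _["spike_t"] = wrap(spike_t),
    _["rates"] = rates,
    _["w_in"] = w_inm, _["w_ee"] = w_eem, _["w_ie"] = w_iem,
    _["ltpi_candidates"] = (int)lt_t.size(),
    _["ltpi_applied"] = ltpi_applied,
    _["v_rec"] = v_rec);
}

// [[Rcpp::export(name = ".sim_decision_cpp")]]
List sim_decision_cpp(int n_e, int n_i,
                      NumericVector VL, NumericVector taum,
                      NumericVector gL, NumericVector Vthb,
                      NumericVector Vres, NumericVector tres,
                      LogicalMatrix mask, NumericMatrix w,
                      NumericMatrix afferents,
                      NumericVector aff_t, IntegerVector aff_id,
                      List kin, double g_noise,
                      double g_urgency, double urg_gain,
                      double dt, double relax_ms, double cue_ms,
                      double readout_ms, double seed) {
  const int N = n_e + n_i;
  const int n_aff = afferents.nrow();

  const double E_ampa = kin["E_ampa"], tau_ampa = kin["tau_ampa"];
  const double E_nmda = kin["E_nmda"], tau_nmda = kin["tau_nmda"];
  const double E_gaba = kin["E_gaba"], tau_gaba = kin["tau_gaba"];
  const double mg = kin["mg"], mg_slope = kin["mg_slope"],
               mg_scale = kin["mg_scale"];
  const double dgref = as<double>(kin["delta_gref"]) *
                       as<double>(kin["gref_gain"]);
  const double V_gref = kin["V_gref"];
  const double Vth_max = kin["Vth_max"];
  const double th_inc = kin["th_increment"], th_tau = kin["th_tau"];
  const double g_unit = kin["g_unit"];
  const double nmda_frac = kin["nmda_frac"];
  const bool hard_reset = as<bool>(kin["hard_reset"]);

  const double T = relax_ms + cue_ms;
  const int n_steps = (int)std::lround(T / dt);
  const double dA = std::exp(-dt / tau_ampa);
  const double dN = std::exp(-dt / tau_nmda);
  const double dG = std::exp(-dt / tau_gaba);
  const double dTh = std::exp(-dt / th_tau);
  std::vector<double> dRef(N);
  for (int i = 0; i < N; ++i) dRef[i] = std::exp(-dt / tres[i]);

  std::vector<double> V(VL.begin(), VL.end());
  std::vector<double> gA(N, 0.0), gN(N, 0.0), gGa(N, 0.0), gRef(N, 0.0);
  std::vector<double> Vthd(Vthb.begin(), Vthb.end());
  std::vector<int> cue_count(N, 0), readout_count(N, 0);
  std::vector<int> spike_id;
  std::vector<double> spike_t;

  FastRng rng((uint64_t)std::llround(seed));

  int aff_ptr = 0;
  const int n_in = aff_t.size();
  const double readout_start = T - readout_ms;
  std::vector<int> spiked; spiked.reserve(64);

  for (int step = 0; step < n_steps; ++step) {
    const double t = (step + 1) * dt;
    const bool in_cue = t > relax_ms;
    const double gu = in_cue
      ? g_urgency * urg_gain * (t - relax_ms) / cue_ms : 0.0;

    for (int i = 0; i < N; ++i) {
      gA[i] *= dA; gN[i] *= dN; gGa[i] *= dG; gRef[i] *= dRef[i];
      Vthd[i] = Vthb[i] + (Vthd[i] - Vthb[i]) * dTh;
    }

    // afferent spikes from the associative layer (times already on the
    // decision trial clock)
    while (aff_ptr < n_in && aff_t[aff_ptr] <= t) {
      const int a = aff_id[aff_ptr] - 1;
      if (a >= 0 && a < n_aff) {
        for (int j = 0; j < n_e; ++j) {
          const double ww = afferents(a, j) * g_unit;
          gA[j] += ww; gN[j] += ww * nmda_frac;
        }
      }
      ++aff_ptr;
    }

    for (int i = 0; i < N; ++i) {
      const double g_urg_i = (i < n_e) ? gu : 0.0;
      const double gA_eff = gA[i] + g_noise * rng.unif() + g_urg_i;
      const double gG_eff = gGa[i] + g_noise * rng.unif();
      const double s_nmda =
        1.0 / (1.0 + mg * std::exp(-mg_slope * V[i]) / mg_scale);
      const double I =
        gL[i] * (VL[i] - V[i]) + gA_eff * (E_ampa - V[i]) +
        gN[i] * s_nmda * (E_nmda - V[i]) + gG_eff * (E_gaba - V[i]) +
        gRef[i] * (V_gref - V[i]);
      V[i] += dt * I / (gL[i] * taum[i]);
      if (!std::isfinite(V[i]))
        stop("integration fault: non-finite voltage (decision neuron %d)",
             i + 1);
    }

    spiked.clear();
    for (int i = 0; i < N; ++i) {
      if (V[i] >= Vthd[i]) {
        spiked.push_back(i);
        spike_id.push_back(i + 1);
        spike_t.push_back(t);
        gRef[i] += dgref;
        Vthd[i] = std::min(Vthd[i] + th_inc, Vth_max);
        if (hard_reset) V[i] = Vres[i];
        if (in_cue) ++cue_count[i];
        if (t >= readout_start) ++readout_count[i];
      }
    }
    for (size_t k = 0; k < spiked.size(); ++k) {
      const int i = spiked[k];
      if (i < n_e) {
        for (int j = 0; j < N; ++j) {
          if (mask(i, j)) {
            const double ww = w(i, j) * g_unit;
            gA[j] += ww; gN[j] += ww * nmda_frac;
          }
        }
      } else {
        for (int j = 0; j < N; ++j)
          if (mask(i, j)) gGa[j] += w(i, j) * g_unit;
      }
    }
  }

  NumericVector rates(N), readout_rates(N);
  for (int i = 0; i < N; ++i) {
    rates[i] = cue_count[i] * 1000.0 / cue_ms;
    readout_rates[i] = readout_count[i] * 1000.0 / readout_ms;
  }
  return List::create(
    _["spike_id"] = wrap(spike_id), _["spike_t"] = wrap(spike_t),
    _["rates"] = rates, _["readout_rates"] = readout_rates);
}
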