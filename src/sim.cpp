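// Reduced multi-compartment Hodgkin-Huxley cable simulator.
//
// Units: mV, ms, nA, uS, nF, mM. With these, uS*mV = nA and nF*mV/ms = nA,
// so the per-segment current balance is assembled directly in nA.
//
// Integration: backward Euler on the compartment tree (Hines elimination,
// segments ordered root-first so parent[i] < i), with gate states advanced
// by exact exponential relaxation toward their steady state evaluated at
// the previous-step voltage (staggered scheme). This keeps stiff HH systems
// stable at dt = 0.025 ms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Gate {
  int expo;
  bool ca_dep;
  double vhalf, slope;                      // sigmoid steady state (mV)
  double tau_base, tau_amp, tau_center, tau_width; // gaussian tau(V) (ms)
  double ca_half, hill, tau_ca;             // calcium-gated variant
  std::vector<double> state;                // one per local segment
  // voltage-grid tables of inf(V) and exp(-dt/tau(V)) for the hot loop
  std::vector<double> tab_inf, tab_dec;
};

constexpr double TAB_VMIN = -150.0, TAB_VMAX = 80.0, TAB_DV = 0.05;
constexpr int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_DV) + 1;

inline double tab_lookup(const std::vector<double>& tab, double v) {
  double x = (v - TAB_VMIN) / TAB_DV;
  if (x <= 0) return tab.front();
  if (x >= TAB_N - 1) return tab.back();
  int i = (int)x;
  double f = x - i;
  return tab[i] * (1 - f) + tab[i + 1] * f;
}

inline double ipow(double x, int n) {
  double r = 1.0;
  while (n-- > 0) r *= x;
  return r;
}

struct Mech {
  std::string name;
  std::vector<int> segs;       // global segment indices (0-based)
  std::vector<double> gbar;    // absolute max conductance per seg (uS)
  std::vector<double> geff;    // effective conductance this step (uS)
  double erev;
  bool nernst;                 // reversal from Nernst on local [Ca]
  bool is_ca;                  // current counts as Ca influx
  double gamma;                // single-channel conductance (uS); 0 = n/a
  std::vector<Gate> gates;
};

struct Stim {
  int seg, kind;               // 0 step, 1 ramp, 2 holding
  double amp, onset, offset;
};

struct Syn {
  int seg;
  double gmax, tau_r, tau_d, onset, erev, nmda_frac, mg, norm;
};

inline double gate_inf(const Gate& g, double v, double ca) {
  if (g.ca_dep) {
    double num = std::pow(ca, g.hill);
    return num / (num + std::pow(g.ca_half, g.hill));
  }
  return 1.0 / (1.0 + std::exp((g.vhalf - v) / g.slope));
}

inline void build_tables(Gate& g, double dt) {
  if (g.ca_dep) return;
  g.tab_inf.resize(TAB_N);
  g.tab_dec.resize(TAB_N);
  for (int i = 0; i < TAB_N; ++i) {
    double v = TAB_VMIN + i * TAB_DV;
    g.tab_inf[i] = 1.0 / (1.0 + std::exp((g.vhalf - v) / g.slope));
    double z = (v - g.tau_center) / g.tau_width;
    double tau = g.tau_base + g.tau_amp * std::exp(-z * z);
    g.tab_dec[i] = std::exp(-dt / tau);
  }
}

inline double gate_tau(const Gate& g, double v) {
  if (g.ca_dep) return g.tau_ca;
  double z = (v - g.tau_center) / g.tau_width;
  return g.tau_base + g.tau_amp * std::exp(-z * z);
}

inline double stim_current(const Stim& s, double t) {
  if (s.kind == 2) return s.amp;  // holding: on for the whole run
  if (t < s.onset || t > s.offset) return 0.0;
  if (s.kind == 1) {              // ramp 0 -> amp over the window
    double w = s.offset - s.onset;
    return w > 0 ? s.amp * (t - s.onset) / w : s.amp;
  }
  return s.amp;                   // step
}

inline double eca_nernst(double ca) {
  // RT/2F at 34 C, mV; extracellular [Ca] fixed at 2 mM
  return 13.2318 * std::log(2.0 / std::max(ca, 1e-9));
}

} // namespace

// [[Rcpp::export(name = ".sim_run")]]
List sim_run(List sys, List mech_list, Nullable<List> ca_dyn_, List stim_list,
             List syn_list, List rec_list, double dt, double duration,
             int rec_every, double v_init, bool stoch_mode, double ca0,
             double stop_v_above, double stop_t_min, double stop_t_max) {
  IntegerVector parent = sys["parent"];
  NumericVector cap = sys["cap_nF"];
  NumericVector gax = sys["g_axial_uS"];
  const int n = parent.size();

  // mechanisms
  std::vector<Mech> mechs;
  for (int i = 0; i < mech_list.size(); ++i) {
    List ml = mech_list[i];
    Mech m;
    m.name = as<std::string>(ml["name"]);
    m.segs = as<std::vector<int> >(ml["segs"]);
    m.gbar = as<std::vector<double> >(ml["gbar_uS"]);
    m.geff.assign(m.segs.size(), 0.0);
    m.erev = as<double>(ml["erev"]);
    m.nernst = as<bool>(ml["nernst"]);
    m.is_ca = as<bool>(ml["is_ca"]);
    m.gamma = as<double>(ml["gamma_uS"]);
    List gl = ml["gates"];
    for (int gi = 0; gi < gl.size(); ++gi) {
      List gg = gl[gi];
      Gate g;
      g.expo = as<int>(gg["exponent"]);
      g.ca_dep = as<bool>(gg["ca_dep"]);
      g.vhalf = as<double>(gg["vhalf"]);
      g.slope = as<double>(gg["slope"]);
      g.tau_base = as<double>(gg["tau_base"]);
      g.tau_amp = as<double>(gg["tau_amp"]);
      g.tau_center = as<double>(gg["tau_center"]);
      g.tau_width = as<double>(gg["tau_width"]);
      g.ca_half = as<double>(gg["ca_half"]);
      g.hill = as<double>(gg["hill"]);
      g.tau_ca = as<double>(gg["tau_ca"]);
      g.state.assign(m.segs.size(), 0.0);
      build_tables(g, dt);
      m.gates.push_back(g);
    }
    mechs.push_back(m);
  }
  const int nmech = (int)mechs.size();

  // calcium dynamics (optional)
  std::vector<int> ca_segs;
  std::vector<double> ca_tau, ca_vol, ca_min;
  if (ca_dyn_.isNotNull()) {
    List cd(ca_dyn_);
    ca_segs = as<std::vector<int> >(cd["segs"]);
    ca_tau = as<std::vector<double> >(cd["tau"]);
    ca_vol = as<std::vector<double> >(cd["vol_um3"]);
    ca_min = as<std::vector<double> >(cd["ca_min"]);
  }

  std::vector<Stim> stims;
  for (int i = 0; i < stim_list.size(); ++i) {
    List sl = stim_list[i];
    Stim s;
    s.seg = as<int>(sl["seg"]); s.kind = as<int>(sl["kind"]);
    s.amp = as<double>(sl["amp"]); s.onset = as<double>(sl["onset"]);
    s.offset = as<double>(sl["offset"]);
    stims.push_back(s);
  }

  std::vector<Syn> syns;
  for (int i = 0; i < syn_list.size(); ++i) {
    List sl = syn_list[i];
    Syn s;
    s.seg = as<int>(sl["seg"]); s.gmax = as<double>(sl["gmax_uS"]);
    s.tau_r = as<double>(sl["tau_rise"]); s.tau_d = as<double>(sl["tau_decay"]);
    s.onset = as<double>(sl["onset"]); s.erev = as<double>(sl["erev"]);
    s.nmda_frac = as<double>(sl["nmda_frac"]); s.mg = as<double>(sl["mg"]);
    double tp = (s.tau_d * s.tau_r / (s.tau_d - s.tau_r)) * std::log(s.tau_d / s.tau_r);
    s.norm = 1.0 / (std::exp(-tp / s.tau_d) - std::exp(-tp / s.tau_r));
    syns.push_back(s);
  }

  // state
  std::vector<double> V(n, v_init), Vold(n, v_init), ca(n, ca0);
  for (auto& m : mechs)
    for (auto& g : m.gates)
      for (size_t k = 0; k < m.segs.size(); ++k)
        g.state[k] = gate_inf(g, v_init, ca0);

  const int nstep = (int)std::lround(duration / dt);
  const int nrec = nstep / rec_every + 1;
  NumericVector times(nrec);

  // recordings
  const int nrq = rec_list.size();
  std::vector<int> rq_seg(nrq), rq_kind(nrq);
  std::vector<NumericVector> rq_vec;
  std::vector<NumericMatrix> rq_mat;
  std::vector<int> rq_slot(nrq);
  for (int i = 0; i < nrq; ++i) {
    List rl = rec_list[i];
    rq_seg[i] = as<int>(rl["seg"]);
    rq_kind[i] = as<int>(rl["kind"]);
    if (rq_kind[i] == 2) {
      rq_slot[i] = (int)rq_mat.size();
      rq_mat.push_back(NumericMatrix(nrec, nmech + 1)); // + synapse column
    } else {
      rq_slot[i] = (int)rq_vec.size();
      rq_vec.push_back(NumericVector(nrec));
    }
  }

  std::vector<double> diag(n), rhs(n), gsum(n), gesum(n), iinj(n);
  std::vector<double> ica_abs(n); // Ca-carrying current (nA), for dynamics
  bool diverged = false;

  // helper lambda to record a sample at row r, time t, with ionic currents
  // computed at the current V / geff
  auto record = [&](int r, double t) {
    times[r] = t / 1.0;
    for (int i = 0; i < nrq; ++i) {
      int sgi = rq_seg[i], kind = rq_kind[i];
      if (kind == 0) rq_vec[rq_slot[i]][r] = V[sgi];
      else if (kind == 1) rq_vec[rq_slot[i]][r] = ca[sgi];
      else if (kind == 2) {
        NumericMatrix& M = rq_mat[rq_slot[i]];
        for (int mi = 0; mi < nmech; ++mi) {
          double cur = 0.0;
          const Mech& m = mechs[mi];
          for (size_t k = 0; k < m.segs.size(); ++k)
            if (m.segs[k] == sgi) {
              double e = m.nernst ? eca_nernst(ca[sgi]) : m.erev;
              cur = m.geff[k] * (V[sgi] - e);
            }
          M(r, mi) = cur;
        }
        double scur = 0.0;
        for (auto& s : syns)
          if (s.seg == sgi) {
            double g = 0.0;
            if (t >= s.onset) {
              double u = t - s.onset;
              g = s.gmax * s.norm * (std::exp(-u / s.tau_d) - std::exp(-u / s.tau_r));
              double block = 1.0 / (1.0 + std::exp(-0.062 * V[sgi]) * s.mg / 3.57);
              g *= (1.0 - s.nmda_frac) + s.nmda_frac * block;
            }
            scur += g * (V[sgi] - s.erev);
          }
        M(r, nmech) = scur;
      } else if (kind == 3) { // capacitive
        rq_vec[rq_slot[i]][r] = (t == 0.0) ? 0.0
          : cap[sgi] * (V[sgi] - Vold[sgi]) / dt;
      } else if (kind == 4) { // net axial (out of segment)
        double a = 0.0;
        if (parent[sgi] >= 0) a += gax[sgi] * (V[sgi] - V[parent[sgi]]);
        for (int j = 0; j < n; ++j)
          if (parent[j] == sgi) a += gax[j] * (V[sgi] - V[j]);
        rq_vec[rq_slot[i]][r] = a;
      } else if (kind == 5) { // injected
        rq_vec[rq_slot[i]][r] = iinj[sgi];
      }
    }
  };

  // initial geff/iinj for the t=0 sample
  for (auto& m : mechs)
    for (size_t k = 0; k < m.segs.size(); ++k) {
      double p = 1.0;
      for (auto& g : m.gates) p *= ipow(g.state[k], g.expo);
      m.geff[k] = m.gbar[k] * p;
    }
  std::fill(iinj.begin(), iinj.end(), 0.0);
  for (auto& s : stims) iinj[s.seg] += stim_current(s, 0.0);
  record(0, 0.0);

  int rrow = 1;
  for (int step = 1; step <= nstep; ++step) {
    const double t = step * dt;
    std::copy(V.begin(), V.end(), Vold.begin());

    // 1. advance gates with V(t-dt), ca(t-dt); accumulate conductances
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    std::fill(ica_abs.begin(), ica_abs.end(), 0.0);
    for (auto& m : mechs) {
      const bool stoch = stoch_mode && m.gamma > 0;
      for (size_t k = 0; k < m.segs.size(); ++k) {
        const int sg = m.segs[k];
        double p = 1.0;
        for (auto& g : m.gates) {
          double inf, dec;
          if (g.ca_dep) {
            inf = gate_inf(g, Vold[sg], ca[sg]);
            dec = std::exp(-dt / g.tau_ca);
          } else {
            inf = tab_lookup(g.tab_inf, Vold[sg]);
            dec = tab_lookup(g.tab_dec, Vold[sg]);
          }
          g.state[k] = inf + (g.state[k] - inf) * dec;
          p *= ipow(g.state[k], g.expo);
        }
        double geff;
        if (stoch) {
          double nch = std::max(0.0, std::round(m.gbar[k] / m.gamma));
          double open = ::Rf_rbinom(nch, std::min(1.0, std::max(0.0, p)));
          geff = open * m.gamma;
        } else {
          geff = m.gbar[k] * p;
        }
        m.geff[k] = geff;
        double e = m.nernst ? eca_nernst(ca[sg]) : m.erev;
        gsum[sg] += geff;
        gesum[sg] += geff * e;
      }
    }

    // 2. synapses (conductance at t, Mg block at V(t-dt))
    for (auto& s : syns) {
      if (t < s.onset) continue;
      double u = t - s.onset;
      double g = s.gmax * s.norm * (std::exp(-u / s.tau_d) - std::exp(-u / s.tau_r));
      double block = 1.0 / (1.0 + std::exp(-0.062 * Vold[s.seg]) * s.mg / 3.57);
      g *= (1.0 - s.nmda_frac) + s.nmda_frac * block;
      gsum[s.seg] += g;
      gesum[s.seg] += g * s.erev;
    }

    // 3. injected currents at t
    std::fill(iinj.begin(), iinj.end(), 0.0);
    for (auto& s : stims) iinj[s.seg] += stim_current(s, t);

    // 4. assemble and solve the tree system (Hines)
    for (int j = 0; j < n; ++j) {
      diag[j] = cap[j] / dt + gsum[j];
      rhs[j] = cap[j] / dt * Vold[j] + gesum[j] + iinj[j];
      if (parent[j] >= 0) diag[j] += gax[j];
    }
    for (int j = 0; j < n; ++j)
      if (parent[j] >= 0) diag[parent[j]] += gax[j];
    for (int j = n - 1; j >= 1; --j) {
      const int p = parent[j];
      const double f = gax[j] / diag[j];
      diag[p] -= gax[j] * f;
      rhs[p] += rhs[j] * f;
    }
    V[0] = rhs[0] / diag[0];
    for (int j = 1; j < n; ++j)
      V[j] = (rhs[j] + gax[j] * V[parent[j]]) / diag[j];

    for (int j = 0; j < n; ++j)
      if (!std::isfinite(V[j]) || std::fabs(V[j]) > 1000.0) diverged = true;
    if (diverged) break;
    if (R_finite(stop_v_above) && V[0] > stop_v_above &&
        t >= stop_t_min && t <= stop_t_max) {
      // spike-predicate early exit (threshold search): record and stop
      if (step % rec_every == 0) { record(rrow, t); ++rrow; }
      return List::create(_["times"] = times, _["traces"] = List(0),
                          _["diverged"] = false, _["stopped_spike"] = true,
                          _["mech_names"] = CharacterVector(0));
    }

    // 5. calcium dynamics (implicit decay, influx from Ca currents at new V)
    if (!ca_segs.empty()) {
      for (auto& m : mechs)
        if (m.is_ca)
          for (size_t k = 0; k < m.segs.size(); ++k) {
            const int sg = m.segs[k];
            double e = m.nernst ? eca_nernst(ca[sg]) : m.erev;
            ica_abs[sg] += m.geff[k] * (V[sg] - e);
          }
      for (size_t ci = 0; ci < ca_segs.size(); ++ci) {
        const int sg = ca_segs[ci];
        // nA -> mM/ms in a shell of vol um^3: I/(2F vol) with unit juggling
        double influx = -ica_abs[sg] * 5.1822 / ca_vol[ci];
        double c = (ca[sg] + dt * (influx + ca_min[ci] / ca_tau[ci])) /
                   (1.0 + dt / ca_tau[ci]);
        ca[sg] = std::max(c, ca_min[ci]);
      }
    }

    if (step % rec_every == 0) { record(rrow, t); ++rrow; }
  }

  if (diverged)
    for (int r = rrow; r < nrec; ++r) {
      times[r] = NA_REAL;
      for (auto& v : rq_vec) if (r < v.size()) v[r] = NA_REAL;
    }

  List traces(nrq);
  for (int i = 0; i < nrq; ++i)
    traces[i] = (rq_kind[i] == 2) ? (SEXP)rq_mat[rq_slot[i]] : (SEXP)rq_vec[rq_slot[i]];

  CharacterVector mech_names(nmech + 1);
  for (int i = 0; i < nmech; ++i) mech_names[i] = mechs[i].name;
  mech_names[nmech] = "synapse";

  return List::create(_["times"] = times, _["traces"] = traces,
                      _["diverged"] = diverged, _["stopped_spike"] = false,
                      _["mech_names"] = mech_names);
}
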