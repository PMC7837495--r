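// Compartmental simulation core: implicit (backward Euler) integration of the
// cable equation on a Hines-ordered tree, interleaved with exponential-
// integrator HH gate updates, implicit Markov channel updates, submembrane
// calcium shells and event-driven dynamic synapses. Voltage-dependent gate
// and rate functions are tabulated on a fine voltage grid at run start.
//
// Units: V mV, t ms, conductance uS, capacitance nF, current nA, area cm^2,
// concentration mM. I = g * (V - E) with outward positive.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline double clamped_exp(double x) {
  if (x > 20.0) x = 20.0;
  if (x < -20.0) x = -20.0;
  return std::exp(x);
}

// voltage grid for tabulated rates
static const double V_MIN = -150.0, V_MAX = 100.0, V_STEP = 0.05;
static const int V_N = (int)((V_MAX - V_MIN) / V_STEP) + 2;

static inline int v_index(double v, double &frac) {
  double x = (v - V_MIN) / V_STEP;
  if (x < 0) x = 0;
  if (x > V_N - 2) x = V_N - 2;
  int i = (int)x;
  frac = x - i;
  return i;
}

static inline double tab_at(const std::vector<double> &tab, int base, int i,
                            double frac) {
  const double *p = &tab[(size_t)base * V_N + i];
  return p[0] + frac * (p[1] - p[0]);
}

static inline double int_ca_pow(double ca, double p) {
  if (p == 0.0) return 1.0;
  if (p == 1.0) return ca;
  if (p == 2.0) return ca * ca;
  return std::pow(ca, p);
}

// ---------------------------------------------------------------------------
// HH gate parameterization (must match R/channels.R)

struct GateDef {
  int kind;      // 0 voltage, 1 calcium
  int exponent;
  double vhalf, k, tau_min, tau_amp, tau_vhalf, tau_ka, tau_kb; // voltage
  double n, kd, tau;                                            // calcium
};

static inline double gate_inf_c(const GateDef &g, double v, double ca) {
  if (g.kind == 1) {
    double can = std::pow(ca, g.n);
    return can / (can + std::pow(g.kd, g.n));
  }
  return 1.0 / (1.0 + clamped_exp(-(v - g.vhalf) / g.k));
}

static inline double gate_tau_c(const GateDef &g, double v, double ca) {
  if (g.kind == 1) return g.tau;
  return g.tau_min + g.tau_amp /
    (clamped_exp((v - g.tau_vhalf) / g.tau_ka) +
     clamped_exp(-(v - g.tau_vhalf) / g.tau_kb));
}

// ---------------------------------------------------------------------------
// Markov transition table

struct Transition {
  int from, to;
  double base, vhalf, kv, ca_pow;
};

struct ChannelInstance {
  int kind;                  // 0 HH, 1 Markov
  std::vector<int> comps;    // compartment indices (0-based)
  std::vector<double> gbar;  // uS per listed compartment
  double erev;
  bool is_ca;
  double tf;                 // Q10 temperature factor on rates
  // HH
  std::vector<GateDef> gates;
  std::vector<double> gstate; // [comp][gate], row-major ncomp x ngates
  // Markov
  int n_states;
  std::vector<int> open_states;
  std::vector<Transition> trans;
  std::vector<double> mstate; // [comp][state]
  // tabulated functions of voltage (built once dt is known):
  // HH: per gate, minf and exp(-dt*tf/tau); Markov: per transition, rate*tf
  std::vector<double> tab_a, tab_b; // [gate_or_trans][V_N]
  // for Markov schemes whose rates depend on V only: tabulated backward-Euler
  // propagator (I - dt Q(v)^T)^{-1}, [V_N][n*n]
  std::vector<double> prop_tab;
  bool has_prop;
  bool has_tab;
};

static double trans_rate(const ChannelInstance &ch, const Transition &tr,
                         double v, double ca) {
  double rate = tr.base * ch.tf;
  if (tr.kv != 0.0) rate *= clamped_exp((v - tr.vhalf) / tr.kv);
  if (tr.ca_pow != 0.0) rate *= int_ca_pow(ca, tr.ca_pow);
  return rate;
}

// dense small linear solve (n <= 10): A x = b, in place, partial pivoting
static void small_solve(int n, double *A, double *b) {
  for (int c = 0; c < n; ++c) {
    int piv = c;
    double best = std::fabs(A[c * n + c]);
    for (int r = c + 1; r < n; ++r) {
      double v = std::fabs(A[r * n + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (piv != c) {
      for (int j = 0; j < n; ++j) std::swap(A[c * n + j], A[piv * n + j]);
      std::swap(b[c], b[piv]);
    }
    double d = A[c * n + c];
    for (int r = c + 1; r < n; ++r) {
      double f = A[r * n + c] / d;
      if (f == 0.0) continue;
      for (int j = c; j < n; ++j) A[r * n + j] -= f * A[c * n + j];
      b[r] -= f * b[c];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int j = r + 1; j < n; ++j) s -= A[r * n + j] * b[j];
    b[r] = s / A[r * n + r];
  }
}

// build (I - dt Q^T) for one compartment and solve for new probabilities;
// exact (non-tabulated) rates, used during initialization
static void markov_step_exact(ChannelInstance &ch, int ci, double v, double ca,
                              double dt) {
  const int n = ch.n_states;
  double A[100];
  double b[10];
  std::memset(A, 0, sizeof(double) * n * n);
  double *p = &ch.mstate[(size_t)ci * n];
  for (int i = 0; i < n; ++i) { A[i * n + i] = 1.0; b[i] = p[i]; }
  for (size_t t = 0; t < ch.trans.size(); ++t) {
    const Transition &tr = ch.trans[t];
    double rate = trans_rate(ch, tr, v, ca);
    A[tr.from * n + tr.from] += dt * rate;
    A[tr.to * n + tr.from] -= dt * rate;
  }
  small_solve(n, A, b);
  double s = 0.0;
  for (int i = 0; i < n; ++i) { if (b[i] < 0) b[i] = 0; s += b[i]; }
  if (s <= 0) {
    for (int i = 0; i < n; ++i) b[i] = (i == 0) ? 1.0 : 0.0;
    s = 1.0;
  }
  for (int i = 0; i < n; ++i) p[i] = b[i] / s;
}

// propagator-table Markov step: p <- M(v) p with M linearly interpolated
static void markov_step_prop(ChannelInstance &ch, int ci, int vi, double vfrac) {
  const int n = ch.n_states;
  double *p = &ch.mstate[(size_t)ci * n];
  const double *M0 = &ch.prop_tab[(size_t)vi * n * n];
  const double *M1 = M0 + n * n;
  double out[10];
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double *r0 = M0 + (size_t)i * n, *r1 = M1 + (size_t)i * n;
    for (int j = 0; j < n; ++j) {
      s += (r0[j] + vfrac * (r1[j] - r0[j])) * p[j];
    }
    out[i] = s;
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) { if (out[i] < 0) out[i] = 0; s += out[i]; }
  if (s <= 0) { out[0] = 1.0; s = 1.0; }
  for (int i = 0; i < n; ++i) p[i] = out[i] / s;
}

// tabulated-rate Markov step for the main loop
static void markov_step_tab(ChannelInstance &ch, int ci, int vi, double vfrac,
                            double ca, double dt) {
  const int n = ch.n_states;
  double A[100];
  double b[10];
  std::memset(A, 0, sizeof(double) * n * n);
  double *p = &ch.mstate[(size_t)ci * n];
  for (int i = 0; i < n; ++i) { A[i * n + i] = 1.0; b[i] = p[i]; }
  for (size_t t = 0; t < ch.trans.size(); ++t) {
    const Transition &tr = ch.trans[t];
    double rate = tab_at(ch.tab_a, (int)t, vi, vfrac);
    if (tr.ca_pow != 0.0) rate *= int_ca_pow(ca, tr.ca_pow);
    double x = dt * rate;
    A[tr.from * n + tr.from] += x;
    A[tr.to * n + tr.from] -= x;
  }
  small_solve(n, A, b);
  double s = 0.0;
  for (int i = 0; i < n; ++i) { if (b[i] < 0) b[i] = 0; s += b[i]; }
  if (s <= 0) {
    for (int i = 0; i < n; ++i) b[i] = (i == 0) ? 1.0 : 0.0;
    s = 1.0;
  }
  for (int i = 0; i < n; ++i) p[i] = b[i] / s;
}

static double channel_open(const ChannelInstance &ch, int ci) {
  if (ch.kind == 0) {
    double o = 1.0;
    for (size_t g = 0; g < ch.gates.size(); ++g) {
      double m = ch.gstate[(size_t)ci * ch.gates.size() + g];
      for (int e = 0; e < ch.gates[g].exponent; ++e) o *= m;
    }
    return o;
  }
  double o = 0.0;
  const double *p = &ch.mstate[(size_t)ci * ch.n_states];
  for (size_t k = 0; k < ch.open_states.size(); ++k) o += p[ch.open_states[k]];
  return o;
}

// ---------------------------------------------------------------------------

struct Shell {
  double ca_rest, pump_vmax, pump_km, factor; // factor: nA -> mM/ms
  double surf_to_conc;                        // mol/cm^2/ms -> mM/ms
  double b_tot[2], b_kon[2], b_koff[2];
  int n_buf;
};

struct Synapse {
  int comp;
  int receptor; // 0 AMPA, 1 NMDA, 2 GABA
  double gmax, erev;
  double tau_r, tau_d, t_norm;
  double rb, ru, rd, rr;
  double mg, mg_k1, mg_k2;
  double ca_frac;
  std::vector<double> ev_t, ev_y;
  size_t next_ev;
  double A, B;   // transmitter components
  double O, D;   // receptor open / desensitized
  double i_nA;
};

struct Electrode {
  int mode; // 0 current clamp, 1 voltage clamp
  int comp;
  std::vector<double> t, val;
  double g_clamp;
  double i_nA;
};

static double waveform_at(const std::vector<double> &t,
                          const std::vector<double> &v, double now) {
  if (t.empty() || now < t[0]) return 0.0;
  size_t k = 0;
  while (k + 1 < t.size() && now >= t[k + 1]) ++k;
  return v[k];
}

// [[Rcpp::export]]
List sim_run(List ws, double t_stop, double dt, double v_init,
             List recordings, double record_dt, double settle_ms) {
  std::vector<int> parent = as<std::vector<int>>(ws["parent"]); // 0-based, -1 root
  std::vector<double> cap = as<std::vector<double>>(ws["cap_nF"]);
  std::vector<double> gl = as<std::vector<double>>(ws["gl_uS"]);
  std::vector<double> el = as<std::vector<double>>(ws["e_leak"]);
  std::vector<double> ga = as<std::vector<double>>(ws["g_axial_uS"]); // to parent
  const int ncomp = (int)parent.size();

  // ---- channels
  List chlist = ws["channels"];
  std::vector<ChannelInstance> channels(chlist.size());
  for (int c = 0; c < chlist.size(); ++c) {
    List cl = chlist[c];
    ChannelInstance &ch = channels[c];
    ch.kind = as<int>(cl["kind"]);
    ch.comps = as<std::vector<int>>(cl["comps"]);
    ch.gbar = as<std::vector<double>>(cl["gbar_uS"]);
    ch.erev = as<double>(cl["erev"]);
    ch.is_ca = as<bool>(cl["is_ca"]);
    ch.tf = as<double>(cl["tf"]);
    ch.has_tab = false;
    if (ch.kind == 0) {
      List gl2 = cl["gates"];
      for (int g = 0; g < gl2.size(); ++g) {
        NumericVector gp = gl2[g];
        GateDef gd;
        gd.kind = (int)gp["kind"];
        gd.exponent = (int)gp["exponent"];
        if (gd.kind == 0) {
          gd.vhalf = gp["vhalf"]; gd.k = gp["k"];
          gd.tau_min = gp["tau_min"]; gd.tau_amp = gp["tau_amp"];
          gd.tau_vhalf = gp["tau_vhalf"]; gd.tau_ka = gp["tau_ka"];
          gd.tau_kb = gp["tau_kb"];
        } else {
          gd.n = gp["n"]; gd.kd = gp["kd"]; gd.tau = gp["tau"];
        }
        ch.gates.push_back(gd);
      }
      ch.gstate.assign(ch.comps.size() * ch.gates.size(), 0.0);
    } else {
      ch.n_states = as<int>(cl["n_states"]);
      ch.open_states = as<std::vector<int>>(cl["open_states"]); // 0-based
      NumericMatrix tm = cl["trans"];
      for (int r = 0; r < tm.nrow(); ++r) {
        Transition tr;
        tr.from = (int)tm(r, 0); tr.to = (int)tm(r, 1);
        tr.base = tm(r, 2); tr.vhalf = tm(r, 3); tr.kv = tm(r, 4);
        tr.ca_pow = tm(r, 5);
        ch.trans.push_back(tr);
      }
      ch.mstate.assign(ch.comps.size() * ch.n_states, 0.0);
    }
  }

  // build voltage tables (dt-dependent decay factors for HH gates)
  for (size_t c = 0; c < channels.size(); ++c) {
    ChannelInstance &ch = channels[c];
    if (ch.kind == 0) {
      size_t ng = ch.gates.size();
      ch.tab_a.assign(ng * V_N, 0.0);
      ch.tab_b.assign(ng * V_N, 0.0);
      for (size_t g = 0; g < ng; ++g) {
        const GateDef &gd = ch.gates[g];
        if (gd.kind != 0) continue;
        for (int i = 0; i < V_N; ++i) {
          double v = V_MIN + i * V_STEP;
          ch.tab_a[g * V_N + i] = gate_inf_c(gd, v, 0.0);
          ch.tab_b[g * V_N + i] = std::exp(-dt * ch.tf / gate_tau_c(gd, v, 0.0));
        }
      }
    } else {
      size_t nt = ch.trans.size();
      ch.tab_a.assign(nt * V_N, 0.0);
      for (size_t t = 0; t < nt; ++t) {
        Transition tr = ch.trans[t];
        tr.ca_pow = 0.0; // tabulate the voltage part only
        for (int i = 0; i < V_N; ++i) {
          double v = V_MIN + i * V_STEP;
          ch.tab_a[t * V_N + i] = trans_rate(ch, tr, v, 1.0);
        }
      }
      ch.has_prop = true;
      for (size_t t = 0; t < nt; ++t) {
        if (ch.trans[t].ca_pow != 0.0) { ch.has_prop = false; break; }
      }
      if (ch.has_prop) {
        const int n = ch.n_states;
        ch.prop_tab.assign((size_t)V_N * n * n, 0.0);
        std::vector<double> A(n * n), Abase(n * n), e(n);
        for (int i = 0; i < V_N; ++i) {
          double v = V_MIN + i * V_STEP;
          std::fill(Abase.begin(), Abase.end(), 0.0);
          for (int d = 0; d < n; ++d) Abase[d * n + d] = 1.0;
          for (size_t t = 0; t < nt; ++t) {
            const Transition &tr = ch.trans[t];
            double rate = trans_rate(ch, tr, v, 1.0);
            Abase[tr.from * n + tr.from] += dt * rate;
            Abase[tr.to * n + tr.from] -= dt * rate;
          }
          double *M = &ch.prop_tab[(size_t)i * n * n];
          for (int col = 0; col < n; ++col) {
            std::copy(Abase.begin(), Abase.end(), A.begin());
            std::fill(e.begin(), e.end(), 0.0);
            e[col] = 1.0;
            small_solve(n, A.data(), e.data());
            for (int row = 0; row < n; ++row) M[row * n + col] = e[row];
          }
        }
      }
    }
    ch.has_tab = true;
  }

  // ---- shells
  List shlist = ws["shells"];
  std::vector<int> shell_of = as<std::vector<int>>(ws["shell_of"]);
  std::vector<Shell> shells(shlist.size());
  std::vector<double> ca(ncomp), sh_b1(ncomp, 0.0), sh_b2(ncomp, 0.0);
  for (int s = 0; s < shlist.size(); ++s) {
    List sl = shlist[s];
    Shell &sh = shells[s];
    sh.ca_rest = as<double>(sl["ca_rest"]);
    sh.pump_vmax = as<double>(sl["pump_vmax"]);
    sh.pump_km = as<double>(sl["pump_km"]);
    sh.factor = as<double>(sl["factor"]);
    sh.surf_to_conc = as<double>(sl["surf_to_conc"]);
    NumericVector bt = sl["b_tot"], bk = sl["b_kon"], bo = sl["b_koff"];
    sh.n_buf = bt.size() > 2 ? 2 : (int)bt.size();
    for (int b = 0; b < sh.n_buf; ++b) {
      sh.b_tot[b] = bt[b]; sh.b_kon[b] = bk[b]; sh.b_koff[b] = bo[b];
    }
  }
  double ca_default = 5e-5;
  for (int i = 0; i < ncomp; ++i) {
    int s = shell_of[i];
    ca[i] = (s >= 0) ? shells[s].ca_rest : ca_default;
    if (s >= 0) {
      const Shell &sh = shells[s];
      for (int b = 0; b < sh.n_buf; ++b) {
        double kd = sh.b_koff[b] / sh.b_kon[b];
        double bound = sh.b_tot[b] * ca[i] / (ca[i] + kd);
        if (b == 0) sh_b1[i] = bound; else sh_b2[i] = bound;
      }
    }
  }

  // ---- synapses
  List sylist = ws["synapses"];
  std::vector<Synapse> syns(sylist.size());
  for (int s = 0; s < sylist.size(); ++s) {
    List sl = sylist[s];
    Synapse &sy = syns[s];
    sy.comp = as<int>(sl["comp"]);
    sy.receptor = as<int>(sl["receptor"]);
    sy.gmax = as<double>(sl["gmax_uS"]);
    sy.erev = as<double>(sl["erev"]);
    sy.tau_r = as<double>(sl["tau_r"]);
    sy.tau_d = as<double>(sl["tau_d"]);
    sy.rb = as<double>(sl["rb"]); sy.ru = as<double>(sl["ru"]);
    sy.rd = as<double>(sl["rd"]); sy.rr = as<double>(sl["rr"]);
    sy.mg = as<double>(sl["mg"]); sy.mg_k1 = as<double>(sl["mg_k1"]);
    sy.mg_k2 = as<double>(sl["mg_k2"]);
    sy.ca_frac = as<double>(sl["ca_frac"]);
    sy.ev_t = as<std::vector<double>>(sl["ev_t"]);
    sy.ev_y = as<std::vector<double>>(sl["ev_y"]);
    double tp = std::log(sy.tau_d / sy.tau_r) * sy.tau_d * sy.tau_r /
      (sy.tau_d - sy.tau_r);
    sy.t_norm = std::exp(-tp / sy.tau_d) - std::exp(-tp / sy.tau_r);
    sy.next_ev = 0; sy.A = sy.B = sy.O = sy.D = 0.0; sy.i_nA = 0.0;
  }

  // ---- electrodes
  List elist = ws["electrodes"];
  std::vector<Electrode> els(elist.size());
  for (int e = 0; e < elist.size(); ++e) {
    List el2 = elist[e];
    Electrode &ee = els[e];
    ee.mode = as<int>(el2["mode"]);
    ee.comp = as<int>(el2["comp"]);
    ee.t = as<std::vector<double>>(el2["t"]);
    ee.val = as<std::vector<double>>(el2["val"]);
    ee.g_clamp = as<double>(el2["g_clamp"]);
    ee.i_nA = 0.0;
  }

  // ---- state init: gates at steady state, Markov relaxed to stationary
  std::vector<double> v(ncomp, v_init);
  for (size_t c = 0; c < channels.size(); ++c) {
    ChannelInstance &ch = channels[c];
    for (size_t ci = 0; ci < ch.comps.size(); ++ci) {
      double cca = ca[ch.comps[ci]];
      if (ch.kind == 0) {
        for (size_t g = 0; g < ch.gates.size(); ++g) {
          ch.gstate[ci * ch.gates.size() + g] = gate_inf_c(ch.gates[g], v_init, cca);
        }
      } else {
        double *p = &ch.mstate[ci * ch.n_states];
        p[0] = 1.0;
        for (int it = 0; it < 60; ++it) {
          markov_step_exact(ch, (int)ci, v_init, cca, 20.0);
        }
      }
    }
  }

  // ---- recordings
  IntegerMatrix rec_m = recordings["spec"]; // cols: kind, idx1, idx2
  const int nrec = rec_m.nrow();
  std::vector<int> rec(rec_m.begin(), rec_m.end()); // column-major
  int sample_every = (int)std::max(1.0, std::floor(record_dt / dt + 0.5));
  int nstep = (int)std::floor(t_stop / dt + 0.5);
  int nsamp = (t_stop <= 0) ? 0 : (nstep / sample_every + 1);
  std::vector<double> out((size_t)(nsamp > 0 ? nsamp : 0) * nrec);
  std::vector<double> tout(nsamp > 0 ? nsamp : 0);

  std::vector<double> diag(ncomp), rhs(ncomp);
  std::vector<double> dscr(ncomp), bscr(ncomp);
  std::vector<double> ica(ncomp);

  int isamp = 0;
  auto record_now = [&](double now) {
    if (isamp >= nsamp) return;
    tout[isamp] = now;
    for (int r = 0; r < nrec; ++r) {
      int kind = rec[r], i1 = rec[nrec + r], i2 = rec[2 * nrec + r];
      double val = 0.0;
      switch (kind) {
      case 0: val = v[i1]; break;
      case 1: val = ca[i1]; break;
      case 2: val = syns[i1].i_nA; break;
      case 3: val = els[i1].i_nA; break;
      case 4: {
        ChannelInstance &chv = channels[i1];
        val = chv.gbar[i2] * channel_open(chv, i2) *
          (v[chv.comps[i2]] - chv.erev);
        break;
      }
      }
      out[(size_t)r * nsamp + isamp] = val;
    }
    ++isamp;
  };

  int settle_steps = (int)std::floor(settle_ms / dt + 0.5);

  if (nsamp > 0) {
    for (int step = -settle_steps; step < nstep; ++step) {
      double now = step * dt;
      double tnew = now + dt;
      bool recording_phase = step >= 0;
      if (step == 0) record_now(0.0);

      for (int i = 0; i < ncomp; ++i) {
        double cd = cap[i] / dt;
        diag[i] = cd + gl[i];
        rhs[i] = cd * v[i] + gl[i] * el[i];
        ica[i] = 0.0;
      }
      for (size_t c = 0; c < channels.size(); ++c) {
        ChannelInstance &ch = channels[c];
        for (size_t ci = 0; ci < ch.comps.size(); ++ci) {
          double g = ch.gbar[ci] * channel_open(ch, (int)ci);
          int i = ch.comps[ci];
          diag[i] += g;
          rhs[i] += g * ch.erev;
          if (ch.is_ca) ica[i] += g * (v[i] - ch.erev); // pre-solve estimate
        }
      }
      for (size_t s = 0; s < syns.size(); ++s) {
        Synapse &sy = syns[s];
        while (sy.next_ev < sy.ev_t.size() && sy.ev_t[sy.next_ev] <= tnew) {
          sy.A += sy.ev_y[sy.next_ev];
          sy.B += sy.ev_y[sy.next_ev];
          ++sy.next_ev;
        }
        double g = sy.gmax * sy.O;
        if (sy.receptor == 1) {
          g *= 1.0 / (1.0 + sy.mg / sy.mg_k1 * std::exp(-sy.mg_k2 * v[sy.comp]));
        }
        diag[sy.comp] += g;
        rhs[sy.comp] += g * sy.erev;
      }
      for (size_t e = 0; e < els.size(); ++e) {
        Electrode &ee = els[e];
        double w = waveform_at(ee.t, ee.val, recording_phase ? now : 0.0);
        if (ee.mode == 0) rhs[ee.comp] += w;
        else { diag[ee.comp] += ee.g_clamp; rhs[ee.comp] += ee.g_clamp * w; }
      }

      // Hines solve
      for (int i = 0; i < ncomp; ++i) { dscr[i] = diag[i]; bscr[i] = rhs[i]; }
      for (int i = 0; i < ncomp; ++i) {
        int p = parent[i];
        if (p >= 0) { dscr[i] += ga[i]; dscr[p] += ga[i]; }
      }
      for (int i = ncomp - 1; i > 0; --i) {
        int p = parent[i];
        if (p < 0) continue;
        double f = ga[i] / dscr[i];
        dscr[p] -= ga[i] * f;
        bscr[p] += f * bscr[i];
      }
      v[0] = bscr[0] / dscr[0];
      for (int i = 1; i < ncomp; ++i) {
        int p = parent[i];
        v[i] = (p >= 0) ? (bscr[i] + ga[i] * v[p]) / dscr[i]
                        : bscr[i] / dscr[i];
      }
      for (int i = 0; i < ncomp; ++i) {
        if (!R_finite(v[i])) {
          stop("integration failure: non-finite voltage in compartment %d at t = %g ms",
               i + 1, tnew);
        }
      }

      for (size_t e = 0; e < els.size(); ++e) {
        Electrode &ee = els[e];
        double w = waveform_at(ee.t, ee.val, recording_phase ? now : 0.0);
        if (ee.mode == 1) ee.i_nA = ee.g_clamp * (w - v[ee.comp]);
        else ee.i_nA = w;
      }

      for (size_t s = 0; s < syns.size(); ++s) {
        Synapse &sy = syns[s];
        double vc = v[sy.comp];
        double unblock = 1.0;
        if (sy.receptor == 1) {
          unblock = 1.0 / (1.0 + sy.mg / sy.mg_k1 * std::exp(-sy.mg_k2 * vc));
        }
        double i_now = sy.gmax * sy.O * unblock * (vc - sy.erev);
        sy.i_nA = i_now;
        if (sy.receptor == 1 && shell_of[sy.comp] >= 0) {
          ica[sy.comp] += sy.ca_frac * i_now;
        }
        double T0 = (sy.A - sy.B) / sy.t_norm;
        sy.A *= std::exp(-dt / sy.tau_d);
        sy.B *= std::exp(-dt / sy.tau_r);
        double T1 = (sy.A - sy.B) / sy.t_norm;
        double T = 0.5 * (T0 + T1);
        double a11 = 1.0 + dt * (sy.rb * T + sy.ru + sy.rd);
        double a12 = dt * sy.rb * T;
        double a21 = -dt * sy.rd;
        double a22 = 1.0 + dt * sy.rr;
        double b1 = sy.O + dt * sy.rb * T;
        double b2 = sy.D;
        double det = a11 * a22 - a12 * a21;
        double On = (b1 * a22 - a12 * b2) / det;
        double Dn = (a11 * b2 - a21 * b1) / det;
        sy.O = On < 0 ? 0 : On;
        sy.D = Dn < 0 ? 0 : Dn;
      }

      // channel state updates at the new voltage (tabulated)
      for (size_t c = 0; c < channels.size(); ++c) {
        ChannelInstance &ch = channels[c];
        const size_t ng = ch.gates.size();
        for (size_t ci = 0; ci < ch.comps.size(); ++ci) {
          int i = ch.comps[ci];
          double vv = v[i], cca = ca[i];
          double vfrac;
          int vi = v_index(vv, vfrac);
          if (ch.kind == 0) {
            for (size_t g = 0; g < ng; ++g) {
              const GateDef &gd = ch.gates[g];
              double minf, dec;
              if (gd.kind == 0) {
                minf = tab_at(ch.tab_a, (int)g, vi, vfrac);
                dec = tab_at(ch.tab_b, (int)g, vi, vfrac);
              } else {
                minf = gate_inf_c(gd, vv, cca);
                dec = std::exp(-dt * ch.tf / gd.tau);
              }
              double &m = ch.gstate[ci * ng + g];
              m = minf + (m - minf) * dec;
            }
          } else if (ch.has_prop) {
            markov_step_prop(ch, (int)ci, vi, vfrac);
          } else {
            markov_step_tab(ch, (int)ci, vi, vfrac, cca, dt);
          }
        }
      }

      // calcium shells
      for (int i = 0; i < ncomp; ++i) {
        int si = shell_of[i];
        if (si < 0) continue;
        const Shell &sh = shells[si];
        double c0 = ca[i];
        double sat0 = sh.ca_rest / (sh.ca_rest + sh.pump_km);
        for (int h = 0; h < 2; ++h) {
          double influx = -ica[i] * sh.factor;
          double sat = c0 / (c0 + sh.pump_km);
          double pump = sh.pump_vmax * (sat - sat0) * sh.surf_to_conc;
          double dca = influx - pump;
          double bnd[2] = { sh_b1[i], sh_b2[i] };
          for (int b = 0; b < sh.n_buf; ++b) {
            double freeb = sh.b_tot[b] - bnd[b];
            double db = sh.b_kon[b] * c0 * freeb - sh.b_koff[b] * bnd[b];
            dca -= db;
            bnd[b] += db * dt * 0.5;
            if (bnd[b] < 0) bnd[b] = 0;
            if (bnd[b] > sh.b_tot[b]) bnd[b] = sh.b_tot[b];
          }
          c0 += dca * dt * 0.5;
          if (c0 < 1e-9) c0 = 1e-9;
          sh_b1[i] = bnd[0]; sh_b2[i] = bnd[1];
        }
        ca[i] = c0;
      }

      if (recording_phase && ((step + 1) % sample_every == 0)) record_now(tnew);
    }
  }

  NumericMatrix outm(nsamp > 0 ? nsamp : 0, nrec);
  if (nsamp > 0) std::copy(out.begin(), out.end(), outm.begin());
  return List::create(_["time"] = wrap(tout), _["traces"] = outm);
}
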