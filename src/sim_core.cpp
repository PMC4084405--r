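#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Activation update shared with the R-level clamp_trace(): explicit Euler on
// (1 - S_inf) tau dS/dt = S_inf - S, S clamped to [0, 1 - 1e-9].
// s_inf: per-sample steady-state activation (already threshold-gated and
// capped below 1); returns components x samples matrix of S *after* each step.
// [[Rcpp::export]]
NumericMatrix clamp_activation_core(NumericVector s_inf, NumericVector tau,
                                    double dt) {
  int nc = tau.size(), n = s_inf.size();
  NumericMatrix S(nc, n);
  std::vector<double> s(nc, 0.0);
  for (int i = 0; i < n; ++i) {
    double si = s_inf[i];
    for (int c = 0; c < nc; ++c) {
      double teff = (1.0 - si) * tau[c];
      s[c] += dt * (si - s[c]) / teff;
      if (s[c] < 0) s[c] = 0;
      if (s[c] > 1 - 1e-9) s[c] = 1 - 1e-9;
      S(c, i) = s[c];
    }
  }
  return S;
}

namespace {

struct Unit {
  double C, gL, EL, VT, Vreset, tref_ms, b, tau_w, noise;
  double V, w;
  int ref_steps_left;
  int render_steps_left;   // depolarised spike plateau for trace realism
  double vt_shift;         // Hi-Di threshold raise
  void init() { V = EL; w = 0; ref_steps_left = 0; render_steps_left = 0; }
};

inline double getd(List& p, const char* nm) { return as<double>(p[nm]); }

} // namespace

// Hybrid integrate-and-fire simulation of the DSI - C2 - VSI swim circuit.
// Units: mV, ms, nS, pA, pF. All randomness comes from the R RNG.
// [[Rcpp::export]]
List simulate_core(List par, double duration_s, double dt, bool keep_traces) {
  RNGScope scope;

  const double dur_ms = duration_s * 1000.0;
  const int n_steps = (int)std::floor(dur_ms / dt);

  // --- circuit switches -----------------------------------------------------
  const bool intact = as<bool>(par["pdn6_intact"]);
  const bool hidi   = as<bool>(par["hi_di"]);
  const int  clamp_mode = as<int>(par["clamp_mode"]); // 0 off, 1 add, -1 subtract
  const int  stim_type  = as<int>(par["stim_type"]);  // 0 none, 1 swim, 2 C2 train

  // --- units: 0 DSI (lumped x3), 1 C2, 2 VSI proximal, 3 VSI distal ---------
  Unit u[4];
  const char* pre[4] = {"dsi", "c2", "vsip", "vsid"};
  for (int k = 0; k < 4; ++k) {
    std::string s(pre[k]);
    u[k].C       = getd(par, (s + "_C").c_str());
    u[k].gL      = getd(par, (s + "_gL").c_str());
    u[k].EL      = getd(par, (s + "_EL").c_str());
    u[k].VT      = getd(par, (s + "_VT").c_str());
    u[k].Vreset  = getd(par, (s + "_Vreset").c_str());
    u[k].tref_ms = getd(par, (s + "_tref").c_str());
    u[k].b       = getd(par, (s + "_b").c_str());
    u[k].tau_w   = getd(par, (s + "_tauw").c_str());
    u[k].noise   = getd(par, (s + "_noise").c_str()); // pA RMS (white, per sqrt(ms))
    u[k].vt_shift = hidi ? getd(par, "hidi_vt_shift") : 0.0;
    u[k].init();
  }
  const int render_steps = std::max(1, (int)std::round(getd(par, "spike_render_ms") / dt));

  // --- C2 burst gate ---------------------------------------------------------
  // C2's slow adaptation current acts with hysteresis (a calcium-activated
  // potassium conductance): once the adaptation variable exceeds w_hi the
  // cell falls silent until w has decayed below w_lo. This gives the kernel
  // an intrinsic burst rhythm that survives loss of VSI feedback; VSI
  // inhibition can still terminate a burst early through the voltage path.
  const double c2_w_hi = getd(par, "c2_w_hi");
  const double c2_w_lo = getd(par, "c2_w_lo");
  bool c2_gated = false;

  // --- synaptic kernels (current-based exponentials, pA) --------------------
  // DSI->C2 E, C2->DSI E, VSI->C2 I, VSI->DSI I, C2->VSId E (crosses PdN6),
  // recruited EPSP barrage onto VSIp.
  // VSI inhibition of C2/DSI is carried by two kernels: distal spikes that
  // cross PdN6 act through a strong slow kernel (the cycle timer of the
  // intact rhythm), proximal-zone spikes through a weaker fast kernel.
  double x_dc = 0, x_cd = 0, x_vc = 0, x_vd = 0, x_vcp = 0, x_vdp = 0,
         x_cvd = 0, x_ep = 0;
  const double tau_dc  = getd(par, "tau_dsi_c2");
  const double tau_cd  = getd(par, "tau_c2_dsi");
  const double tau_vc  = getd(par, "tau_vsi_c2");
  const double tau_vd  = getd(par, "tau_vsi_dsi");
  const double tau_vp  = getd(par, "tau_vsip_inh");
  const double tau_cvd = getd(par, "tau_c2_vsid");
  const double tau_ep  = getd(par, "tau_epsp");
  const double a_dc  = getd(par, "w_dsi_c2");
  const double a_cd  = getd(par, "w_c2_dsi");
  const double a_vc  = getd(par, "w_vsi_c2");   // negative
  const double a_vd  = getd(par, "w_vsi_dsi");  // negative
  const double vsip_scale = getd(par, "vsip_inh_scale"); // proximal share
  const double a_cvd = getd(par, "w_c2_vsid") * getd(par, "distal_gain");
  const double d_dc = std::exp(-dt / tau_dc), d_cd = std::exp(-dt / tau_cd),
               d_vc = std::exp(-dt / tau_vc), d_vd = std::exp(-dt / tau_vd),
               d_vp = std::exp(-dt / tau_vp),
               d_cvd = std::exp(-dt / tau_cvd), d_ep = std::exp(-dt / tau_ep);

  // --- PdN6 conduction delay line -------------------------------------------
  const double delay_ms = getd(par, "pdn6_delay");
  const int delay_steps = std::max(1, (int)std::round(delay_ms / dt));
  // scheduled C2->VSId increments and VSId->soma arrivals
  std::vector<double> sched_cvd(n_steps + delay_steps + 2, 0.0);
  std::vector<char>   sched_arrival(n_steps + delay_steps + 2, 0);

  // --- direct C2->VSIp synapse: threshold-gated first-order kinetics --------
  // fast depolarising component and slow (700/1300 ms) hyperpolarising pair
  const double vth = getd(par, "syn_vthresh"), vsl = getd(par, "syn_vslope");
  const double tau_fast = getd(par, "syn_tau_fast");
  const double tau_s1 = getd(par, "syn_tau_slow1"), tau_s2 = getd(par, "syn_tau_slow2");
  // The per-animal scales are calibrated in Hi-Di saline, which depresses
  // transmitter release; in normal saline the two components are stronger by
  // separate gains. The hyperpolarizing component acts through a slowly
  // deactivating potassium conductance (first-order filter on the release
  // signal), so it outlasts the release transient.
  const double A_d = (hidi ? 1.0 : getd(par, "depol_gain_normal")) *
    getd(par, "A_d");
  const double A_h = (hidi ? 1.0 : getd(par, "hyperpol_gain_normal")) *
    getd(par, "A_h");
  const double tau_hf = getd(par, "h_filter_tau");
  const bool use_hf = !hidi;     // calibration measures the raw release signal
  double S_fast = 0, S_s1 = 0, S_s2 = 0, S_hf = 0;

  // --- dynamic clamp (same kinetics, injected at the soma) -------------------
  // clamp_net_gain converts the commanded conductance (nS) to the reduced
  // current scale of the lumped model units.
  const double g_clamp = getd(par, "clamp_net_gain") *
    getd(par, "clamp_gsyn") * (clamp_mode == 0 ? 0.0 : (double)clamp_mode);
  const double clamp_vsyn = getd(par, "clamp_vsyn");
  const double clamp_vpost = getd(par, "clamp_vpost");
  const double clamp_w1 = getd(par, "clamp_w1"), clamp_w2 = 1.0 - getd(par, "clamp_w1");
  double Sc1 = 0, Sc2 = 0;

  // --- recruited polysynaptic pool ------------------------------------------
  // Each C2 spike feeds a recruiting stage (pool_p, decay tau_rise) which in
  // turn charges the active pool (pool_r, decay tau_pool): the barrage rate
  // therefore rises with a lag after C2 starts firing and outlasts the burst.
  double pool_r = 0, pool_p = 0;
  const double tau_pool = getd(par, "tau_pool");        // ms (~10 s)
  const double tau_rise = getd(par, "pool_rise");       // ms recruitment lag
  const double d_pool = std::exp(-dt / tau_pool);
  const double d_rise = std::exp(-dt / tau_rise);
  const double pool_per_spike = getd(par, "pool_per_spike");
  const double pool_rate_hz = getd(par, "pool_rate_hz"); // Hz per unit of r
  const double pool_rate0 = hidi ? 0.0 : getd(par, "pool_rate0");
  // the recruited population is finite: its firing rate saturates once a
  // couple of C2 spikes have recruited every member
  const double pool_cap = getd(par, "pool_cap");
  // recruitment threshold: an isolated C2 spike leaves the pool below the
  // level needed to start the barrage; only summed burst input clears it
  const double pool_floor = getd(par, "pool_floor");
  const double ep_meanlog = getd(par, "epsp_meanlog"), ep_sdlog = getd(par, "epsp_sdlog");
  const double ep_gain = getd(par, "epsp_gain");        // pA per mV of EPSP
  const bool pool_on = !hidi;

  // --- episode drive / stimulation ------------------------------------------
  const double stim_start = getd(par, "stim_start") * 1000.0; // ms
  const double stim_dur   = getd(par, "stim_dur") * 1000.0;
  double D = 0;                                     // excitatory drive reservoir
  const double D0 = getd(par, "D0");
  const double tau_D = getd(par, "tau_D");          // ms
  const double c_rel = getd(par, "c_rel");          // reservoir use per C2 spike
  const double kD = getd(par, "kD");                // pA per unit D onto DSI
  const double stim_dsi = getd(par, "stim_dsi");    // pA during nerve shock
  const double stim_vsip = getd(par, "stim_vsip");  // pA, brief direct VSI drive
  const double stim_vsip_dur = getd(par, "stim_vsip_dur"); // ms
  const double c2_pulse = getd(par, "c2_pulse") * (hidi ? getd(par, "hidi_pulse_boost") : 1.0);
  const double c2_pulse_width = getd(par, "c2_pulse_width"); // ms
  const double c2_rate = getd(par, "c2_rate");      // Hz

  const double sqdt = std::sqrt(dt);

  std::vector<double> sp[4];
  std::vector<double> arrivals;         // distal spikes arriving at the soma
  std::vector<double> ep_times, ep_amps;

  NumericMatrix traces;
  if (keep_traces) traces = NumericMatrix(n_steps, 5); // DSI, C2, VSIp, Iclamp, soma add-on handled in R

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;

    // decay kernels
    x_dc *= d_dc; x_cd *= d_cd; x_vc *= d_vc; x_vd *= d_vd;
    x_vcp *= d_vp; x_vdp *= d_vp;
    x_cvd *= d_cvd; x_ep *= d_ep;
    pool_r *= d_pool;
    pool_r += pool_p * (dt / tau_rise);
    pool_p *= d_rise;
    x_cvd += sched_cvd[i];

    // recruited EPSP barrage (inhomogeneous Poisson)
    if (pool_on) {
      double drive = std::min(pool_r, pool_cap) - pool_floor;
      if (drive < 0) drive = 0;
      double lam = (pool_rate_hz * drive + pool_rate0) / 1000.0; // per ms
      if (unif_rand() < lam * dt) {
        double amp = std::exp(ep_meanlog + ep_sdlog * norm_rand()); // mV
        x_ep += amp * ep_gain;
        ep_times.push_back(t / 1000.0);
        ep_amps.push_back(amp);
      }
    }

    // direct synapse + clamp activations driven by C2 membrane potential
    double vpre = u[1].V;
    double sinf = (vpre > vth) ? std::tanh((vpre - vth) / vsl) : 0.0;
    if (sinf > 1 - 1e-6) sinf = 1 - 1e-6;
    S_fast += dt * (sinf - S_fast) / ((1 - sinf) * tau_fast);
    S_s1   += dt * (sinf - S_s1)   / ((1 - sinf) * tau_s1);
    S_s2   += dt * (sinf - S_s2)   / ((1 - sinf) * tau_s2);
    if (S_fast > 1 - 1e-9) S_fast = 1 - 1e-9;
    if (S_s1 > 1 - 1e-9) S_s1 = 1 - 1e-9;
    if (S_s2 > 1 - 1e-9) S_s2 = 1 - 1e-9;
    double S_rel = 0.5 * (S_s1 + S_s2);
    S_hf += dt * (S_rel - S_hf) / tau_hf;
    double S_slow = use_hf ? S_hf : S_rel;
    Sc1 += dt * (sinf - Sc1) / ((1 - sinf) * tau_s1);
    Sc2 += dt * (sinf - Sc2) / ((1 - sinf) * tau_s2);
    if (Sc1 > 1 - 1e-9) Sc1 = 1 - 1e-9;
    if (Sc2 > 1 - 1e-9) Sc2 = 1 - 1e-9;
    double I_clamp = g_clamp * (clamp_w1 * Sc1 + clamp_w2 * Sc2) * (clamp_vsyn - clamp_vpost);

    // stimulation currents
    bool in_stim = (stim_type == 1) && t >= stim_start && t < stim_start + stim_dur;
    double I_stim_dsi = in_stim ? stim_dsi : 0.0;
    double I_stim_vsip = (stim_type == 1 && t >= stim_start &&
                          t < stim_start + stim_vsip_dur) ? stim_vsip : 0.0;
    double I_stim_c2 = 0.0;
    if (stim_type == 2 && t >= stim_start && t < stim_start + stim_dur) {
      double period = 1000.0 / c2_rate;
      double el = t - stim_start;
      double phase = el - period * std::floor(el / period);
      if (phase < c2_pulse_width) I_stim_c2 = c2_pulse;
    }

    // drive reservoir
    if (stim_type == 1) {
      if (in_stim) D += dt * (D0 - D) / 800.0;
      else D -= dt * D / tau_D;
      if (D < 0) D = 0;
    }

    // total input currents
    double I_in[4];
    I_in[0] = kD * D + x_cd + x_vd + x_vdp + I_stim_dsi;         // DSI
    I_in[1] = x_dc + x_vc + x_vcp + I_stim_c2;                   // C2
    I_in[2] = x_ep + A_d * S_fast - A_h * S_slow + I_clamp + I_stim_vsip; // VSI proximal
    I_in[3] = intact ? x_cvd : 0.0;                              // VSI distal

    // integrate units
    for (int k = 0; k < 4; ++k) {
      Unit& q = u[k];
      q.w += dt * (-q.w / q.tau_w);
      // one draw per noisy unit per step, even while refractory, so the
      // shared RNG stream is identical across lesion/clamp conditions
      double nz = (q.noise > 0) ? norm_rand() : 0.0;
      if (q.ref_steps_left > 0) {
        q.ref_steps_left--;
        if (q.render_steps_left > 0) {
          // brief depolarised plateau so the presynaptic waveform drives the
          // release kinetics over a realistic spike width
          q.V = 30.0 - (30.0 - q.Vreset) *
            (1.0 - (double)q.render_steps_left / render_steps);
          q.render_steps_left--;
        } else q.V = q.Vreset;
        continue;
      }
      if (k == 1 && c2_w_hi > 0) {
        if (c2_gated && q.w < c2_w_lo) c2_gated = false;
        else if (!c2_gated && q.w > c2_w_hi) c2_gated = true;
      }
      double dV = dt / q.C * (-q.gL * (q.V - q.EL) - q.w + I_in[k]);
      if (q.noise > 0) dV += q.noise / q.C * sqdt * nz;
      q.V += dV;
      if (q.V < -120) q.V = -120;
      if (q.V > 60) q.V = 60;
      if (k == 1 && c2_gated && q.V > q.VT + q.vt_shift - 2.0)
        q.V = q.VT + q.vt_shift - 2.0;   // gated: clamped just below threshold
      if (q.V >= q.VT + q.vt_shift) {
        sp[k].push_back(t / 1000.0);
        q.w += q.b;
        q.ref_steps_left = std::max(1, (int)std::round(q.tref_ms / dt));
        q.render_steps_left = render_steps;
        q.V = 30.0;
        // downstream events
        if (k == 0) { x_dc += a_dc; }
        else if (k == 1) {
          x_cd += a_cd;
          pool_p += pool_per_spike;
          if (stim_type == 1) { D -= c_rel; if (D < 0) D = 0; }
          if (intact) {
            int j = i + delay_steps;
            if (j < (int)sched_cvd.size()) sched_cvd[j] += a_cvd;
          }
        } else if (k == 2) { // proximal spike: reaches C2/DSI via proximal paths
          x_vcp += vsip_scale * a_vc; x_vdp += vsip_scale * a_vd;
        } else if (k == 3) { // distal spike: must cross PdN6 to act centrally
          if (intact) {
            int j = i + delay_steps;
            if (j < (int)sched_arrival.size()) sched_arrival[j] = 1;
          }
        }
      }
    }

    // antidromic arrival at the soma: invades the proximal zone (collision /
    // refractory takeover) and feeds the central synapses of VSI
    if (intact && sched_arrival[i]) {
      arrivals.push_back(t / 1000.0);
      x_vc += a_vc; x_vd += a_vd;
      Unit& q = u[2];
      q.ref_steps_left = std::max(q.ref_steps_left,
                                  (int)std::round(q.tref_ms / dt));
      q.render_steps_left = 0;
      q.V = q.Vreset;
    }

    if (keep_traces) {
      traces(i, 0) = u[0].V;
      traces(i, 1) = u[1].V;
      traces(i, 2) = u[2].V;
      traces(i, 3) = I_clamp;
      traces(i, 4) = A_d * S_fast - A_h * S_slow; // direct synaptic current
    }
  }

  return List::create(
    _["spikes_dsi"] = wrap(sp[0]),
    _["spikes_c2"] = wrap(sp[1]),
    _["spikes_vsip"] = wrap(sp[2]),
    _["spikes_vsid"] = wrap(sp[3]),
    _["vsid_arrivals"] = wrap(arrivals),
    _["epsp_times"] = wrap(ep_times),
    _["epsp_amps"] = wrap(ep_amps),
    _["traces"] = keep_traces ? (SEXP)traces : R_NilValue,
    _["dt"] = dt,
    _["n_steps"] = n_steps,
    _["D_end"] = D);
}
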