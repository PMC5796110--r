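// Single-compartment conductance-based integrator.
//
// Units throughout: mV, ms, pA, nS, pF (so dV/dt in mV/ms = pA/pF).
// Gating variables follow first-order Boltzmann kinetics,
//   x_inf(V) = 1 / (1 + exp(-(V - half)/k))      (sign of k sets direction)
//   tau_x(V) = tau_min + tau_amp * exp(-((V - tau_v0)/tau_sig)^2)
// and are advanced with the exponential-Euler update, which is
// unconditionally stable for this class of equations. The membrane
// equation is likewise advanced with exponential Euler on the
// instantaneous conductance decomposition I_ion = g_tot (V - E_eff).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline double xinf(double v, double half, double k) {
  return 1.0 / (1.0 + std::exp(-(v - half) / k));
}

inline double tauv(double v, double tmin, double tamp, double tv0, double tsig) {
  const double z = (v - tv0) / tsig;
  return tmin + tamp * std::exp(-z * z);
}

struct Pars {
  double cm, gl, el;
  double gna, ena, nam_half, nam_k, nam_tau;
  double nah_half, nah_k, nah_tau_min, nah_tau_amp, nah_tau_v0, nah_tau_sig;
  double gk, ek, kn_half, kn_k, kn_tau_min, kn_tau_amp, kn_tau_v0, kn_tau_sig;
  double gh, eh, hcn_half, hcn_k, hcn_tau_min, hcn_tau_amp, hcn_tau_v0, hcn_tau_sig;
  double gnap, nap_half, nap_k;
};

Pars read_pars(const NumericVector& p) {
  Pars q;
  q.cm = p["cm"]; q.gl = p["gl"]; q.el = p["el"];
  q.gna = p["gna"]; q.ena = p["ena"];
  q.nam_half = p["nam_half"]; q.nam_k = p["nam_k"]; q.nam_tau = p["nam_tau"];
  q.nah_half = p["nah_half"]; q.nah_k = p["nah_k"];
  q.nah_tau_min = p["nah_tau_min"]; q.nah_tau_amp = p["nah_tau_amp"];
  q.nah_tau_v0 = p["nah_tau_v0"]; q.nah_tau_sig = p["nah_tau_sig"];
  q.gk = p["gk"]; q.ek = p["ek"];
  q.kn_half = p["kn_half"]; q.kn_k = p["kn_k"];
  q.kn_tau_min = p["kn_tau_min"]; q.kn_tau_amp = p["kn_tau_amp"];
  q.kn_tau_v0 = p["kn_tau_v0"]; q.kn_tau_sig = p["kn_tau_sig"];
  q.gh = p["gh"]; q.eh = p["eh"];
  q.hcn_half = p["hcn_half"]; q.hcn_k = p["hcn_k"];
  q.hcn_tau_min = p["hcn_tau_min"]; q.hcn_tau_amp = p["hcn_tau_amp"];
  q.hcn_tau_v0 = p["hcn_tau_v0"]; q.hcn_tau_sig = p["hcn_tau_sig"];
  q.gnap = p["gnap"]; q.nap_half = p["nap_half"]; q.nap_k = p["nap_k"];
  return q;
}

struct State {
  double v, m, h, n, r;
};

// Advance gates one step at voltage v (exponential Euler).
inline void step_gates(State& s, const Pars& p, double dt) {
  const double v = s.v;
  s.m += (xinf(v, p.nam_half, p.nam_k) - s.m) * (1.0 - std::exp(-dt / p.nam_tau));
  const double th = tauv(v, p.nah_tau_min, p.nah_tau_amp, p.nah_tau_v0, p.nah_tau_sig);
  s.h += (xinf(v, p.nah_half, p.nah_k) - s.h) * (1.0 - std::exp(-dt / th));
  const double tn = tauv(v, p.kn_tau_min, p.kn_tau_amp, p.kn_tau_v0, p.kn_tau_sig);
  s.n += (xinf(v, p.kn_half, p.kn_k) - s.n) * (1.0 - std::exp(-dt / tn));
  const double tr = tauv(v, p.hcn_tau_min, p.hcn_tau_amp, p.hcn_tau_v0, p.hcn_tau_sig);
  s.r += (xinf(v, p.hcn_half, p.hcn_k) - s.r) * (1.0 - std::exp(-dt / tr));
}

// Instantaneous conductances; writes g_tot and sum(g_i * E_i).
inline void conductances(const State& s, const Pars& p,
                         double& gtot, double& gesum) {
  const double gna_t = p.gna * s.m * s.m * s.m * s.h;
  const double gk_t = p.gk * s.n * s.n * s.n * s.n;
  const double gh_t = p.gh * s.r;
  const double gnap_t = p.gnap * xinf(s.v, p.nap_half, p.nap_k);
  gtot = p.gl + gna_t + gk_t + gh_t + gnap_t;
  gesum = p.gl * p.el + gna_t * p.ena + gk_t * p.ek + gh_t * p.eh + gnap_t * p.ena;
}

inline void init_gates(State& s, const Pars& p) {
  s.m = xinf(s.v, p.nam_half, p.nam_k);
  s.h = xinf(s.v, p.nah_half, p.nah_k);
  s.n = xinf(s.v, p.kn_half, p.kn_k);
  s.r = xinf(s.v, p.hcn_half, p.hcn_k);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sim_current_clamp")]]
NumericVector sim_current_clamp(NumericVector pars, NumericVector stim,
                                double dt, int record_every,
                                double settle_ms, double v0) {
  const Pars p = read_pars(pars);
  const R_xlen_t nt = stim.size();
  const R_xlen_t nrec = (nt + record_every - 1) / record_every;
  NumericVector out(nrec);

  State s;
  s.v = v0;
  init_gates(s, p);

  // settle to rest (or baseline-holding state) before the protocol
  const double i0 = nt > 0 ? stim[0] : 0.0;
  const R_xlen_t nsettle = (R_xlen_t)std::ceil(settle_ms / dt);
  for (R_xlen_t i = 0; i < nsettle; ++i) {
    step_gates(s, p, dt);
    double gtot, gesum;
    conductances(s, p, gtot, gesum);
    const double vinf = (gesum + i0) / gtot;
    s.v = vinf + (s.v - vinf) * std::exp(-dt * gtot / p.cm);
  }
  if (!std::isfinite(s.v))
    stop("integration failure during settling (non-finite membrane potential)");

  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i < nt; ++i) {
    if (i % record_every == 0) out[k++] = s.v;
    step_gates(s, p, dt);
    double gtot, gesum;
    conductances(s, p, gtot, gesum);
    const double vinf = (gesum + stim[i]) / gtot;
    s.v = vinf + (s.v - vinf) * std::exp(-dt * gtot / p.cm);
    if (!std::isfinite(s.v))
      stop("integration failure at t = %.4f ms (non-finite membrane potential)",
           (double)(i + 1) * dt);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sim_voltage_clamp")]]
NumericVector sim_voltage_clamp(NumericVector pars, NumericVector command,
                                double dt, int record_every,
                                double settle_ms) {
  const Pars p = read_pars(pars);
  const R_xlen_t nt = command.size();
  const R_xlen_t nrec = (nt + record_every - 1) / record_every;
  NumericVector out(nrec);

  State s;
  s.v = nt > 0 ? command[0] : -60.0;
  init_gates(s, p);

  // equilibrate gates at the holding potential
  const R_xlen_t nsettle = (R_xlen_t)std::ceil(settle_ms / dt);
  for (R_xlen_t i = 0; i < nsettle; ++i) step_gates(s, p, dt);

  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i < nt; ++i) {
    s.v = command[i];  // ideal clamp: membrane potential follows the command
    if (i % record_every == 0) {
      double gtot, gesum;
      conductances(s, p, gtot, gesum);
      // membrane (ionic) current the amplifier must supply
      out[k++] = gtot * s.v - gesum;
    }
    step_gates(s, p, dt);
    if (!std::isfinite(s.r))
      stop("integration failure at t = %.4f ms (non-finite gating state)",
           (double)(i + 1) * dt);
  }
  return out;
}
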