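#include <Rcpp.h>
#include "crn_core.h"
using namespace Rcpp;

static const char *PAR_NAMES[] = {"gNa", "gK1",  "gto",  "gKur", "gKr",
                                  "gKs", "gCaL", "gbCa", "gbNa", "INaKmax",
                                  "INaCamax", "IpCamax", "gKACh", "ACh",
                                  "Ko",  "Nao",  "Cao"};
static const int NPAR = 17;

crn::Params params_from_r(const NumericVector &pv) {
  if (pv.size() != NPAR)
    stop("parameter vector must have %d entries", NPAR);
  crn::Params p;
  p.gNa = pv[0]; p.gK1 = pv[1]; p.gto = pv[2]; p.gKur = pv[3];
  p.gKr = pv[4]; p.gKs = pv[5]; p.gCaL = pv[6]; p.gbCa = pv[7];
  p.gbNa = pv[8]; p.INaKmax = pv[9]; p.INaCamax = pv[10]; p.IpCamax = pv[11];
  p.gKACh = pv[12]; p.ACh = pv[13]; p.Ko = pv[14]; p.Nao = pv[15];
  p.Cao = pv[16];
  crn::derive(p);
  return p;
}

// [[Rcpp::export]]
NumericVector crn_default_params_cpp() {
  crn::Params p = crn::default_params();
  NumericVector pv = NumericVector::create(
      p.gNa, p.gK1, p.gto, p.gKur, p.gKr, p.gKs, p.gCaL, p.gbCa, p.gbNa,
      p.INaKmax, p.INaCamax, p.IpCamax, p.gKACh, p.ACh, p.Ko, p.Nao, p.Cao);
  pv.attr("names") = CharacterVector(PAR_NAMES, PAR_NAMES + NPAR);
  return pv;
}

// [[Rcpp::export]]
NumericVector crn_default_state_cpp() {
  NumericVector s(crn::NSTATE);
  crn::default_state(REAL(s));
  return s;
}

// [[Rcpp::export]]
NumericVector crn_currents_cpp(NumericVector state, NumericVector params) {
  if (state.size() != crn::NSTATE) stop("state must have 21 entries");
  for (int i = 0; i < crn::NSTATE; ++i)
    if (!R_finite(state[i]))
      stop("non-finite state variable at position %d", i + 1);
  crn::Params p = params_from_r(params);
  double r[crn::NR], e[3];
  crn::vrates(state[0], r);
  crn::nernst(REAL(state), p, e);
  crn::Currents c;
  crn::currents(REAL(state), p, r, e, c);
  NumericVector out = NumericVector::create(
      _["INa"] = c.INa, _["IK1"] = c.IK1, _["Ito"] = c.Ito, _["IKur"] = c.IKur,
      _["IKr"] = c.IKr, _["IKs"] = c.IKs, _["ICaL"] = c.ICaL,
      _["IpCa"] = c.IpCa, _["INaK"] = c.INaK, _["INaCa"] = c.INaCa,
      _["IbNa"] = c.IbNa, _["IbCa"] = c.IbCa, _["IKACh"] = c.IKACh,
      _["Itot"] = c.Itot, _["EK"] = c.EK, _["ENa"] = c.ENa, _["ECa"] = c.ECa);
  return out;
}

// Single-cell integrator.  Stimuli: square pulses of amplitude stim_amp
// (pA/pF, depolarizing) and duration stim_dur starting at stim_times.
// Records (t, Vm) every record_every steps (>=1).
// [[Rcpp::export]]
List crn_run_cpp(NumericVector state, NumericVector params, double dt,
                 double duration, NumericVector stim_times, double stim_amp,
                 double stim_dur, int record_every, double t0,
                 bool use_tables) {
  if (dt <= 0) stop("dt must be positive");
  crn::Params p = params_from_r(params);
  double s[crn::NSTATE];
  for (int i = 0; i < crn::NSTATE; ++i) s[i] = state[i];

  long nsteps = (long)std::ceil(duration / dt - 1e-9);
  long nrec = nsteps / record_every + 2;  // in-loop samples + final state
  NumericVector tr_t(nrec), tr_v(nrec);

  crn::RateTable tab;
  if (use_tables) tab.build(dt);
  double r[crn::NR], e[3];
  crn::StepConsts sc;
  sc.set(dt);
  crn::nernst(s, p, e);

  int next_stim = 0;
  long irec = 0;
  for (long k = 0; k < nsteps; ++k) {
    double t = t0 + k * dt;
    if (k % crn::NERNST_EVERY == 0) crn::nernst(s, p, e);
    if (k % record_every == 0) { tr_t[irec] = t; tr_v[irec] = s[0]; ++irec; }
    double istim = 0.0;
    while (next_stim < stim_times.size() &&
           t >= stim_times[next_stim] + stim_dur - 1e-9)
      ++next_stim;
    if (next_stim < stim_times.size() && t >= stim_times[next_stim] - 1e-9 &&
        t < stim_times[next_stim] + stim_dur - 1e-9)
      istim = stim_amp;

    if (use_tables) tab.lookup(s[0], r); else crn::vrates(s[0], r);
    crn::step(s, p, sc, istim, r, use_tables, e);

    if ((k & 511) == 0 || k == nsteps - 1) {
      if (!std::isfinite(s[0]))
        stop("non-finite membrane potential at t = %.3f ms", t + dt);
    }
  }
  double tend = t0 + nsteps * dt;
  tr_t[irec] = tend; tr_v[irec] = s[0]; ++irec;

  NumericVector fin(crn::NSTATE);
  for (int i = 0; i < crn::NSTATE; ++i) fin[i] = s[i];
  for (int i = 1; i < 16; ++i)
    if (fin[i] < -1e-9 || fin[i] > 1.0 + 1e-9)
      stop("gating variable %d left [0,1] (value %g)", i, (double)fin[i]);

  return List::create(_["state"] = fin, _["t_end"] = tend,
                      _["time"] = tr_t[Range(0, irec - 1)],
                      _["Vm"] = tr_v[Range(0, irec - 1)]);
}
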