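#ifndef ATRIABLOCK_CRN_CORE_H
#define ATRIABLOCK_CRN_CORE_H

// Courtemanche-Ramirez-Nattel (CRN) human atrial myocyte model, extended with
// the Kneller acetylcholine-activated inward rectifier (I_KACh).
// All sarcolemmal currents are expressed per unit capacitance (pA/pF).
// State layout (21 doubles):
//   0 Vm, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//   10 d, 11 f, 12 fca, 13 u, 14 v, 15 w,
//   16 Nai, 17 Ki, 18 Cai, 19 Caup, 20 Carel

#include <cmath>
#include <vector>

namespace crn {

const int NSTATE = 21;

// physical constants
const double Rgas = 8.3143;      // J/(K mol)
const double Temp = 310.0;       // K
const double Frdy = 96.4867;     // C/mmol
const double RTF  = Rgas * Temp / Frdy;  // mV
const double Cm   = 100.0;       // pF (used only where total currents enter Fn)

// cell geometry (um^3)
const double Vi   = 13668.0;
const double Vup  = 1109.52;
const double Vrel = 96.48;

// Ca handling
const double Krel    = 30.0;     // 1/ms
const double Iupmax  = 0.005;    // mM/ms
const double Kup     = 0.00092;  // mM
const double Caupmax = 15.0;     // mM
const double tautr   = 180.0;    // ms
const double taufca  = 2.0;      // ms
const double tauu    = 8.0;      // ms
const double Cmdnmax = 0.05, KmCmdn = 0.00238;
const double Trpnmax = 0.07, KmTrpn = 0.0005;
const double Csqnmax = 10.0, KmCsqn = 0.8;

// exchanger / pump constants
const double KmNai = 10.0, KmKo = 1.5;
const double KmNa = 87.5, KmCa = 1.38, ksat = 0.1, gma = 0.35;

struct Params {
  // maximal conductances / fluxes (per pF where applicable)
  double gNa, gK1, gto, gKur, gKr, gKs, gCaL, gbCa, gbNa;
  double INaKmax, INaCamax, IpCamax;
  double gKACh;    // dimensionless multiplier on the Kneller expression
  double ACh;      // uM
  double Ko, Nao, Cao;  // mM
  double achf;     // derived: 10/(1+9.13652/ACh^0.477811), 0 when ACh == 0
};

inline void derive(Params &p) {
  p.achf = (p.ACh > 0.0) ? 10.0 / (1.0 + 9.13652 / std::pow(p.ACh, 0.477811))
                         : 0.0;
}

inline Params default_params() {
  Params p;
  p.gNa = 7.8; p.gK1 = 0.09; p.gto = 0.1652; p.gKur = 1.0;
  p.gKr = 0.029411765; p.gKs = 0.12941176; p.gCaL = 0.12375;
  p.gbCa = 0.001131; p.gbNa = 0.0006744375;
  p.INaKmax = 0.59933874; p.INaCamax = 1600.0; p.IpCamax = 0.275;
  p.gKACh = 1.0; p.ACh = 0.0;
  p.Ko = 5.4; p.Nao = 140.0; p.Cao = 1.8;
  derive(p);
  return p;
}

// published CRN resting initial conditions
inline void default_state(double *s) {
  s[0] = -81.18;
  s[1] = 2.908e-3; s[2] = 9.649e-1; s[3] = 9.775e-1;
  s[4] = 3.043e-2; s[5] = 9.992e-1;
  s[6] = 4.966e-3; s[7] = 9.986e-1;
  s[8] = 3.296e-5; s[9] = 1.869e-2;
  s[10] = 1.367e-4; s[11] = 9.996e-1; s[12] = 7.755e-1;
  s[13] = 0.0; s[14] = 1.0; s[15] = 9.992e-1;
  s[16] = 11.17; s[17] = 139.0; s[18] = 1.013e-4;
  s[19] = 1.488; s[20] = 1.488;
}

// ---- voltage-dependent rate/aux pack --------------------------------------
// layout: for each of 12 V-gates (m h j oa oi ua ui xr xs d f w):
//   [2g] = steady state, [2g+1] = time constant (or Rush-Larsen factor in a
//   baked table); then 7 auxiliaries.
const int NR = 31;
const int IX_K1R = 24;    // 1/(1+exp(0.07(V+80)))
const int IX_GKUR = 25;   // voltage-dependent gKur (nS/pF)
const int IX_KRR = 26;    // IKr inward rectification factor
const int IX_FNAK = 27;
const int IX_ENACA1 = 28; // exp(gma F V / RT)
const int IX_ENACA2 = 29; // exp((gma-1) F V / RT)
const int IX_KACHV = 30;  // 0.0517 + 0.4516/(1+exp((V+59.53)/17.18))

inline double safediv(double num, double den, double lim) {
  return (std::fabs(den) < 1e-10) ? lim : num / den;
}

inline void vrates(double V, double *r) {
  const double KQ10 = 3.0;
  double a, b;

  // m (Luo-Rudy fast Na kinetics as used by CRN)
  a = (std::fabs(V + 47.13) < 1e-10)
        ? 3.2
        : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  r[0] = a / (a + b); r[1] = 1.0 / (a + b);

  // h
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  }
  r[2] = a / (a + b); r[3] = 1.0 / (a + b);

  // j
  if (V >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  r[4] = a / (a + b); r[5] = 1.0 / (a + b);

  // oa, oi (Ito)
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r[7] = 1.0 / ((a + b) * KQ10);
  r[6] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  double a2 = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double b2 = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  r[9] = 1.0 / ((a2 + b2) * KQ10);
  r[8] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));

  // ua, ui (IKur) -- ua shares alpha/beta forms with oa
  r[11] = r[7];
  r[10] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  a2 = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b2 = std::exp((V - 158.0) / 16.0);
  r[13] = 1.0 / ((a2 + b2) * KQ10);
  r[12] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));

  // xr
  a = safediv(0.0003 * (V + 14.1), 1.0 - std::exp(-(V + 14.1) / 5.0),
              0.0003 * 5.0);
  b = safediv(7.3898e-5 * (V - 3.3328), std::exp((V - 3.3328) / 5.1237) - 1.0,
              7.3898e-5 * 5.1237);
  r[15] = 1.0 / (a + b);
  r[14] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));

  // xs
  a = safediv(4e-5 * (V - 19.9), 1.0 - std::exp(-(V - 19.9) / 17.0), 4e-5 * 17.0);
  b = safediv(3.5e-5 * (V - 19.9), std::exp((V - 19.9) / 9.0) - 1.0, 3.5e-5 * 9.0);
  r[17] = 0.5 / (a + b);
  r[16] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));

  // d
  r[18] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  {
    double e = std::exp(-(V + 10.0) / 6.24);
    r[19] = (std::fabs(V + 10.0) < 1e-10)
              ? 1.0 / (0.035 * 6.24 * 2.0)
              : (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }

  // f
  r[20] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  {
    double z = 0.0337 * (V + 10.0);
    r[21] = 9.0 / (0.0197 * std::exp(-z * z) + 0.02);
  }

  // w
  r[22] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  {
    double e = std::exp(-(V - 7.9) / 5.0);
    r[23] = (std::fabs(V - 7.9) < 1e-10)
              ? 6.0 * 0.2 / 1.3
              : 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }

  // auxiliaries
  r[IX_K1R]  = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
  r[IX_GKUR] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  r[IX_KRR]  = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
  {
    double sig = (std::exp(140.0 / 67.3) - 1.0) / 7.0;  // Nao = 140 convention
    r[IX_FNAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                        0.0365 * sig * std::exp(-V / RTF));
  }
  r[IX_ENACA1] = std::exp(gma * V / RTF);
  r[IX_ENACA2] = std::exp((gma - 1.0) * V / RTF);
  r[IX_KACHV]  = 0.0517 + 0.4516 / (1.0 + std::exp((V + 59.53) / 17.18));
}

// baked lookup table: taus replaced by Rush-Larsen factors exp(-dt/tau)
struct RateTable {
  double Vmin, Vmax, dV, inv_dV, dt;
  int n;
  std::vector<double> tab;  // n * NR
  void build(double dt_) {
    dt = dt_; Vmin = -120.0; Vmax = 80.0; dV = 0.05;
    inv_dV = 1.0 / dV;
    n = (int)((Vmax - Vmin) / dV) + 1;
    tab.assign((size_t)n * NR, 0.0);
    double r[NR];
    for (int i = 0; i < n; ++i) {
      vrates(Vmin + i * dV, r);
      for (int g = 0; g < 12; ++g) r[2 * g + 1] = std::exp(-dt / r[2 * g + 1]);
      for (int k = 0; k < NR; ++k) tab[(size_t)i * NR + k] = r[k];
    }
  }
  inline void lookup(double V, double *r) const {
    double x = (V - Vmin) * inv_dV;
    if (x < 0.0) x = 0.0;
    if (x > n - 1.001) x = n - 1.001;
    int i = (int)x;
    double w = x - i;
    const double *a = &tab[(size_t)i * NR], *b = a + NR;
    for (int k = 0; k < NR; ++k) r[k] = a[k] + w * (b[k] - a[k]);
  }
};

// Nernst potentials drift with the slow concentration variables only, so the
// integrators refresh them every NERNST_EVERY steps (identical cadence in the
// single-cell and tissue paths, keeping the D = 0 decoupling limit exact).
const int NERNST_EVERY = 10;

struct Currents {
  double INa, IK1, Ito, IKur, IKr, IKs, ICaL, IpCa, INaK, INaCa, IbNa, IbCa,
      IKACh, Irel, Iup, Iupleak, Itr, EK, ENa, ECa, Itot;
};

inline void nernst(const double *s, const Params &p, double *e) {
  e[0] = RTF * std::log(p.Ko / s[17]);          // EK
  e[1] = RTF * std::log(p.Nao / s[16]);         // ENa
  e[2] = 0.5 * RTF * std::log(p.Cao / s[18]);   // ECa
}

// evaluate all currents at a state given a rate/aux pack for its Vm and the
// (possibly cached) Nernst potentials
inline void currents(const double *s, const Params &p, const double *r,
                     const double *e, Currents &c) {
  double V = s[0], Nai = s[16], Cai = s[18];
  c.EK = e[0]; c.ENa = e[1]; c.ECa = e[2];

  c.INa  = p.gNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - c.ENa);
  c.IK1  = p.gK1 * (V - c.EK) * r[IX_K1R];
  c.Ito  = p.gto * s[4] * s[4] * s[4] * s[5] * (V - c.EK);
  c.IKur = p.gKur * r[IX_GKUR] * s[6] * s[6] * s[6] * s[7] * (V - c.EK);
  c.IKr  = p.gKr * s[8] * (V - c.EK) * r[IX_KRR];
  c.IKs  = p.gKs * s[9] * s[9] * (V - c.EK);
  c.ICaL = p.gCaL * s[10] * s[11] * s[12] * (V - 65.0);
  c.IKACh = p.gKACh * p.achf * r[IX_KACHV] * (V - c.EK);

  {
    double q = KmNai / Nai;  // q^1.5 without pow()
    c.INaK = p.INaKmax * r[IX_FNAK] * (p.Ko / (p.Ko + KmKo)) /
             (1.0 + q * std::sqrt(q));
  }
  {
    double n3 = Nai * Nai * Nai, N3 = p.Nao * p.Nao * p.Nao;
    c.INaCa = p.INaCamax *
              (r[IX_ENACA1] * n3 * p.Cao - r[IX_ENACA2] * N3 * Cai) /
              ((KmNa * KmNa * KmNa + N3) * (KmCa + p.Cao) *
               (1.0 + ksat * r[IX_ENACA2]));
  }
  c.IbNa = p.gbNa * (V - c.ENa);
  c.IbCa = p.gbCa * (V - c.ECa);
  c.IpCa = p.IpCamax * Cai / (0.0005 + Cai);

  c.Irel = Krel * s[13] * s[13] * s[14] * s[15] * (s[20] - Cai);
  c.Iup = Iupmax / (1.0 + Kup / Cai);
  c.Iupleak = Iupmax * s[19] / Caupmax;
  c.Itr = (s[19] - s[20]) / tautr;

  c.Itot = c.INa + c.IK1 + c.Ito + c.IKur + c.IKr + c.IKs + c.ICaL + c.IpCa +
           c.INaK + c.INaCa + c.IbNa + c.IbCa + c.IKACh;
}

// dt-dependent constants shared by every step of a run
struct StepConsts {
  double dt, rl_fca, rl_u;
  void set(double dt_) {
    dt = dt_;
    rl_fca = std::exp(-dt_ / taufca);
    rl_u = std::exp(-dt_ / tauu);
  }
};

// one integration step: Rush-Larsen gates, forward Euler for Vm and
// concentrations.  `r` holds the rate pack for s[0]; if `baked`, tau slots
// already contain exp(-dt/tau).  `e` holds the Nernst potentials for s.
inline void step(double *s, const Params &p, const StepConsts &sc,
                 double istim, const double *r, bool baked, const double *e) {
  const double dt = sc.dt;
  Currents c;
  currents(s, p, r, e, c);

  // Ca release gating driven by Fn (total currents in pA)
  double Fn = 1e-12 * Vrel * c.Irel -
              (5e-13 / Frdy) * (0.5 * c.ICaL * Cm - 0.2 * c.INaCa * Cm);
  double uinf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 1.367e-15));
  double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 1.367e-15));
  double tauv = 1.91 + 2.09 * uinf;

  // V-dependent gates
  for (int g = 0; g < 12; ++g) {
    double inf = r[2 * g], rl = r[2 * g + 1];
    if (!baked) rl = std::exp(-dt / rl);
    int ix = (g < 9) ? (g + 1) : (g == 9 ? 10 : (g == 10 ? 11 : 15));
    s[ix] = inf + (s[ix] - inf) * rl;
  }
  // Ca-dependent gates
  double fcainf = 1.0 / (1.0 + s[18] / 0.00035);
  s[12] = fcainf + (s[12] - fcainf) * sc.rl_fca;
  s[13] = uinf + (s[13] - uinf) * sc.rl_u;
  s[14] = vinf + (s[14] - vinf) * std::exp(-dt / tauv);

  // concentrations (forward Euler)
  double dNai = (-3.0 * c.INaK - 3.0 * c.INaCa - c.IbNa - c.INa) * Cm /
                (Frdy * Vi);
  double dKi = (2.0 * c.INaK - c.IK1 - c.Ito - c.IKur - c.IKr - c.IKs -
                c.IKACh) * Cm / (Frdy * Vi);
  double B1 = (2.0 * c.INaCa - c.IpCa - c.ICaL - c.IbCa) * Cm /
                  (2.0 * Frdy * Vi) +
              (Vup * (c.Iupleak - c.Iup) + c.Irel * Vrel) / Vi;
  double cai = s[18];
  double B2 = 1.0 + Trpnmax * KmTrpn / ((cai + KmTrpn) * (cai + KmTrpn)) +
              Cmdnmax * KmCmdn / ((cai + KmCmdn) * (cai + KmCmdn));
  double dCaup = c.Iup - c.Iupleak - c.Itr * Vrel / Vup;
  double crel = s[20];
  double dCarel = (c.Itr - c.Irel) /
                  (1.0 + Csqnmax * KmCsqn / ((crel + KmCsqn) * (crel + KmCsqn)));

  s[16] += dt * dNai;
  s[17] += dt * dKi;
  s[18] += dt * B1 / B2;
  s[19] += dt * dCaup;
  s[20] += dt * dCarel;

  // membrane potential
  s[0] += dt * (-c.Itot + istim);
}

}  // namespace crn

#endif
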