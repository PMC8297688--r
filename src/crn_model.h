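// Courtemanche-Ramirez-Nattel (1998) human atrial ionic model.
// 15 gating variables, 5 intracellular concentrations, physical units:
// V in mV, time in ms, currents in pA/pF, concentrations in mM.
#ifndef ATRIALCV_CRN_MODEL_H
#define ATRIALCV_CRN_MODEL_H

#include <cmath>
#include <vector>

namespace crn {

// state layout
enum Gate { G_M = 0, G_H, G_J, G_OA, G_OI, G_UA, G_UI, G_XR, G_XS,
            G_D, G_F, G_FCA, G_U, G_V, G_W, N_GATES };
enum Conc { C_NAI = 0, C_KI, C_CAI, C_CAUP, C_CAREL, N_CONC };

struct Params {
  // maximal conductances (nS/pF) and current scales (pA/pF)
  double g_Na     = 7.8;
  double g_K1     = 0.09;
  double g_to     = 0.1652;
  double g_Kr     = 0.029411765;
  double g_Ks     = 0.12941176;
  double g_CaL    = 0.12375;
  double g_bCa    = 0.001131;
  double g_bNa    = 0.0006744375;
  double INaK_max = 0.59933874;
  double INaCa_max = 1600.0;
  double IpCa_max = 0.275;
  // extracellular concentrations (mM)
  double Ko  = 5.4;
  double Nao = 140.0;
  double Cao = 1.8;
  // cell geometry / physics
  double Cm   = 100.0;     // pF
  double Frd  = 96.4867;   // C/mmol
  double Rgas = 8.3143;    // J/(mol K)
  double Temp = 310.0;     // K
  double Vi   = 13668.0;   // um^3
  double Vup  = 1109.52;
  double Vrel = 96.48;
  // SR handling / buffers
  double k_rel    = 30.0;     // 1/ms
  double Iup_max  = 0.005;    // mM/ms
  double K_up     = 0.00092;  // mM
  double Caup_max = 15.0;     // mM
  double tau_tr   = 180.0;    // ms
  double tau_u    = 8.0;      // ms
  double tau_fca  = 2.0;      // ms
  double CMDN_max = 0.05, Km_CMDN = 0.00238;
  double TRPN_max = 0.07, Km_TRPN = 0.0005;
  double CSQN_max = 10.0, Km_CSQN = 0.8;
  // Na/K and Na/Ca exchanger kinetics
  double Km_Nai = 10.0, Km_Ko = 1.5;
  double Km_Na = 87.5, Km_Ca = 1.38, k_sat = 0.1, gamma = 0.35;
  double K_Q10 = 3.0;

  double RT_F() const { return Rgas * Temp / Frd; }
};

// remodeling scales applied to g_to, g_CaL, g_Kur (multiplicative, 1 = CRN)
struct Remodel {
  double s_to = 1.0, s_CaL = 1.0, s_Kur = 1.0;
};

struct Currents {
  double INa, IK1, Ito, IKur, IKr, IKs, ICaL, IpCa, INaK, INaCa, IbNa, IbCa;
  double Irel, Itr, Iup, Iupleak;
  double Iion;  // total membrane ionic current, pA/pF
};

// voltage-dependent gate kinetics: steady state and time constant.
// Removable singularities are evaluated by their analytic limit within
// a +/- 1e-6 mV guard band.
struct VRates {
  double inf[N_GATES];  // fca/u/v entries are unused (state-dependent)
  double tau[N_GATES];
  // voltage-only current factors
  double k1_den;     // 1 + exp(0.07 (V + 80))
  double g_kur;      // 0.005 + 0.05 / (1 + exp(-(V-15)/13))
  double kr_den;     // 1 + exp((V+15)/22.4)
  double f_nak;      // voltage factor of INaK
  double exp_gvfrt;  // exp(gamma V F / RT)
  double exp_gm1vfrt;
};

inline double safe_div(double num, double den, double lim, double x, double guard = 1e-6) {
  return (std::fabs(x) < guard) ? lim : num / den;
}

inline void voltage_rates(double V, const Params& p, VRates& r) {
  const double RT_F = p.RT_F();

  // m
  {
    double x = V + 47.13;
    double am = safe_div(0.32 * x, 1.0 - std::exp(-0.1 * x), 3.2, x);
    double bm = 0.08 * std::exp(-V / 11.0);
    r.tau[G_M] = 1.0 / (am + bm);
    r.inf[G_M] = am * r.tau[G_M];
  }
  // h, j (fast sodium inactivation, piecewise at V = -40 mV)
  {
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
      bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
      aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    r.tau[G_H] = 1.0 / (ah + bh);
    r.inf[G_H] = ah * r.tau[G_H];
    r.tau[G_J] = 1.0 / (aj + bj);
    r.inf[G_J] = aj * r.tau[G_J];
  }
  // oa, oi (transient outward)
  {
    double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
    double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
    r.tau[G_OA] = 1.0 / ((a + b) * p.K_Q10);
    r.inf[G_OA] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
    a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
    b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
    r.tau[G_OI] = 1.0 / ((a + b) * p.K_Q10);
    r.inf[G_OI] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  }
  // ua, ui (ultrarapid delayed rectifier)
  {
    double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
    double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
    r.tau[G_UA] = 1.0 / ((a + b) * p.K_Q10);
    r.inf[G_UA] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
    a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
    b = std::exp((V - 158.0) / 16.0);
    r.tau[G_UI] = 1.0 / ((a + b) * p.K_Q10);
    r.inf[G_UI] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  }
  // xr
  {
    double x = V + 14.1;
    double a = safe_div(0.0003 * x, 1.0 - std::exp(-x / 5.0), 0.0015, x);
    double y = V - 3.3328;
    double b = safe_div(7.3898e-5 * y, std::exp(y / 5.1237) - 1.0,
                        7.3898e-5 * 5.1237, y);
    r.tau[G_XR] = 1.0 / (a + b);
    r.inf[G_XR] = 1.0 / (1.0 + std::exp(-x / 6.5));
  }
  // xs
  {
    double x = V - 19.9;
    double a = safe_div(4e-5 * x, 1.0 - std::exp(-x / 17.0), 4e-5 * 17.0, x);
    double b = safe_div(3.5e-5 * x, std::exp(x / 9.0) - 1.0, 3.5e-5 * 9.0, x);
    r.tau[G_XS] = 0.5 / (a + b);
    r.inf[G_XS] = 1.0 / std::sqrt(1.0 + std::exp(-x / 12.7));
  }
  // d, f (L-type calcium)
  {
    double x = V + 10.0;
    double e = std::exp(-x / 6.24);
    r.tau[G_D] = safe_div(1.0 - e, 0.035 * x * (1.0 + e),
                          1.0 / (0.035 * 6.24 * 2.0), x);
    r.inf[G_D] = 1.0 / (1.0 + std::exp(-x / 8.0));
    r.tau[G_F] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * x * x) + 0.02);
    r.inf[G_F] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  }
  // fca (tau only; inf depends on Cai)
  r.tau[G_FCA] = p.tau_fca;
  // u, v: set by fn_rates() (depend on SR flux); w is voltage-only
  r.tau[G_U] = p.tau_u;
  {
    double x = V - 7.9;
    double e = std::exp(-x / 5.0);
    r.tau[G_W] = safe_div(6.0 * (1.0 - e), (1.0 + 0.3 * e) * x,
                          6.0 / (5.0 * 1.3), x);
    r.inf[G_W] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  }

  r.k1_den = 1.0 + std::exp(0.07 * (V + 80.0));
  r.g_kur  = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  r.kr_den = 1.0 + std::exp((V + 15.0) / 22.4);
  {
    double sigma = (std::exp(p.Nao / 67.3) - 1.0) / 7.0;
    r.f_nak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RT_F) +
                     0.0365 * sigma * std::exp(-V / RT_F));
  }
  r.exp_gvfrt   = std::exp(p.gamma * V / RT_F);
  r.exp_gm1vfrt = std::exp((p.gamma - 1.0) * V / RT_F);
}

// Membrane + SR currents from V-dependent factors plus state.
inline void currents(double V, const double* w, const double* c,
                     const Params& p, const Remodel& rm, const VRates& r,
                     Currents& I) {
  const double RT_F = p.RT_F();
  double ENa = RT_F * std::log(p.Nao / c[C_NAI]);
  double EK  = RT_F * std::log(p.Ko / c[C_KI]);
  double ECa = 0.5 * RT_F * std::log(p.Cao / c[C_CAI]);

  I.INa  = p.g_Na * w[G_M] * w[G_M] * w[G_M] * w[G_H] * w[G_J] * (V - ENa);
  I.IK1  = p.g_K1 * (V - EK) / r.k1_den;
  I.Ito  = rm.s_to * p.g_to * w[G_OA] * w[G_OA] * w[G_OA] * w[G_OI] * (V - EK);
  I.IKur = rm.s_Kur * r.g_kur * w[G_UA] * w[G_UA] * w[G_UA] * w[G_UI] * (V - EK);
  I.IKr  = p.g_Kr * w[G_XR] * (V - EK) / r.kr_den;
  I.IKs  = p.g_Ks * w[G_XS] * w[G_XS] * (V - EK);
  I.ICaL = rm.s_CaL * p.g_CaL * w[G_D] * w[G_F] * w[G_FCA] * (V - 65.0);
  I.IpCa = p.IpCa_max * c[C_CAI] / (0.0005 + c[C_CAI]);
  {
    double x = p.Km_Nai / c[C_NAI];  // x^1.5 = x sqrt(x)
    I.INaK = p.INaK_max * r.f_nak / (1.0 + x * std::sqrt(x)) *
             p.Ko / (p.Ko + p.Km_Ko);
  }
  {
    double na3 = c[C_NAI] * c[C_NAI] * c[C_NAI];
    double nao3 = p.Nao * p.Nao * p.Nao;
    I.INaCa = p.INaCa_max *
              (r.exp_gvfrt * na3 * p.Cao - r.exp_gm1vfrt * nao3 * c[C_CAI]) /
              ((p.Km_Na * p.Km_Na * p.Km_Na + nao3) * (p.Km_Ca + p.Cao) *
               (1.0 + p.k_sat * r.exp_gm1vfrt));
  }
  I.IbNa = p.g_bNa * (V - ENa);
  I.IbCa = p.g_bCa * (V - ECa);

  I.Irel = p.k_rel * w[G_U] * w[G_U] * w[G_V] * w[G_W] * (c[C_CAREL] - c[C_CAI]);
  I.Itr  = (c[C_CAUP] - c[C_CAREL]) / p.tau_tr;
  I.Iup  = p.Iup_max / (1.0 + p.K_up / c[C_CAI]);
  I.Iupleak = p.Iup_max * c[C_CAUP] / p.Caup_max;

  I.Iion = I.INa + I.IK1 + I.Ito + I.IKur + I.IKr + I.IKs + I.ICaL +
           I.IpCa + I.INaK + I.INaCa + I.IbNa + I.IbCa;
}

// SR release-gate targets driven by Fn (Courtemanche Eq. for u, v gates).
inline void fn_rates(const Params& p, const Currents& I,
                     double& u_inf, double& v_inf, double& tau_v) {
  // currents in pA (pA/pF scaled by Cm)
  double Fn = 1e-12 * p.Vrel * I.Irel -
              (5e-13 / p.Frd) * (0.5 * I.ICaL - 0.2 * I.INaCa) * p.Cm;
  u_inf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 1.367e-15));
  tau_v = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 1.367e-15));
  v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 1.367e-15));
}

// Full right-hand side: H (gate derivatives), G (concentration derivatives)
// and the total ionic current.
inline void rhs(double V, const double* w, const double* c,
                const Params& p, const Remodel& rm,
                double* dw, double* dc, Currents& I) {
  VRates r;
  voltage_rates(V, p, r);
  currents(V, w, c, p, rm, r, I);

  double u_inf, v_inf, tau_v;
  fn_rates(p, I, u_inf, v_inf, tau_v);
  double fca_inf = 1.0 / (1.0 + c[C_CAI] / 0.00035);

  for (int g = 0; g < N_GATES; ++g) {
    double inf = r.inf[g], tau = r.tau[g];
    if (g == G_FCA) inf = fca_inf;
    else if (g == G_U) inf = u_inf;
    else if (g == G_V) { inf = v_inf; tau = tau_v; }
    dw[g] = (inf - w[g]) / tau;
  }

  double FVi = p.Frd * p.Vi;
  dc[C_NAI] = (-3.0 * I.INaK - 3.0 * I.INaCa - I.IbNa - I.INa) * p.Cm / FVi;
  dc[C_KI]  = (2.0 * I.INaK - I.IK1 - I.Ito - I.IKur - I.IKr - I.IKs) * p.Cm / FVi;
  {
    double B1 = (2.0 * I.INaCa - I.IpCa - I.ICaL - I.IbCa) * p.Cm /
                    (2.0 * FVi) +
                (p.Vup * (I.Iupleak - I.Iup) + I.Irel * p.Vrel) / p.Vi;
    double t1 = c[C_CAI] + p.Km_TRPN;
    double t2 = c[C_CAI] + p.Km_CMDN;
    double B2 = 1.0 + p.TRPN_max * p.Km_TRPN / (t1 * t1) +
                p.CMDN_max * p.Km_CMDN / (t2 * t2);
    dc[C_CAI] = B1 / B2;
  }
  dc[C_CAUP]  = I.Iup - I.Iupleak - I.Itr * p.Vrel / p.Vup;
  {
    double t = c[C_CAREL] + p.Km_CSQN;
    dc[C_CAREL] = (I.Itr - I.Irel) /
                  (1.0 + p.CSQN_max * p.Km_CSQN / (t * t));
  }
}

// Published CRN initial (resting) state.
inline void initial_state(double& V, double* w, double* c) {
  V = -81.18;
  w[G_M] = 2.908e-3;  w[G_H] = 0.9649;   w[G_J] = 0.9775;
  w[G_OA] = 3.043e-2; w[G_OI] = 0.9992;
  w[G_UA] = 4.966e-3; w[G_UI] = 0.9986;
  w[G_XR] = 3.296e-5; w[G_XS] = 1.869e-2;
  w[G_D] = 1.367e-4;  w[G_F] = 0.9996;   w[G_FCA] = 0.7755;
  w[G_U] = 0.0;       w[G_V] = 1.0;      w[G_W] = 0.9992;
  c[C_NAI] = 11.17;  c[C_KI] = 139.0; c[C_CAI] = 1.013e-4;
  c[C_CAUP] = 1.488; c[C_CAREL] = 1.488;
}

// ---------------------------------------------------------------------------
// Voltage lookup tables (tissue-scale runs): piecewise-linear interpolation of
// every voltage-only quantity on a uniform grid. Out-of-range V falls back to
// direct evaluation.
struct VTable {
  double vmin = -120.0, vmax = 80.0, dv = 0.05;
  int n = 0;
  // per entry: inf[12 used], tau[12 used], 6 current factors
  std::vector<double> data;  // n x stride
  static const int STRIDE = 2 * N_GATES + 6;

  void build(const Params& p) {
    n = static_cast<int>((vmax - vmin) / dv) + 2;
    data.assign(static_cast<size_t>(n) * STRIDE, 0.0);
    VRates r;
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      voltage_rates(V, p, r);
      double* row = &data[static_cast<size_t>(i) * STRIDE];
      for (int g = 0; g < N_GATES; ++g) { row[g] = r.inf[g]; row[N_GATES + g] = r.tau[g]; }
      row[2 * N_GATES + 0] = r.k1_den;
      row[2 * N_GATES + 1] = r.g_kur;
      row[2 * N_GATES + 2] = r.kr_den;
      row[2 * N_GATES + 3] = r.f_nak;
      row[2 * N_GATES + 4] = r.exp_gvfrt;
      row[2 * N_GATES + 5] = r.exp_gm1vfrt;
    }
  }

  // interpolate only the 6 voltage-only current factors (hot SVI path)
  void lookup_factors(double V, const Params& p, VRates& r) const {
    if (V < vmin || V > vmax - dv) { voltage_rates(V, p, r); return; }
    double s = (V - vmin) / dv;
    int i = static_cast<int>(s);
    double a = s - i;
    const double* r0 = &data[static_cast<size_t>(i) * STRIDE + 2 * N_GATES];
    const double* r1 = r0 + STRIDE;
    r.k1_den      = r0[0] + a * (r1[0] - r0[0]);
    r.g_kur       = r0[1] + a * (r1[1] - r0[1]);
    r.kr_den      = r0[2] + a * (r1[2] - r0[2]);
    r.f_nak       = r0[3] + a * (r1[3] - r0[3]);
    r.exp_gvfrt   = r0[4] + a * (r1[4] - r0[4]);
    r.exp_gm1vfrt = r0[5] + a * (r1[5] - r0[5]);
  }

  bool lookup(double V, const Params& p, VRates& r) const {
    if (V < vmin || V > vmax - dv) { voltage_rates(V, p, r); return false; }
    double s = (V - vmin) / dv;
    int i = static_cast<int>(s);
    double a = s - i;
    const double* r0 = &data[static_cast<size_t>(i) * STRIDE];
    const double* r1 = r0 + STRIDE;
    for (int g = 0; g < N_GATES; ++g) {
      r.inf[g] = r0[g] + a * (r1[g] - r0[g]);
      r.tau[g] = r0[N_GATES + g] + a * (r1[N_GATES + g] - r0[N_GATES + g]);
    }
    const int o = 2 * N_GATES;
    r.k1_den      = r0[o + 0] + a * (r1[o + 0] - r0[o + 0]);
    r.g_kur       = r0[o + 1] + a * (r1[o + 1] - r0[o + 1]);
    r.kr_den      = r0[o + 2] + a * (r1[o + 2] - r0[o + 2]);
    r.f_nak       = r0[o + 3] + a * (r1[o + 3] - r0[o + 3]);
    r.exp_gvfrt   = r0[o + 4] + a * (r1[o + 4] - r0[o + 4]);
    r.exp_gm1vfrt = r0[o + 5] + a * (r1[o + 5] - r0[o + 5]);
    return true;
  }
};

}  // namespace crn

#endif
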