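// Cell-level interface to the CRN model: right-hand side evaluation and a
// paced single-cell integrator using the same BDF(1-3) family with segregated
// extrapolated coupling as the tissue solver.
#include <Rcpp.h>
#include "crn_model.h"

using namespace Rcpp;

static crn::Remodel as_remodel(NumericVector scales) {
  crn::Remodel rm;
  rm.s_to  = scales[0];
  rm.s_CaL = scales[1];
  rm.s_Kur = scales[2];
  return rm;
}

// [[Rcpp::export]]
List crn_rhs_cpp(double V, NumericVector gates, NumericVector conc,
                 NumericVector scales) {
  if (!R_finite(V)) stop("non-finite transmembrane potential");
  for (double g : gates) if (!R_finite(g)) stop("non-finite gating variable");
  for (double c : conc) if (!R_finite(c)) stop("non-finite concentration");
  crn::Params p;
  crn::Remodel rm = as_remodel(scales);
  double dw[crn::N_GATES], dc[crn::N_CONC];
  crn::Currents I;
  crn::rhs(V, gates.begin(), conc.begin(), p, rm, dw, dc, I);
  return List::create(
      _["iion"] = I.Iion,
      _["dgates"] = NumericVector(dw, dw + crn::N_GATES),
      _["dconc"] = NumericVector(dc, dc + crn::N_CONC),
      _["currents"] = NumericVector::create(
          _["I_Na"] = I.INa, _["I_K1"] = I.IK1, _["I_to"] = I.Ito,
          _["I_Kur"] = I.IKur, _["I_Kr"] = I.IKr, _["I_Ks"] = I.IKs,
          _["I_CaL"] = I.ICaL, _["I_pCa"] = I.IpCa, _["I_NaK"] = I.INaK,
          _["I_NaCa"] = I.INaCa, _["I_bNa"] = I.IbNa, _["I_bCa"] = I.IbCa,
          _["I_rel"] = I.Irel, _["I_tr"] = I.Itr, _["I_up"] = I.Iup,
          _["I_upleak"] = I.Iupleak));
}

// [[Rcpp::export]]
List crn_initial_state_cpp() {
  double V, w[crn::N_GATES], c[crn::N_CONC];
  crn::initial_state(V, w, c);
  return List::create(_["v"] = V,
                      _["gates"] = NumericVector(w, w + crn::N_GATES),
                      _["conc"] = NumericVector(c, c + crn::N_CONC));
}

// Paced single cell. Stimulus: rectangular pulses of `amp` (pA/pF, i.e.
// mV/ms) and `dur` ms at the start of each cycle. Returns the full trace.
// [[Rcpp::export]]
List cell_pace_cpp(double cycle_length, int n_beats, double amp, double dur,
                   double dt, NumericVector scales, int bdf_order,
                   NumericVector init_v, NumericVector init_gates,
                   NumericVector init_conc, bool record_currents) {
  crn::Params p;
  crn::Remodel rm = as_remodel(scales);

  double V, w[crn::N_GATES], c[crn::N_CONC];
  if (init_v.size() == 1 && init_gates.size() == crn::N_GATES) {
    V = init_v[0];
    for (int g = 0; g < crn::N_GATES; ++g) w[g] = init_gates[g];
    for (int k = 0; k < crn::N_CONC; ++k) c[k] = init_conc[k];
  } else {
    crn::initial_state(V, w, c);
  }

  const int n_steps = static_cast<int>(std::ceil(cycle_length * n_beats / dt));
  NumericVector t_out(n_steps + 1), v_out(n_steps + 1);
  NumericMatrix cur_out = record_currents ? NumericMatrix(n_steps + 1, 12)
                                          : NumericMatrix(1, 1);
  t_out[0] = 0.0;
  v_out[0] = V;

  // histories (index 0 = newest)
  double Vh[3] = {V, V, V};
  double wh[3][crn::N_GATES], ch[3][crn::N_CONC];
  for (int k = 0; k < 3; ++k) {
    for (int g = 0; g < crn::N_GATES; ++g) wh[k][g] = w[g];
    for (int j = 0; j < crn::N_CONC; ++j) ch[k][j] = c[j];
  }

  const double alphas[3] = {1.0, 1.5, 11.0 / 6.0};
  const double bdfw[3][3] = {{1, 0, 0}, {2, -0.5, 0}, {3, -1.5, 1.0 / 3.0}};
  const double extw[3][3] = {{1, 0, 0}, {2, -1, 0}, {3, -3, 1}};

  crn::Currents I;
  double dw[crn::N_GATES], dc[crn::N_CONC];

  for (int n = 0; n < n_steps; ++n) {
    int ord = std::min(bdf_order, std::min(n + 1, 3));
    const double a = alphas[ord - 1];
    const double* bw = bdfw[ord - 1];
    const double* ew = extw[ord - 1];

    double V_bdf = 0, V_ext = 0;
    double w_bdf[crn::N_GATES], w_ext[crn::N_GATES];
    double c_bdf[crn::N_CONC], c_ext[crn::N_CONC];
    for (int g = 0; g < crn::N_GATES; ++g) { w_bdf[g] = 0; w_ext[g] = 0; }
    for (int j = 0; j < crn::N_CONC; ++j) { c_bdf[j] = 0; c_ext[j] = 0; }
    for (int k = 0; k < ord; ++k) {
      V_bdf += bw[k] * Vh[k];
      V_ext += ew[k] * Vh[k];
      for (int g = 0; g < crn::N_GATES; ++g) {
        w_bdf[g] += bw[k] * wh[k][g];
        w_ext[g] += ew[k] * wh[k][g];
      }
      for (int j = 0; j < crn::N_CONC; ++j) {
        c_bdf[j] += bw[k] * ch[k][j];
        c_ext[j] += ew[k] * ch[k][j];
      }
    }

    // segregated ionic advance at extrapolated states; the gate equations
    // are linear in the gate itself, so the BDF update is resolved
    // implicitly in closed form (voltage and cross-state terms extrapolated)
    crn::rhs(V_ext, w_ext, c_ext, p, rm, dw, dc, I);
    crn::VRates r;
    crn::voltage_rates(V_ext, p, r);
    double u_inf, v_inf, tau_v;
    crn::fn_rates(p, I, u_inf, v_inf, tau_v);
    double fca_inf = 1.0 / (1.0 + c_ext[crn::C_CAI] / 0.00035);
    double w_new[crn::N_GATES], c_new[crn::N_CONC];
    for (int g = 0; g < crn::N_GATES; ++g) {
      double inf = r.inf[g], tau = r.tau[g];
      if (g == crn::G_FCA) inf = fca_inf;
      else if (g == crn::G_U) inf = u_inf;
      else if (g == crn::G_V) { inf = v_inf; tau = tau_v; }
      double rt = dt / tau;
      double wn = (w_bdf[g] + rt * inf) / (a + rt);
      w_new[g] = std::min(1.0, std::max(0.0, wn));
    }
    for (int j = 0; j < crn::N_CONC; ++j) {
      c_new[j] = (c_bdf[j] + dt * dc[j]) / a;
      if (c_new[j] < 1e-10) c_new[j] = 1e-10;
    }

    // membrane update: a V^{n+1} = V_bdf + dt (-Iion(V_ext, w^{n+1}, c^{n+1}) + Istim)
    crn::currents(V_ext, w_new, c_new, p, rm, r, I);

    double t_new = (n + 1) * dt;
    double phase = t_new - std::floor(t_new / cycle_length) * cycle_length;
    double Istim = (phase <= dur && t_new <= cycle_length * n_beats) ? amp : 0.0;
    // pulse of beat k spans [k*CL, k*CL + dur]
    double V_new = (V_bdf + dt * (-I.Iion + Istim)) / a;

    if (!R_finite(V_new))
      stop("cell integration diverged at t = %f ms", t_new);

    // shift histories
    Vh[2] = Vh[1]; Vh[1] = Vh[0]; Vh[0] = V_new;
    for (int g = 0; g < crn::N_GATES; ++g) {
      wh[2][g] = wh[1][g]; wh[1][g] = wh[0][g]; wh[0][g] = w_new[g];
    }
    for (int j = 0; j < crn::N_CONC; ++j) {
      ch[2][j] = ch[1][j]; ch[1][j] = ch[0][j]; ch[0][j] = c_new[j];
    }

    t_out[n + 1] = t_new;
    v_out[n + 1] = V_new;
    if (record_currents) {
      double cur[12] = {I.INa, I.IK1, I.Ito, I.IKur, I.IKr, I.IKs,
                        I.ICaL, I.IpCa, I.INaK, I.INaCa, I.IbNa, I.IbCa};
      for (int q = 0; q < 12; ++q) cur_out(n + 1, q) = cur[q];
    }
  }

  NumericVector gates_f(crn::N_GATES), conc_f(crn::N_CONC);
  for (int g = 0; g < crn::N_GATES; ++g) gates_f[g] = wh[0][g];
  for (int j = 0; j < crn::N_CONC; ++j) conc_f[j] = ch[0][j];

  List out = List::create(_["t_ms"] = t_out, _["v_mv"] = v_out,
                          _["gates"] = gates_f, _["conc"] = conc_f);
  if (record_currents) out["currents"] = cur_out;
  return out;
}
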