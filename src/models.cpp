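// ODE right-hand sides for the three ERK-cascade archetypes, compiled for
// speed: SMC calibration evaluates the likelihood (one or more ODE solves)
// ~1e5 times per fit.  Each model is exposed twice:
//   * deSolve-compatible entry points (initmod / derivs_* / root_*) so that
//     deSolve::lsoda()/lsodar() integrate without R-level callbacks;
//   * an Rcpp wrapper rhs_eval_cpp() so R code (Newton refinement,
//     conservation checks) can evaluate f(x, theta) directly.
//
// Units: concentrations nM, time minutes.  The EGF state has zero time
// derivative in every model (sustained stimulus).
#include <Rcpp.h>
#include <cmath>

// Parameter block shared with deSolve.  Slots 0..29 hold model parameters
// (padded with zeros), slot 30 = steady-state event absolute tolerance,
// slot 31 = steady-state event relative tolerance.
#define NPARMS 32
static double parms[NPARMS];

# if defined(__GNUC__) || defined(__clang__)
#   define ERKMMI_EXPORT __attribute__((visibility("default")))
# else
#   define ERKMMI_EXPORT
# endif

extern "C" {

ERKMMI_EXPORT void initmod(void (*odeparms)(int *, double *)) {
  int n = NPARMS;
  odeparms(&n, parms);
}

// ---- MA_CASCADE: three-tier mass-action cascade, dual phosphorylation of
// MEK and ERK (distributive), explicit phosphatase rates.
// states: 0 EGF, 1 Raf, 2 aRaf, 3 MEK, 4 pMEK, 5 ppMEK, 6 ERK, 7 pERK, 8 ppERK
// params: 0 k1_Raf_act, 1 k2_Raf_deact, 2 k3_MEK_phos, 3 k4_MEK_phos2,
//         4 k5_MEK_dephos2, 5 k6_MEK_dephos, 6 k7_ERK_phos, 7 k8_ERK_phos2,
//         8 k9_ERK_dephos2, 9 k10_ERK_dephos, 10..12 Raf/MEK/ERK totals
static void rhs_ma(const double *y, double *ydot, const double *p) {
  const double EGF = y[0], Raf = y[1], aRaf = y[2];
  const double MEK = y[3], pMEK = y[4], ppMEK = y[5];
  const double ERK = y[6], pERK = y[7], ppERK = y[8];
  const double v1 = p[0] * EGF * Raf;     // Raf activation by EGF(R)
  const double v2 = p[1] * aRaf;          // Raf deactivation
  const double v3 = p[2] * aRaf * MEK;    // MEK -> pMEK
  const double v4 = p[3] * aRaf * pMEK;   // pMEK -> ppMEK
  const double v5 = p[4] * ppMEK;         // ppMEK -> pMEK
  const double v6 = p[5] * pMEK;          // pMEK -> MEK
  const double v7 = p[6] * ppMEK * ERK;   // ERK -> pERK
  const double v8 = p[7] * ppMEK * pERK;  // pERK -> ppERK
  const double v9 = p[8] * ppERK;         // ppERK -> pERK
  const double v10 = p[9] * pERK;         // pERK -> ERK
  ydot[0] = 0.0;
  ydot[1] = -v1 + v2;
  ydot[2] = v1 - v2;
  ydot[3] = -v3 + v6;
  ydot[4] = v3 - v4 + v5 - v6;
  ydot[5] = v4 - v5;
  ydot[6] = -v7 + v10;
  ydot[7] = v7 - v8 + v9 - v10;
  ydot[8] = v8 - v9;
}

// ---- FB_CASCADE: Michaelis-Menten tiers with divisive ERK->Raf negative
// feedback (1 + aERK/K_fb)^-1 on Raf activation.
// states: 0 EGF, 1 Raf, 2 aRaf, 3 MEK, 4 aMEK, 5 ERK, 6 aERK
// params: 0 k1_Raf_act, 1 Km_Raf_act, 2 k2_Raf_deact, 3 Km_Raf_deact,
//         4 k3_MEK_act, 5 Km_MEK_act, 6 k4_MEK_deact, 7 Km_MEK_deact,
//         8 k5_ERK_act, 9 Km_ERK_act, 10 k6_ERK_deact, 11 Km_ERK_deact,
//         12 K_fb, 13..15 Raf/MEK/ERK totals
static void rhs_fb_core(const double *y, double *ydot, const double *p,
                        double extra_raf_act) {
  const double EGF = y[0], Raf = y[1], aRaf = y[2];
  const double MEK = y[3], aMEK = y[4];
  const double ERK = y[5], aERK = y[6];
  const double fb = 1.0 / (1.0 + aERK / p[12]);
  const double vRafA = p[0] * EGF * Raf / (p[1] + Raf) * fb + extra_raf_act;
  const double vRafD = p[2] * aRaf / (p[3] + aRaf);
  const double vMekA = p[4] * aRaf * MEK / (p[5] + MEK);
  const double vMekD = p[6] * aMEK / (p[7] + aMEK);
  const double vErkA = p[8] * aMEK * ERK / (p[9] + ERK);
  const double vErkD = p[10] * aERK / (p[11] + aERK);
  ydot[0] = 0.0;
  ydot[1] = -vRafA + vRafD;
  ydot[2] = vRafA - vRafD;
  ydot[3] = -vMekA + vMekD;
  ydot[4] = vMekA - vMekD;
  ydot[5] = -vErkA + vErkD;
  ydot[6] = vErkA - vErkD;
}

static void rhs_fb(const double *y, double *ydot, const double *p) {
  rhs_fb_core(y, ydot, p, 0.0);
}

// ---- RAP1_CASCADE: FB_CASCADE plus an EGFR->C3G->Rap1->Raf branch that is
// not modulated by ERK negative feedback.
// states: 0..6 as FB, then 7 C3G, 8 aC3G, 9 Rap1, 10 aRap1
// params: 0..12 as FB, 13 k_C3G_act, 14 k1_C3G_deact, 15 k_Rap1_act,
//         16 k_Rap1_deact, 17 k_Raf_Rap1, 18 Km_Raf_Rap1,
//         19..23 Raf/MEK/ERK/C3G/Rap1 totals
static void rhs_rap1(const double *y, double *ydot, const double *p) {
  const double EGF = y[0], Raf = y[1];
  const double C3G = y[7], aC3G = y[8], Rap1 = y[9], aRap1 = y[10];
  const double vRafRap1 = p[17] * aRap1 * Raf / (p[18] + Raf);
  rhs_fb_core(y, ydot, p, vRafRap1);
  const double vC3GA = p[13] * EGF * C3G;
  const double vC3GD = p[14] * aC3G;   // k1_C3G_deact
  const double vRapA = p[15] * aC3G * Rap1;
  const double vRapD = p[16] * aRap1;
  ydot[7] = -vC3GA + vC3GD;
  ydot[8] = vC3GA - vC3GD;
  ydot[9] = -vRapA + vRapD;
  ydot[10] = vRapA - vRapD;
}

ERKMMI_EXPORT void derivs_ma(int *neq, double *t, double *y, double *ydot, double *yout, int *ip) {
  rhs_ma(y, ydot, parms);
}
ERKMMI_EXPORT void derivs_fb(int *neq, double *t, double *y, double *ydot, double *yout, int *ip) {
  rhs_fb(y, ydot, parms);
}
ERKMMI_EXPORT void derivs_rap1(int *neq, double *t, double *y, double *ydot, double *yout, int *ip) {
  rhs_rap1(y, ydot, parms);
}

// Steady-state event: g(x) = ||f(x)||_2 - (atol_ss + rtol_ss * ||x||_2)
static double ss_gout(int n, const double *y, const double *ydot) {
  double nf = 0.0, nx = 0.0;
  for (int i = 0; i < n; ++i) {
    nf += ydot[i] * ydot[i];
    nx += y[i] * y[i];
  }
  return std::sqrt(nf) - (parms[30] + parms[31] * std::sqrt(nx));
}

ERKMMI_EXPORT void root_ma(int *neq, double *t, double *y, int *ng, double *gout, double *out, int *ip) {
  double ydot[9];
  rhs_ma(y, ydot, parms);
  gout[0] = ss_gout(9, y, ydot);
}
ERKMMI_EXPORT void root_fb(int *neq, double *t, double *y, int *ng, double *gout, double *out, int *ip) {
  double ydot[7];
  rhs_fb(y, ydot, parms);
  gout[0] = ss_gout(7, y, ydot);
}
ERKMMI_EXPORT void root_rap1(int *neq, double *t, double *y, int *ng, double *gout, double *out, int *ip) {
  double ydot[11];
  rhs_rap1(y, ydot, parms);
  gout[0] = ss_gout(11, y, ydot);
}

} // extern "C"

// deSolve resolves initmod/derivs_*/root_* by dynamic symbol lookup, which
// the generated registration turns off; re-enable it at load time.
// [[Rcpp::init]]
void erkmmi_enable_dynamic_lookup(DllInfo *dll) {
  R_useDynamicSymbols(dll, TRUE);
}

// Direct rhs evaluation from R.  model_id: 1 = MA_CASCADE, 2 = FB_CASCADE,
// 3 = RAP1_CASCADE.  theta must be the model's full parameter vector.
// [[Rcpp::export]]
Rcpp::NumericVector rhs_eval_cpp(int model_id, Rcpp::NumericVector x,
                                 Rcpp::NumericVector theta) {
  double p[NPARMS];
  for (int i = 0; i < NPARMS; ++i) p[i] = 0.0;
  for (int i = 0; i < theta.size() && i < NPARMS; ++i) p[i] = theta[i];
  Rcpp::NumericVector ydot(x.size());
  switch (model_id) {
  case 1:
    if (x.size() != 9) Rcpp::stop("MA_CASCADE has 9 states");
    rhs_ma(x.begin(), ydot.begin(), p);
    break;
  case 2:
    if (x.size() != 7) Rcpp::stop("FB_CASCADE has 7 states");
    rhs_fb(x.begin(), ydot.begin(), p);
    break;
  case 3:
    if (x.size() != 11) Rcpp::stop("RAP1_CASCADE has 11 states");
    rhs_rap1(x.begin(), ydot.begin(), p);
    break;
  default:
    Rcpp::stop("unknown model id %d", model_id);
  }
  return ydot;
}
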