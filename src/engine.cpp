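// Compiled core: model right-hand sides and an adaptive embedded
// Dormand-Prince 5(4) integrator.  Parameter vectors are packed on the R
// side in the canonical orders defined in R/params.R; the index enums below
// must stay in step with those name vectors (checked by a dual-route test
// against the pure-R rhs implementations).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// parameter layouts

// clock (4 states: MP, PC, MR, RN), concentrations in nM
enum {
  CK_VSP, CK_VSPL, CK_KIP, CK_NP, CK_VMP, CK_KMP, CK_KSP, CK_VDP, CK_KDP,
  CK_KST, CK_BTOT, CK_KBP, CK_NBP, CK_KRB, CK_NRB, CK_KAB, CK_NAB,
  CK_VSR, CK_KAR, CK_NR, CK_VMR, CK_KMR, CK_KSR, CK_VDR,
  CK_KDR, CK_LDON, CK_LDUR, CK_DDUR, CK_PHASE0, CK_BNCLAMP, N_CLK_PAR
};

// cdk network (13 states: Rb, E2F, Md, Me, Ma, Cb, Mb, W, C25, Ch1, A20, P, X)
// concentrations in uM; C25, Ch1, A20 are fractions
enum {
  CD_S, CD_GF, CD_KAGF, CD_VSD, CD_KDD, CD_KDDB,
  CD_VSPRB, CD_KDRB, CD_KPRB, CD_KPRBM, CD_CE, CD_KIRB, CD_NIRB,
  CD_VSE2F, CD_KDE2F, CD_KDE2FA,
  CD_VSE, CD_KDE, CD_KDEA,
  CD_VSA, CD_KDA, CD_KDACH, CD_KDAA,
  CD_VCB, CD_KDB, CD_KDBCH, CD_KDBA,
  CD_V250, CD_V25, CD_KIW, CD_VSWEE1, CD_KDW, CD_VIW, CD_KIWW,
  CD_VA25, CD_VI25, CD_KAC25, CD_KIC25, CD_KXC,
  CD_VACH, CD_KICHA, CD_KICHB, CD_KACH, CD_KICH,
  CD_VA20, CD_VI20, CD_KA20, CD_KI20,
  CD_VBP21, CD_VEP21, CD_KDP21, CD_KIP1, CD_KIP2,
  CD_RHO2, CD_KIW2, CD_KAATR, CD_KDX, CD_XTOT,
  CD_VSPBI, CD_VSPBIREF, N_CDK_PAR
};

// coupling channels (3 states: Mw, Mp21, Mce), mRNA in uM, Bn/Rn in nM
enum {
  CP_MUW, CP_MUP, CP_MUC,
  CP_VSW, CP_KAW, CP_NMW, CP_VDMW, CP_KDMW, CP_KSW,
  CP_VSMP21, CP_KIP21, CP_NMP21, CP_VDMP21, CP_KDMP21, CP_VS1P21,
  CP_VSCE, CP_KICE, CP_NCE, CP_VDMCE, CP_KDMCE, CP_KCE2, N_CPL_PAR
};

static const int N_CLK = 4, N_CDK = 13, N_CPL = 3;

static inline double hill(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n), Kn = std::pow(K, n);
  return xn / (Kn + xn);
}
static inline double hillrep(double x, double K, double n) {
  if (x <= 0.0) return 1.0;
  double xn = std::pow(x, n), Kn = std::pow(K, n);
  return Kn / (Kn + xn);
}
static inline double mm(double x, double K) { return x / (K + x); }
static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

// light phase indicator for an LD square wave with L starting at phase0
// (floor-based modulo: std::fmod is avoided for glibc-version portability)
static inline bool in_light(double t, const double* p) {
  double per = p[CK_LDUR] + p[CK_DDUR];
  double x = (t - p[CK_PHASE0]) / per;
  double u = (x - std::floor(x)) * per;
  return u < p[CK_LDUR];
}

// Bn repressed by PER and (optionally) by nuclear REV-ERBalpha
static inline double bmal1_of(double PC, double RN, const double* p) {
  if (p[CK_BNCLAMP] >= 0.0) return p[CK_BNCLAMP];
  double b = p[CK_BTOT] * hillrep(pos(PC), p[CK_KBP], p[CK_NBP]);
  if (p[CK_NRB] > 0.0) b *= hillrep(pos(RN), p[CK_KRB], p[CK_NRB]);
  return b;
}

// clock rhs; y = (MP, PC, MR, RN).  PER degradation may include a
// complex-protection term (P^2/K_st); Per transcription may be gated by Bn.
static void clock_rhs(double t, const double* y, double* dy, const double* p) {
  double MP = pos(y[0]), PC = pos(y[1]), MR = pos(y[2]), RN = pos(y[3]);
  double vsP = p[CK_VSP] + ((p[CK_LDON] > 0.5 && in_light(t, p)) ? p[CK_VSPL] : 0.0);
  double Bn = bmal1_of(PC, RN, p);
  double act = p[CK_KAB] > 0.0 ? hill(Bn, p[CK_KAB], p[CK_NAB]) : 1.0;
  double degP = p[CK_VDP] * PC /
      (p[CK_KDP] + PC + (p[CK_KST] > 0.0 ? PC * PC / p[CK_KST] : 0.0));
  dy[0] = vsP * hillrep(PC, p[CK_KIP], p[CK_NP]) * act
          - p[CK_VMP] * mm(MP, p[CK_KMP]);
  dy[1] = p[CK_KSP] * MP - degP;
  dy[2] = p[CK_VSR] * hill(Bn, p[CK_KAR], p[CK_NR]) - p[CK_VMR] * mm(MR, p[CK_KMR]);
  dy[3] = p[CK_KSR] * MR - p[CK_VDR] * mm(RN, p[CK_KDR]);
}

// cdk rhs; y = (Rb, E2F, Md, Me, Ma, Cb, Mb, W, C25, Ch1, A20, P, X)
// in_w/in_p/in_e: circadian protein-synthesis contributions (0 when uncoupled)
static void cdk_rhs(const double* y, double* dy, const double* p,
                    double in_w, double in_p, double in_e) {
  double Rb = pos(y[0]), E2F = pos(y[1]), Md = pos(y[2]), Me = pos(y[3]),
         Ma = pos(y[4]), Cb = pos(y[5]), Mb = pos(y[6]), W = pos(y[7]),
         C25 = y[8], Ch1 = y[9], A20 = y[10], P = pos(y[11]), X = pos(y[12]);
  double s = p[CD_S];
  double fp1 = 1.0 / (1.0 + P / p[CD_KIP1]);
  double fp2 = 1.0 / (1.0 + P / p[CD_KIP2]);
  double fw2 = 1.0 / (1.0 + p[CD_RHO2] * W / p[CD_KIW2]);
  double Mea = Me * fp2 * fw2, Maa = Ma * fp2 * fw2, Mba = Mb * fp1;
  double E2Fa = E2F * hillrep(Rb, p[CD_KIRB], p[CD_NIRB]);
  double pool25 = p[CD_VSPBI] / p[CD_VSPBIREF];
  double kdegB = p[CD_KDB] + p[CD_KDBCH] * pos(Ch1) + p[CD_KDBA] * pos(A20);

  dy[0] = s * (p[CD_VSPRB] - p[CD_KDRB] * Rb
               - p[CD_KPRB] * (Md + p[CD_CE] * Mea) * mm(Rb, p[CD_KPRBM]));
  dy[1] = s * (p[CD_VSE2F] - p[CD_KDE2F] * E2F - p[CD_KDE2FA] * Maa * E2F);
  dy[2] = s * (p[CD_VSD] * mm(p[CD_GF], p[CD_KAGF]) - p[CD_KDD] * Md
               - p[CD_KDDB] * Mba * Md);
  dy[3] = s * (p[CD_VSE] * E2Fa + in_e - p[CD_KDE] * Me - p[CD_KDEA] * Maa * Me);
  dy[4] = s * (p[CD_VSA] * E2Fa - p[CD_KDA] * Ma - p[CD_KDACH] * pos(Ch1) * Ma
               - p[CD_KDAA] * pos(A20) * Ma);
  dy[5] = s * (p[CD_VCB] - kdegB * Cb);
  dy[6] = s * ((p[CD_V250] + p[CD_V25] * pos(C25)) * pool25 * pos(Cb - Mb)
               - p[CD_KIW] * W * Mb - kdegB * Mb);
  dy[7] = s * (p[CD_VSWEE1] + in_w - p[CD_KDW] * W
               - p[CD_VIW] * Mba * mm(W, p[CD_KIWW]));
  dy[8] = s * (p[CD_VA25] * Mba / (1.0 + X / p[CD_KXC])
                 * mm(pos(1.0 - C25), p[CD_KAC25])
               - p[CD_VI25] * mm(pos(C25), p[CD_KIC25]));
  dy[9] = s * (p[CD_VACH] * mm(pos(1.0 - Ch1), p[CD_KACH])
               - (p[CD_KICHA] * Maa + p[CD_KICHB] * Mba) * mm(pos(Ch1), p[CD_KICH]));
  dy[10] = s * (p[CD_VA20] * Mba * mm(pos(1.0 - A20), p[CD_KA20])
                - p[CD_VI20] * mm(pos(A20), p[CD_KI20]));
  dy[11] = s * (p[CD_VBP21] + p[CD_VEP21] * E2Fa + in_p - p[CD_KDP21] * P);
  dy[12] = s * (p[CD_KAATR] * (Mea + Maa) * pos(p[CD_XTOT] - X) - p[CD_KDX] * X);
}

// coupled rhs; y = clock(4) | cdk(13) | Mw, Mp21, Mce
// par = clock | cdk | coupling concatenated
static void coupled_rhs(double t, const double* y, double* dy, const double* p) {
  const double* pk = p;
  const double* pd = p + N_CLK_PAR;
  const double* pc = p + N_CLK_PAR + N_CDK_PAR;
  clock_rhs(t, y, dy, pk);
  double Bn = bmal1_of(y[1], y[3], pk);
  double Rn = pos(y[3]);
  double Mw = pos(y[N_CLK + N_CDK]), Mp21 = pos(y[N_CLK + N_CDK + 1]),
         Mce = pos(y[N_CLK + N_CDK + 2]);
  double in_w = pc[CP_KSW] * Mw;
  double in_p = pc[CP_VS1P21] * Mp21;
  double in_e = pc[CP_KCE2] * Mce;
  cdk_rhs(y + N_CLK, dy + N_CLK, pd, in_w, in_p, in_e);
  // clock-controlled mRNA balances (not scaled by s)
  dy[N_CLK + N_CDK] = pc[CP_MUW] * pc[CP_VSW] * hill(Bn, pc[CP_KAW], pc[CP_NMW])
                      - pc[CP_VDMW] * mm(Mw, pc[CP_KDMW]);
  dy[N_CLK + N_CDK + 1] =
      pc[CP_MUP] * pc[CP_VSMP21] * hillrep(Rn, pc[CP_KIP21], pc[CP_NMP21])
      - pc[CP_VDMP21] * mm(Mp21, pc[CP_KDMP21]);
  dy[N_CLK + N_CDK + 2] =
      pc[CP_MUC] * pc[CP_VSCE] * hillrep(Bn, pc[CP_KICE], pc[CP_NCE])
      - pc[CP_VDMCE] * mm(Mce, pc[CP_KDMCE]);
}

static void cdk_only_rhs(double t, const double* y, double* dy, const double* p) {
  (void)t;
  cdk_rhs(y, dy, p, 0.0, 0.0, 0.0);
}

typedef void (*RhsFn)(double t, const double* y, double* dy, const double* p);

static RhsFn pick_model(const std::string& model, int* nstate, int* npar) {
  if (model == "clock") { *nstate = N_CLK; *npar = N_CLK_PAR; return clock_rhs; }
  if (model == "cdk")   { *nstate = N_CDK; *npar = N_CDK_PAR; return cdk_only_rhs; }
  if (model == "coupled") {
    *nstate = N_CLK + N_CDK + N_CPL;
    *npar = N_CLK_PAR + N_CDK_PAR + N_CPL_PAR;
    return coupled_rhs;
  }
  stop("unknown compiled model '" + model + "'");
}

// single rhs evaluation, used by the R-level rhs wrappers
// [[Rcpp::export]]
NumericVector cpp_rhs(std::string model, double t, NumericVector y,
                      NumericVector par) {
  int ns, np;
  RhsFn f = pick_model(model, &ns, &np);
  if (y.size() != ns) stop("state length %d, expected %d", (int)y.size(), ns);
  if (par.size() != np) stop("parameter length %d, expected %d", (int)par.size(), np);
  NumericVector dy(ns);
  f(t, REAL(y), REAL(dy), REAL(par));
  for (int i = 0; i < ns; i++)
    if (!R_finite(dy[i]))
      stop("non-finite derivative for state index %d at t=%g", i + 1, t);
  return dy;
}

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4) with adaptive step size; steps land exactly on the
// requested output times, so no dense output is needed.

struct DPStepper {
  RhsFn f;
  const double* par;
  Function* rfun;      // non-null: R-function model (test/plug-in path)
  int n;
  double rtol, atol;
  long nsteps = 0, nreject = 0;
  double minval = 0.0; // most negative pre-clip state seen

  std::vector<double> k1, k2, k3, k4, k5, k6, k7, ytmp, y5, y4;

  DPStepper(RhsFn f_, const double* par_, Function* rf, int n_, double rt, double at)
      : f(f_), par(par_), rfun(rf), n(n_), rtol(rt), atol(at),
        k1(n_), k2(n_), k3(n_), k4(n_), k5(n_), k6(n_), k7(n_), ytmp(n_),
        y5(n_), y4(n_) {}

  void eval(double t, const double* y, double* dy) {
    if (rfun) {
      NumericVector yv(y, y + n);
      NumericVector out = as<NumericVector>((*rfun)(t, yv));
      if (out.size() != n) stop("R rhs returned length %d, expected %d",
                                (int)out.size(), n);
      for (int i = 0; i < n; i++) {
        dy[i] = out[i];
        if (!R_finite(dy[i]))
          stop("non-finite derivative for state index %d at t=%g", i + 1, t);
      }
    } else {
      f(t, y, dy, par);
      for (int i = 0; i < n; i++)
        if (!R_finite(dy[i]))
          stop("non-finite derivative for state index %d at t=%g", i + 1, t);
    }
  }

  // advance y from t to t_end, adapting h; h is carried between calls
  void advance(std::vector<double>& y, double t, double t_end, double& h) {
    const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
    const double a21 = 1.0 / 5;
    const double a31 = 3.0 / 40, a32 = 9.0 / 40;
    const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
    const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                 a53 = 64448.0 / 6561, a54 = -212.0 / 729;
    const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                 a64 = 49.0 / 176, a65 = -5103.0 / 18656;
    const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                 b5 = -2187.0 / 6784, b6 = 11.0 / 84;
    const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                 e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

    double span = t_end - t;
    if (span <= 0) return;
    double hmin = std::max(1e-12, 1e-10 * span);
    while (t < t_end) {
      if (h > t_end - t) h = t_end - t;
      if (h < hmin) h = hmin;
      eval(t, y.data(), k1.data());
      for (int i = 0; i < n; i++) ytmp[i] = y[i] + h * a21 * k1[i];
      eval(t + c2 * h, ytmp.data(), k2.data());
      for (int i = 0; i < n; i++)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      eval(t + c3 * h, ytmp.data(), k3.data());
      for (int i = 0; i < n; i++)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      eval(t + c4 * h, ytmp.data(), k4.data());
      for (int i = 0; i < n; i++)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      eval(t + c5 * h, ytmp.data(), k5.data());
      for (int i = 0; i < n; i++)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      eval(t + h, ytmp.data(), k6.data());
      for (int i = 0; i < n; i++)
        y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                            b6 * k6[i]);
      eval(t + h, y5.data(), k7.data());

      double err = 0.0;
      for (int i = 0; i < n; i++) {
        double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
        double r = ei / sc;
        err += r * r;
      }
      err = std::sqrt(err / n);

      if (err <= 1.0 || h <= hmin * 1.0001) {
        t += h;
        for (int i = 0; i < n; i++) {
          if (y5[i] < minval) minval = y5[i];
          // clip tiny negative concentrations produced by truncation error
          y[i] = (y5[i] < 0.0 && y5[i] > -1e3 * atol) ? 0.0 : y5[i];
        }
        nsteps++;
      } else {
        nreject++;
      }
      double fac = 0.9 * std::pow(err > 1e-12 ? err : 1e-12, -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (nsteps + nreject > 100000000L)
        stop("step-size underflow / excessive work near t=%g", t);
      if ((nsteps + nreject) % 4096 == 0) checkUserInterrupt();
    }
  }
};

// Integrate over an output grid `times` (strictly increasing; first entry is
// the initial time).  For model "rfun" the rhs is the R function `rfn`.
// [[Rcpp::export]]
List cpp_integrate(std::string model, NumericVector par, NumericVector y0,
                   NumericVector times, double rel_tol, double abs_tol,
                   Nullable<Function> rfn = R_NilValue) {
  int ns = y0.size(), np = 0;
  RhsFn f = NULL;
  Function* rf = NULL;
  Function rfun_holder = Environment::base_env()["identity"];
  if (model == "rfun") {
    if (rfn.isNull()) stop("model 'rfun' needs an R function");
    rfun_holder = Function(rfn);
    rf = &rfun_holder;
  } else {
    f = pick_model(model, &ns, &np);
    if (y0.size() != ns) stop("state length %d, expected %d", (int)y0.size(), ns);
    if (par.size() != np) stop("parameter length %d, expected %d",
                               (int)par.size(), np);
  }
  int nt = times.size();
  if (nt < 2) stop("need at least two output times");
  NumericMatrix out(nt, ns);
  std::vector<double> y(REAL(y0), REAL(y0) + ns);
  for (int j = 0; j < ns; j++) out(0, j) = y[j];

  DPStepper st(f, model == "rfun" ? NULL : REAL(par), rf, ns, rel_tol, abs_tol);
  double h = std::min(1e-3, (times[1] - times[0]) * 0.1);
  for (int i = 1; i < nt; i++) {
    double t0 = times[i - 1], t1 = times[i];
    if (t1 <= t0) stop("output times must be strictly increasing");
    st.advance(y, t0, t1, h);
    for (int j = 0; j < ns; j++) out(i, j) = y[j];
  }
  return List::create(_["states"] = out, _["nsteps"] = st.nsteps,
                      _["nreject"] = st.nreject, _["minval"] = st.minval);
}
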