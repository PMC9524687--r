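// Multiscale cardiovascular model core: sarcomere stress generation,
// TriSeg biventricular mechanics (nested 2-D algebraic solve), and a
// 0D systemic/pulmonary circulation, plus an adaptive Cash-Karp
// Runge-Kutta integrator so that whole-study pipelines (screening,
// profiling, MCMC) can run many thousands of simulations.
//
// Units: pressure kPa, volume ul (= mm^3), length um, area mm^2,
// curvature 1/mm, time s, resistance kPa.s/ul, compliance ul/kPa.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------- packed parameter layout ----------------
// 0..12   atrial sarcomere group
// 13..25  ventricular sarcomere group
// 26      tau_offset_A
// 27..31  Vw       (LA, LV, RA, RV, S)
// 32..36  Am_ref   (LA, LV, RA, RV, S)
// 37..44  Ra_val, Rm_val, Rp_val, Rt_val, R_vc, R_pv, R_sys, R_pulm
// 45..48  C_sa, C_sv, C_pa, C_pv
// 49      cardiac period T
// 50..53  V_un (sa, sv, pa, pv)
static const int NPACK = 54;
// sarcomere group offsets
enum { S_LS_REF = 0, S_LS_ISO, S_V0, S_LSC0, S_GAMMA_REST, S_TAU_RISE,
       S_TAU_DECAY, S_TAU_SYS, S_SIGMA_ACT, S_SIGMA_PAS, S_LS_PAS_REF,
       S_BETA_PAS, S_K1 };
static const int P_TAU_OFFSET = 26;
static const int P_VW = 27;      // +0..4 LA LV RA RV S
static const int P_AMREF = 32;   // +0..4
static const int P_RAVAL = 37, P_RMVAL = 38, P_RPVAL = 39, P_RTVAL = 40,
                 P_RVC = 41, P_RPV = 42, P_RSYS = 43, P_RPULM = 44,
                 P_CSA = 45, P_CSV = 46, P_CPA = 47, P_CPV = 48,
                 P_PERIOD = 49, P_VUN = 50;

// wall ids
enum { W_LA = 0, W_LV = 1, W_RA = 2, W_RV = 3, W_S = 4 };
// state layout: Lsc[w] = 2w, Gamma[w] = 2w+1 (w = 0..4), volumes 10..17
enum { Y_VLA = 10, Y_VLV, Y_VRA, Y_VRV, Y_VSA, Y_VSV, Y_VPA, Y_VPV };
static const int NSTATE = 18;
// auxiliary output layout (43 entries)
// 0..7 pressures LA LV RA RV SA SV PA PV
// 8..15 flows mval aval sys vc tval pval pulm pv
// 16 + 5w + {0 eps_f, 1 Ls, 2 Am, 3 Cm, 4 Tm} for w = 0..4
// 41 VmS, 42 ym, 43 achieved tension-balance residual
static const int NOUT = 44;

struct Stress { double act, ecm, titin, tot; };

static inline const double* sgroup(const double* p, int grp) {
  return p + (grp == 0 ? 0 : 13);
}

static inline Stress sarc_stress(double Ls, double Lsc, double Gam,
                                 const double* p, int grp) {
  const double* s = sgroup(p, grp);
  Stress g;
  double phi = Lsc - s[S_LSC0];
  if (phi < 0.0) phi = 0.0;
  g.act = s[S_SIGMA_ACT] * Gam * phi * (Ls - Lsc) / s[S_LS_ISO];
  double r = Ls / s[S_LS_PAS_REF];
  g.ecm = s[S_SIGMA_PAS] * (std::pow(r, s[S_BETA_PAS]) - std::pow(r, -6.0));
  g.titin = 0.01 * s[S_SIGMA_ACT] * (std::pow(r, s[S_K1]) - 1.0);
  g.tot = g.act + g.ecm + g.titin;
  return g;
}

// positive modulo without libm fmod (keeps symbol versioning portable)
static inline double pos_mod(double a, double b) {
  double m = a - b * std::floor(a / b);
  if (m < 0.0) m += b;
  if (m >= b) m -= b;
  return m;
}

// activation clock: ventricular walls use t mod T, atrial walls are
// shifted by tau_offset_A so atrial systole precedes ventricular onset
static inline double wall_clock(double t, const double* p, int grp) {
  double T = p[P_PERIOD];
  double tc = (grp == 0) ? (t - p[P_TAU_OFFSET]) : t;
  return pos_mod(tc, T);
}

static inline void sarc_rates(double Ls, double Lsc, double Gam, double t,
                              const double* p, int grp,
                              double* dLsc, double* dGam) {
  const double* s = sgroup(p, grp);
  *dLsc = ((Ls - Lsc) / s[S_LS_ISO] - 1.0) * s[S_V0];
  double tc = wall_clock(t, p, grp);
  double x = tc / s[S_TAU_RISE];
  double Fr = (x < 8.0) ? 0.02 * x * x * x * (8.0 - x) * (8.0 - x) * std::exp(-x)
                        : 0.0;
  double phi = Lsc - s[S_LSC0];
  if (phi < 0.0) phi = 0.0;
  double Fd = 0.5 * (1.0 + std::tanh((tc - s[S_TAU_SYS]) / s[S_TAU_DECAY]));
  *dGam = phi * Fr / s[S_TAU_RISE] - Fd * (Gam - s[S_GAMMA_REST]) / s[S_TAU_DECAY];
}

// signed spherical-cap height x from signed cap volume Vm and junction
// radius ym:  Vm = (pi/6) x (x^2 + 3 ym^2)  (single real root, Cardano)
static inline double cap_x(double Vm, double ym) {
  double y = std::fabs(ym);
  double u = 3.0 * Vm / (M_PI * y * y * y);
  return 2.0 * y * std::sinh(std::asinh(u) / 3.0);
}

struct WallQ {
  double x, Am, Cm, z, eps, Ls, Gtot, Tm, Tx, Ty;
};

// curved-wall kinematics and tension for one wall patch
static inline bool wall_eval(double Vm, double ym, double Vwall, double Amref,
                             double Lsc, double Gam, const double* p, int grp,
                             WallQ* w) {
  double x = cap_x(Vm, ym);
  double d2 = x * x + ym * ym;
  double Am = M_PI * d2;
  if (!(Am > 1e-10)) return false;
  double Cm = 2.0 * x / d2;
  double z = 3.0 * Cm * Vwall / (2.0 * Am);
  double z2 = z * z;
  double eps = 0.5 * std::log(Am / Amref) - z2 / 12.0 - 0.019 * z2 * z2;
  const double* s = sgroup(p, grp);
  double Ls = s[S_LS_REF] * std::exp(eps);
  Stress g = sarc_stress(Ls, Lsc, Gam, p, grp);
  double Tm = (Vwall * g.tot / (2.0 * Am)) * (1.0 + z2 / 3.0 + z2 * z2 / 5.0);
  double sina = 2.0 * x * ym / d2;
  double cosa = (ym * ym - x * x) / d2;
  w->x = x; w->Am = Am; w->Cm = Cm; w->z = z; w->eps = eps; w->Ls = Ls;
  w->Gtot = g.tot; w->Tm = Tm; w->Tx = Tm * sina; w->Ty = Tm * cosa;
  return std::isfinite(Tm);
}

struct TriOut {
  double Rx, Ry, pLV, pRV, Tscale;
  WallQ lv, s, rv;
};

// residuals of the junction tension balance at candidate (VmS, ym);
// yst carries Lsc/Gamma for the LV, RV and S walls
static bool triseg_eval(double VmS, double ym, double VLV, double VRV,
                        const double* yst, const double* p, TriOut* o) {
  if (!(ym > 1e-4)) return false;
  double VwLV = p[P_VW + W_LV], VwRV = p[P_VW + W_RV], VwS = p[P_VW + W_S];
  double VmLV = VmS - (VLV + 0.5 * VwLV + 0.5 * VwS);
  double VmRV = VmS + VRV + 0.5 * VwRV + 0.5 * VwS;
  bool ok = true;
  ok = ok && wall_eval(VmLV, ym, VwLV, p[P_AMREF + W_LV],
                       yst[2 * W_LV], yst[2 * W_LV + 1], p, 1, &o->lv);
  ok = ok && wall_eval(VmS, ym, VwS, p[P_AMREF + W_S],
                       yst[2 * W_S], yst[2 * W_S + 1], p, 1, &o->s);
  ok = ok && wall_eval(VmRV, ym, VwRV, p[P_AMREF + W_RV],
                       yst[2 * W_RV], yst[2 * W_RV + 1], p, 1, &o->rv);
  if (!ok) return false;
  o->Rx = o->lv.Tx + o->s.Tx + o->rv.Tx;
  o->Ry = o->lv.Ty + o->s.Ty + o->rv.Ty;
  double Ts = std::fabs(o->lv.Tm);
  if (std::fabs(o->s.Tm) > Ts) Ts = std::fabs(o->s.Tm);
  if (std::fabs(o->rv.Tm) > Ts) Ts = std::fabs(o->rv.Tm);
  o->Tscale = (Ts > 1e-3) ? Ts : 1e-3;
  // transmural law of the curved free walls gives the cavity pressures
  o->pLV = -2.0 * o->lv.Tm * o->lv.Cm;
  o->pRV = 2.0 * o->rv.Tm * o->rv.Cm;
  return std::isfinite(o->Rx) && std::isfinite(o->Ry);
}

// workspace persisted across right-hand-side calls: warm-start pair
// and a reusable (Broyden-updated) Jacobian of the tension balance
struct SolveWS {
  double VmS, ym;
  double J[4];
  bool Jvalid;
};
static inline void ws_init(SolveWS* ws, double VmS0, double ym0) {
  ws->VmS = VmS0; ws->ym = ym0;
  ws->J[0] = ws->J[1] = ws->J[2] = ws->J[3] = 0.0;
  ws->Jvalid = false;
}

// damped Newton from a given start; the Jacobian is finite-differenced
// on demand, Broyden-updated along accepted steps, and reused across
// calls through ws; true iff tol is reached
static bool triseg_newton(double VLV, double VRV, const double* yst,
                          const double* p, double* VmS, double* ym,
                          TriOut* out, double tol, int maxit,
                          double lo, double hi, double rchar,
                          double* J, bool* Jvalid) {
  double vs = *VmS, y = *ym, span = hi - lo;
  TriOut o;
  if (!triseg_eval(vs, y, VLV, VRV, yst, p, &o)) return false;
  bool fresh = false;
  for (int it = 0; it < maxit; ++it) {
    double rn = std::hypot(o.Rx, o.Ry) / o.Tscale;
    if (rn <= tol) break;
    if (!*Jvalid) {
      double dv = 1e-6 * span + 1e-9;
      double dy = 1e-6 * rchar + 1e-9;
      TriOut ov, oy;
      double vsp = vs + dv; if (vsp >= hi) { vsp = vs - dv; dv = -dv; }
      double yp = y + dy;
      if (!triseg_eval(vsp, y, VLV, VRV, yst, p, &ov) ||
          !triseg_eval(vs, yp, VLV, VRV, yst, p, &oy)) return false;
      J[0] = (ov.Rx - o.Rx) / dv; J[1] = (oy.Rx - o.Rx) / dy;
      J[2] = (ov.Ry - o.Ry) / dv; J[3] = (oy.Ry - o.Ry) / dy;
      *Jvalid = true; fresh = true;
    }
    double det = J[0] * J[3] - J[1] * J[2];
    if (!std::isfinite(det) || std::fabs(det) < 1e-300) {
      if (fresh) return false;
      *Jvalid = false; continue;
    }
    double sv = -(J[3] * o.Rx - J[1] * o.Ry) / det;
    double sy = -(-J[2] * o.Rx + J[0] * o.Ry) / det;
    double lam = 1.0;
    bool moved = false;
    TriOut on;
    double nvs = vs, ny = y;
    for (int k = 0; k < 10; ++k, lam *= 0.5) {
      nvs = vs + lam * sv; ny = y + lam * sy;
      if (nvs <= lo + 1e-9 * span) nvs = lo + 1e-9 * span + 0.5 * (vs - lo);
      if (nvs >= hi - 1e-9 * span) nvs = hi - 0.5 * (hi - vs);
      if (ny < 1e-3) ny = 0.5 * (y + 1e-3);
      if (triseg_eval(nvs, ny, VLV, VRV, yst, p, &on) &&
          std::hypot(on.Rx, on.Ry) / on.Tscale < rn * (1.0 - 1e-4 * lam) + 1e-14) {
        moved = true; break;
      }
    }
    if (!moved) {
      if (fresh) return false;  // even a fresh Jacobian cannot improve
      *Jvalid = false; continue;
    }
    // Broyden rank-1 update along the accepted step
    double s0 = nvs - vs, s1 = ny - y;
    double ss = s0 * s0 + s1 * s1;
    if (ss > 0.0) {
      double r0 = (on.Rx - o.Rx) - (J[0] * s0 + J[1] * s1);
      double r1 = (on.Ry - o.Ry) - (J[2] * s0 + J[3] * s1);
      J[0] += r0 * s0 / ss; J[1] += r0 * s1 / ss;
      J[2] += r1 * s0 / ss; J[3] += r1 * s1 / ss;
    }
    vs = nvs; y = ny; o = on; fresh = false;
  }
  if (std::hypot(o.Rx, o.Ry) / o.Tscale > tol) return false;
  *VmS = vs; *ym = y; *out = o;
  return true;
}

// derivative-free compass search on the residual norm; used to walk
// into narrow root basins that Newton cannot reach from the grid
static bool pattern_polish(double VLV, double VRV, const double* yst,
                           const double* p, double* vs0, double* y0,
                           double lo, double hi, double rchar) {
  double vs = *vs0, y = *y0;
  TriOut o;
  if (!triseg_eval(vs, y, VLV, VRV, yst, p, &o)) return false;
  double best = std::hypot(o.Rx, o.Ry) / o.Tscale;
  double dv = 0.04 * (hi - lo), dy = 0.08 * rchar;
  static const int mv[8][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1},
                               {1, 1}, {1, -1}, {-1, 1}, {-1, -1}};
  for (int it = 0; it < 240 && (dv > 1e-11 * (hi - lo)); ++it) {
    bool improved = false;
    double bvs = vs, by = y;
    for (int m = 0; m < 8; ++m) {
      double tv = vs + mv[m][0] * dv, ty = y + mv[m][1] * dy;
      if (tv <= lo || tv >= hi || ty < 1e-3) continue;
      TriOut t2;
      if (triseg_eval(tv, ty, VLV, VRV, yst, p, &t2)) {
        double r = std::hypot(t2.Rx, t2.Ry) / t2.Tscale;
        if (std::isfinite(r) && r < best) { best = r; bvs = tv; by = ty; improved = true; }
      }
    }
    if (improved) { vs = bvs; y = by; }
    else { dv *= 0.5; dy *= 0.5; }
  }
  *vs0 = vs; *y0 = y;
  return true;
}

// full solve: warm-started quasi-Newton, then a brute-force bracketing
// grid with Newton restarts, then compass-search polishing
static bool triseg_solve(double VLV, double VRV, const double* yst,
                         const double* p, SolveWS* ws, TriOut* out,
                         double tol, int maxit) {
  double lo = -(VRV + 0.5 * p[P_VW + W_RV] + 0.5 * p[P_VW + W_S]);
  double hi = (VLV + 0.5 * p[P_VW + W_LV] + 0.5 * p[P_VW + W_S]);
  double span = hi - lo;
  double rchar = std::cbrt(0.75 * (VLV + VRV + p[P_VW + W_LV] +
                                   p[P_VW + W_RV] + p[P_VW + W_S]) / M_PI);
  if (std::isfinite(ws->VmS) && std::isfinite(ws->ym) &&
      ws->VmS > lo && ws->VmS < hi && ws->ym > 1e-3) {
    double vs = ws->VmS, y = ws->ym;
    if (triseg_newton(VLV, VRV, yst, p, &vs, &y, out, tol, maxit,
                      lo, hi, rchar, ws->J, &ws->Jvalid)) {
      ws->VmS = vs; ws->ym = y;
      return true;
    }
  }
  // lattice of Newton restarts, ordered from the physiologically likely
  // region (small septal cap volume, junction radius ~ half the
  // characteristic radius) outward; the relative residual surface is
  // deceptive in extreme-geometry regions, so basin membership is probed
  // directly by cheap Newton attempts rather than by residual ranking
  const int NV = 13, NY = 8;
  std::vector<std::pair<double, std::pair<double, double>>> starts;
  starts.reserve(NV * NY);
  for (int iv = 0; iv < NV; ++iv) {
    double tvs = lo + span * (iv + 0.5) / NV;
    for (int iy = 0; iy < NY; ++iy) {
      double ty = rchar * (0.2 + 1.8 * iy / (NY - 1.0));
      double sc = (tvs - 0.1 * span - lo) / span;
      double score = (sc - 0.5) * (sc - 0.5) +
                     (ty / rchar - 0.55) * (ty / rchar - 0.55);
      starts.push_back({score, {tvs, ty}});
    }
  }
  std::sort(starts.begin(), starts.end());
  for (size_t k = 0; k < starts.size(); ++k) {
    double bvs = starts[k].second.first, by = starts[k].second.second;
    ws->Jvalid = false;
    if (triseg_newton(VLV, VRV, yst, p, &bvs, &by, out, tol, 25,
                      lo, hi, rchar, ws->J, &ws->Jvalid)) {
      ws->VmS = bvs; ws->ym = by;
      return true;
    }
  }
  // last resort: derivative-free descent from a spread of starts
  for (int iy = 1; iy <= 3; ++iy) {
    double bvs = lo + 0.5 * span, by = rchar * (0.25 + 0.35 * iy);
    if (!pattern_polish(VLV, VRV, yst, p, &bvs, &by, lo, hi, rchar))
      continue;
    ws->Jvalid = false;
    if (triseg_newton(VLV, VRV, yst, p, &bvs, &by, out, tol, maxit,
                      lo, hi, rchar, ws->J, &ws->Jvalid)) {
      ws->VmS = bvs; ws->ym = by;
      return true;
    }
  }
  return false;
}

// full right-hand side; returns false on infeasible geometry / failure
static bool rhs_core(double t, const double* y, const double* p,
                     double* dy, double* out, SolveWS* ws) {
  for (int i = Y_VLA; i <= Y_VRV; ++i)
    if (!(y[i] > 0.0)) return false;
  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(y[i])) return false;

  double pres[8], Ls_w[5];
  // atria: single spherical walls
  for (int k = 0; k < 2; ++k) {
    int w = (k == 0) ? W_LA : W_RA;
    int yv = (k == 0) ? Y_VLA : Y_VRA;
    double Vm = y[yv] + 0.5 * p[P_VW + w];
    double r = std::cbrt(3.0 * Vm / (4.0 * M_PI));
    double Am = 4.0 * M_PI * r * r;
    double Cm = 1.0 / r;
    double z = 3.0 * Cm * p[P_VW + w] / (2.0 * Am);
    double z2 = z * z;
    double eps = 0.5 * std::log(Am / p[P_AMREF + w]) - z2 / 12.0 - 0.019 * z2 * z2;
    const double* s = sgroup(p, 0);
    double Ls = s[S_LS_REF] * std::exp(eps);
    Stress g = sarc_stress(Ls, y[2 * w], y[2 * w + 1], p, 0);
    double Tm = (p[P_VW + w] * g.tot / (2.0 * Am)) * (1.0 + z2 / 3.0 + z2 * z2 / 5.0);
    pres[w] = 2.0 * Tm * Cm;
    Ls_w[w] = Ls;
    if (out) {
      out[16 + 5 * w] = eps; out[16 + 5 * w + 1] = Ls;
      out[16 + 5 * w + 2] = Am; out[16 + 5 * w + 3] = Cm;
      out[16 + 5 * w + 4] = Tm;
    }
  }

  // ventricles: TriSeg equilibrium
  TriOut tri;
  if (!triseg_solve(y[Y_VLV], y[Y_VRV], y, p, ws, &tri, 1e-8, 50))
    return false;
  pres[W_LV] = tri.pLV;
  pres[W_RV] = tri.pRV;
  Ls_w[W_LV] = tri.lv.Ls; Ls_w[W_RV] = tri.rv.Ls; Ls_w[W_S] = tri.s.Ls;
  if (out) {
    const WallQ* wq[3] = { &tri.lv, &tri.rv, &tri.s };
    int wi[3] = { W_LV, W_RV, W_S };
    for (int k = 0; k < 3; ++k) {
      out[16 + 5 * wi[k]] = wq[k]->eps; out[16 + 5 * wi[k] + 1] = wq[k]->Ls;
      out[16 + 5 * wi[k] + 2] = wq[k]->Am; out[16 + 5 * wi[k] + 3] = wq[k]->Cm;
      out[16 + 5 * wi[k] + 4] = wq[k]->Tm;
    }
    out[41] = ws->VmS; out[42] = ws->ym;
    out[43] = std::hypot(tri.Rx, tri.Ry) / tri.Tscale;
  }

  // vascular compartments (electric circuit analogy)
  double pSA = (y[Y_VSA] - p[P_VUN + 0]) / p[P_CSA];
  double pSV = (y[Y_VSV] - p[P_VUN + 1]) / p[P_CSV];
  double pPA = (y[Y_VPA] - p[P_VUN + 2]) / p[P_CPA];
  double pPV = (y[Y_VPV] - p[P_VUN + 3]) / p[P_CPV];
  double pLA = pres[W_LA], pLV = pres[W_LV], pRA = pres[W_RA], pRV = pres[W_RV];

  // diode valves (incl. vena cava resistor), linear resistors elsewhere
  double q_mval = (pLA > pLV) ? (pLA - pLV) / p[P_RMVAL] : 0.0;
  double q_aval = (pLV > pSA) ? (pLV - pSA) / p[P_RAVAL] : 0.0;
  double q_sys = (pSA - pSV) / p[P_RSYS];
  double q_vc = (pSV > pRA) ? (pSV - pRA) / p[P_RVC] : 0.0;
  double q_tval = (pRA > pRV) ? (pRA - pRV) / p[P_RTVAL] : 0.0;
  double q_pval = (pRV > pPA) ? (pRV - pPA) / p[P_RPVAL] : 0.0;
  double q_pulm = (pPA - pPV) / p[P_RPULM];
  double q_pv = (pPV - pLA) / p[P_RPV];

  dy[Y_VLA] = q_pv - q_mval;
  dy[Y_VLV] = q_mval - q_aval;
  dy[Y_VSA] = q_aval - q_sys;
  dy[Y_VSV] = q_sys - q_vc;
  dy[Y_VRA] = q_vc - q_tval;
  dy[Y_VRV] = q_tval - q_pval;
  dy[Y_VPA] = q_pval - q_pulm;
  dy[Y_VPV] = q_pulm - q_pv;

  for (int w = 0; w < 5; ++w) {
    int grp = (w == W_LA || w == W_RA) ? 0 : 1;
    sarc_rates(Ls_w[w], y[2 * w], y[2 * w + 1], t, p, grp,
               &dy[2 * w], &dy[2 * w + 1]);
  }
  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(dy[i])) return false;

  if (out) {
    out[0] = pLA; out[1] = pLV; out[2] = pRA; out[3] = pRV;
    out[4] = pSA; out[5] = pSV; out[6] = pPA; out[7] = pPV;
    out[8] = q_mval; out[9] = q_aval; out[10] = q_sys; out[11] = q_vc;
    out[12] = q_tval; out[13] = q_pval; out[14] = q_pulm; out[15] = q_pv;
  }
  return true;
}

// ---------------- adaptive Cash-Karp RK45 ----------------
static const double CK_A[6] = {0.0, 0.2, 0.3, 0.6, 1.0, 0.875};
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {0.2, 0, 0, 0, 0},
  {3.0 / 40.0, 9.0 / 40.0, 0, 0, 0},
  {0.3, -0.9, 1.2, 0, 0},
  {-11.0 / 54.0, 2.5, -70.0 / 27.0, 35.0 / 27.0, 0},
  {1631.0 / 55296.0, 175.0 / 512.0, 575.0 / 13824.0,
   44275.0 / 110592.0, 253.0 / 4096.0}};
static const double CK_C[6] = {37.0 / 378.0, 0.0, 250.0 / 621.0,
                               125.0 / 594.0, 0.0, 512.0 / 1771.0};
static const double CK_D[6] = {
  37.0 / 378.0 - 2825.0 / 27648.0, 0.0, 250.0 / 621.0 - 18575.0 / 48384.0,
  125.0 / 594.0 - 13525.0 / 55296.0, -277.0 / 14336.0, 512.0 / 1771.0 - 0.25};

struct IntStats { long nrhs; long nstep; long nreject; };

// one attempted CK step; returns false if any stage is infeasible
static bool ck_stage(double t, double dt, const double* y, const double* p,
                     double* ynew, double* yerr, SolveWS* ws, IntStats* st) {
  double k[6][NSTATE], ytmp[NSTATE];
  if (!rhs_core(t, y, p, k[0], NULL, ws)) return false;
  st->nrhs++;
  for (int s = 1; s < 6; ++s) {
    for (int i = 0; i < NSTATE; ++i) {
      double acc = 0.0;
      for (int j = 0; j < s; ++j) acc += CK_B[s][j] * k[j][i];
      ytmp[i] = y[i] + dt * acc;
    }
    if (!rhs_core(t + CK_A[s] * dt, ytmp, p, k[s], NULL, ws))
      return false;
    st->nrhs++;
  }
  for (int i = 0; i < NSTATE; ++i) {
    double acc = 0.0, err = 0.0;
    for (int s = 0; s < 6; ++s) { acc += CK_C[s] * k[s][i]; err += CK_D[s] * k[s][i]; }
    ynew[i] = y[i] + dt * acc;
    yerr[i] = dt * err;
  }
  return true;
}

static inline double err_norm(const double* y, const double* ynew,
                              const double* yerr, double rtol, double atol) {
  double acc = 0.0;
  for (int i = 0; i < NSTATE; ++i) {
    double typ = (i < 10) ? 1.0 : 10.0;  // sarcomere states O(1), volumes O(10)
    double sc = atol * typ + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
    double e = yerr[i] / sc;
    acc += e * e;
  }
  return std::sqrt(acc / NSTATE);
}

// [[Rcpp::export]]
List cv_integrate(NumericVector parms, NumericVector y0,
                  NumericVector out_times, double rtol = 1e-6,
                  double atol = 1e-6, double dt_init = 1e-4,
                  double dt_max = 0.02, double VmS0 = NA_REAL,
                  double ym0 = NA_REAL) {
  if (parms.size() != NPACK) stop("packed parameter vector must have length %d", NPACK);
  if (y0.size() != NSTATE) stop("state vector must have length %d", NSTATE);
  int nt = out_times.size();
  NumericMatrix Y(nt, NSTATE), OUT(nt, NOUT);
  std::fill(Y.begin(), Y.end(), NA_REAL);
  std::fill(OUT.begin(), OUT.end(), NA_REAL);
  double y[NSTATE], ynew[NSTATE], yerr[NSTATE], dy[NSTATE], aux[NOUT];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];
  const double* p = REAL(parms);
  SolveWS ws;
  ws_init(&ws, VmS0, ym0);
  IntStats st = {0, 0, 0};
  double t = 0.0, dt = dt_init;
  int status = 0, iout = 0;
  double t_fail = NA_REAL;

  // record any output times at t = 0
  while (iout < nt && out_times[iout] <= t + 1e-14) {
    if (rhs_core(t, y, p, dy, aux, &ws)) {
      for (int i = 0; i < NSTATE; ++i) Y(iout, i) = y[i];
      for (int i = 0; i < NOUT; ++i) OUT(iout, i) = aux[i];
    } else { status = 2; }
    iout++;
  }
  double t_end = out_times[nt - 1];

  while (status == 0 && t < t_end - 1e-12) {
    double t_target = (iout < nt) ? out_times[iout] : t_end;
    if (t + dt > t_target) dt = t_target - t;
    if (dt > dt_max) dt = dt_max;
    bool ok = ck_stage(t, dt, y, p, ynew, yerr, &ws, &st);
    if (ok) {
      double en = err_norm(y, ynew, yerr, rtol, atol);
      if (en <= 1.0) {
        t += dt;
        for (int i = 0; i < NSTATE; ++i) y[i] = ynew[i];
        st.nstep++;
        double fac = 0.9 * std::pow(en > 1e-10 ? en : 1e-10, -0.2);
        dt *= std::min(5.0, std::max(0.2, fac));
        if (t >= t_target - 1e-12 && iout < nt) {
          if (rhs_core(t, y, p, dy, aux, &ws)) {
            for (int i = 0; i < NSTATE; ++i) Y(iout, i) = y[i];
            for (int i = 0; i < NOUT; ++i) OUT(iout, i) = aux[i];
          }
          iout++;
        }
        continue;
      }
      st.nreject++;
      double fac = 0.9 * std::pow(en, -0.25);
      dt *= std::max(0.1, fac);
    } else {
      st.nreject++;
      dt *= 0.25;
    }
    if (dt < 1e-10) { status = 1; t_fail = t; break; }
  }

  return List::create(
    _["states"] = Y, _["aux"] = OUT, _["status"] = status,
    _["t_fail"] = t_fail, _["n_rhs"] = (double)st.nrhs,
    _["n_steps"] = (double)st.nstep, _["n_reject"] = (double)st.nreject,
    _["VmS"] = ws.VmS, _["ym"] = ws.ym);
}

// ---------------- exported scalar building blocks ----------------

// [[Rcpp::export]]
List cv_rhs(double t, NumericVector y, NumericVector parms,
            double VmS0 = NA_REAL, double ym0 = NA_REAL) {
  if (parms.size() != NPACK) stop("packed parameter vector must have length %d", NPACK);
  if (y.size() != NSTATE) stop("state vector must have length %d", NSTATE);
  double dy[NSTATE], aux[NOUT];
  SolveWS ws;
  ws_init(&ws, VmS0, ym0);
  bool ok = rhs_core(t, REAL(y), REAL(parms), dy, aux, &ws);
  if (!ok) return List::create(_["ok"] = false);
  return List::create(_["ok"] = true,
                      _["dy"] = NumericVector(dy, dy + NSTATE),
                      _["aux"] = NumericVector(aux, aux + NOUT),
                      _["VmS"] = ws.VmS, _["ym"] = ws.ym);
}

// [[Rcpp::export]]
List cv_sarc_stress(double Ls, double Lsc, double Gamma, NumericVector parms,
                    int group) {
  Stress g = sarc_stress(Ls, Lsc, Gamma, REAL(parms), group);
  return List::create(_["act"] = g.act, _["ecm"] = g.ecm,
                      _["titin"] = g.titin, _["total"] = g.tot);
}

// [[Rcpp::export]]
NumericVector cv_sarc_rates(double Ls, double Lsc, double Gamma, double t,
                            NumericVector parms, int group) {
  double dLsc, dGam;
  sarc_rates(Ls, Lsc, Gamma, t, REAL(parms), group, &dLsc, &dGam);
  return NumericVector::create(_["dLsc"] = dLsc, _["dGamma"] = dGam);
}

// [[Rcpp::export]]
List cv_cap_geometry(double Vm, double ym) {
  double x = cap_x(Vm, ym);
  double d2 = x * x + ym * ym;
  return List::create(_["x"] = x, _["Am"] = M_PI * d2,
                      _["Cm"] = 2.0 * x / d2,
                      _["sina"] = 2.0 * x * ym / d2,
                      _["cosa"] = (ym * ym - x * x) / d2);
}

static List triout_to_list(const TriOut& o, double VmS, double ym,
                           bool converged, int iters) {
  NumericVector Tm = NumericVector::create(
    _["LV"] = o.lv.Tm, _["RV"] = o.rv.Tm, _["S"] = o.s.Tm);
  NumericVector Am = NumericVector::create(
    _["LV"] = o.lv.Am, _["RV"] = o.rv.Am, _["S"] = o.s.Am);
  NumericVector Cm = NumericVector::create(
    _["LV"] = o.lv.Cm, _["RV"] = o.rv.Cm, _["S"] = o.s.Cm);
  NumericVector eps = NumericVector::create(
    _["LV"] = o.lv.eps, _["RV"] = o.rv.eps, _["S"] = o.s.eps);
  NumericVector Ls = NumericVector::create(
    _["LV"] = o.lv.Ls, _["RV"] = o.rv.Ls, _["S"] = o.s.Ls);
  return List::create(_["converged"] = converged, _["VmS"] = VmS, _["ym"] = ym,
                      _["Rx"] = o.Rx, _["Ry"] = o.Ry, _["Tscale"] = o.Tscale,
                      _["p_LV"] = o.pLV, _["p_RV"] = o.pRV, _["Tm"] = Tm,
                      _["Am"] = Am, _["Cm"] = Cm, _["eps_f"] = eps,
                      _["Ls"] = Ls, _["iterations"] = iters);
}

// assemble a pseudo-state carrying wall Lsc/Gamma for the three walls
static void fill_wall_state(double* yst, NumericVector Lsc, NumericVector Gamma) {
  for (int i = 0; i < NSTATE; ++i) yst[i] = 0.0;
  yst[2 * W_LV] = Lsc[0]; yst[2 * W_LV + 1] = Gamma[0];
  yst[2 * W_RV] = Lsc[1]; yst[2 * W_RV + 1] = Gamma[1];
  yst[2 * W_S] = Lsc[2]; yst[2 * W_S + 1] = Gamma[2];
}

// [[Rcpp::export]]
List cv_triseg_residual(double VmS, double ym, double V_LV, double V_RV,
                        NumericVector Lsc, NumericVector Gamma,
                        NumericVector parms) {
  double yst[NSTATE];
  fill_wall_state(yst, Lsc, Gamma);
  TriOut o;
  if (!triseg_eval(VmS, ym, V_LV, V_RV, yst, REAL(parms), &o))
    return List::create(_["converged"] = false);
  return triout_to_list(o, VmS, ym, true, 0);
}

// [[Rcpp::export]]
List cv_triseg_solve(double V_LV, double V_RV, NumericVector Lsc,
                     NumericVector Gamma, NumericVector parms,
                     double VmS0 = NA_REAL, double ym0 = NA_REAL,
                     double tol = 1e-8, int maxit = 50) {
  double yst[NSTATE];
  fill_wall_state(yst, Lsc, Gamma);
  SolveWS ws;
  ws_init(&ws, VmS0, ym0);
  TriOut o;
  bool ok = triseg_solve(V_LV, V_RV, yst, REAL(parms), &ws, &o, tol, maxit);
  if (!ok) return List::create(_["converged"] = false);
  return triout_to_list(o, ws.VmS, ws.ym, true, NA_INTEGER);
}
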