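// Cross-bridge cycling myofilament mechanics (Rice-2008-style reduced
// formulation): regulatory-unit activation N <-> P, pre/post-rotation
// strongly-bound cross-bridge states, mean-strain ODEs, troponin Ca binding,
// normalized active force, contractile ATP consumption rate, and
// sarcomere-length dynamics under isotonic load or an isosarcometric clamp.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

enum { jN = 0, jP, jPreR, jPostR, jxPreR, jxPostR, jTCa, jSL, jIntf, MNSTATE };
static const char *MSTATE_NAMES[MNSTATE] = {
  "N_xb", "P_xb", "XB_PreR", "XB_PostR", "xXB_PreR", "xXB_PostR",
  "TCa_Tot", "SL", "intf"
};

struct MechParams {
  double x0, SL0, SLmin, SLmax, mass, visc;
  double fapp, gapp, gslmod, hf, hfmdc, hb, gxb, sigmap, sigman, xPsi;
  double kon, koff, perm50, nperm, knp, kpn, inprmt_max, tca_floor;
  double PCon, PExp, force_scale, max_vel;
  double len_thin, len_thick, len_hbare;
};

static double getp(const NumericVector &p, const char *nm) {
  if (!p.containsElementNamed(nm))
    stop("mechanics parameter '%s' missing", nm);
  return as<double>(p[nm]);
}

static MechParams mk(const NumericVector &p) {
  MechParams q;
  q.x0 = getp(p, "x0"); q.SL0 = getp(p, "SL0");
  q.SLmin = getp(p, "SLmin"); q.SLmax = getp(p, "SLmax");
  q.mass = getp(p, "mass"); q.visc = getp(p, "viscosity");
  q.fapp = getp(p, "fapp"); q.gapp = getp(p, "gapp");
  q.gslmod = getp(p, "gslmod"); q.hf = getp(p, "hf");
  q.hfmdc = getp(p, "hfmdc"); q.hb = getp(p, "hb"); q.gxb = getp(p, "gxb");
  q.sigmap = getp(p, "sigmap"); q.sigman = getp(p, "sigman");
  q.xPsi = getp(p, "xPsi");
  q.kon = getp(p, "kon"); q.koff = getp(p, "koff");
  q.perm50 = getp(p, "perm50"); q.nperm = getp(p, "nperm");
  q.knp = getp(p, "knp"); q.kpn = getp(p, "kpn");
  q.inprmt_max = getp(p, "inprmt_max"); q.tca_floor = getp(p, "tca_floor");
  q.PCon = getp(p, "PCon"); q.PExp = getp(p, "PExp");
  q.force_scale = getp(p, "force_scale");
  q.max_vel = getp(p, "max_vel");
  q.len_thin = getp(p, "len_thin"); q.len_thick = getp(p, "len_thick");
  q.len_hbare = getp(p, "len_hbare");
  return q;
}

// Thick-filament single-overlap fraction (piecewise-linear in SL).
static double sovf_thick(double SL, const MechParams &q) {
  double ze = std::min(q.len_thick / 2.0, SL / 2.0);
  double cle = std::max(SL / 2.0 - (SL - q.len_thin), q.len_hbare / 2.0);
  double sovr = std::max(ze - cle, 0.0);
  return 2.0 * sovr / (q.len_thick - q.len_hbare);
}

// Duty fractions of the attached states in the base (unmodified-rate) cycle
// P -> PreR -> PostR -> P; used to normalize force and scale strain kinetics.
static void duty_fractions(const MechParams &q, double *dutyPreR,
                           double *dutyPostR) {
  // steady state of: dPreR = fapp*P + hb*PostR - (gapp+hf)*PreR
  //                  dPostR = hf*PreR - (hb+gxb)*PostR,  P = 1 - PreR - PostR
  double r = q.hf / (q.hb + q.gxb);          // PostR / PreR
  double pfrac = ((q.gapp + q.hf) - q.hb * r) / q.fapp;  // P / PreR
  double denom = pfrac + 1.0 + r;
  *dutyPreR = 1.0 / denom;
  *dutyPostR = r / denom;
}

struct MechRates {
  double knpT, kpnT, fappT, gappT, hfT, hbT, gxbT, sovf;
};

static MechRates mech_rates(const double *y, const MechParams &q) {
  MechRates r;
  r.sovf = sovf_thick(y[jSL], q);
  double tca = std::max(y[jTCa], q.tca_floor);
  double permtot = sqrt(1.0 / (1.0 + pow(q.perm50 / tca, q.nperm)));
  double inprmt = std::min(1.0 / permtot, q.inprmt_max);
  r.knpT = q.knp * permtot;
  r.kpnT = q.kpn * inprmt;
  r.fappT = q.fapp;
  r.gappT = q.gapp * (1.0 + (1.0 - r.sovf) * q.gslmod);
  double xr = y[jxPreR] / q.x0;
  double hfarg = ((y[jxPreR] >= 0.0) ? 1.0 : -1.0) * q.hfmdc * xr * xr;
  r.hfT = q.hf * exp(-std::min(std::max(hfarg, -30.0), 30.0));
  r.hbT = q.hb;
  double s = (y[jxPostR] - q.x0) / q.x0;
  double gxarg = ((y[jxPostR] < q.x0) ? q.sigmap : q.sigman) * s * s;
  r.gxbT = q.gxb * exp(std::min(gxarg, 30.0));
  return r;
}

static double active_force_c(const double *y, const MechParams &q) {
  double dPre, dPost;
  duty_fractions(q, &dPre, &dPost);
  return sovf_thick(y[jSL], q) *
         (y[jxPreR] * y[jPreR] + y[jxPostR] * y[jPostR]) / (q.x0 * dPost);
}

// Signed normalized passive (titin-like) force relative to rest length SL0:
// positive above rest (resists stretch), negative below (resists compression).
static double passive_force_c(double SL, const MechParams &q) {
  double d = SL - q.SL0;
  double s = (d >= 0.0) ? 1.0 : -1.0;
  return s * q.PCon * (exp(q.PExp * fabs(d)) - 1.0);
}

// Right-hand side at clamped SL velocity dSLdt (occupancies/strains/troponin).
static void mech_rhs(const double *y, double ca_uM, double dSLdt,
                     const MechParams &q, double *dy) {
  MechRates r = mech_rates(y, q);
  dy[jN] = r.kpnT * y[jP] - r.knpT * y[jN];
  dy[jP] = r.knpT * y[jN] + r.gappT * y[jPreR] + r.gxbT * y[jPostR] -
           (r.kpnT + r.fappT) * y[jP];
  dy[jPreR] = r.fappT * y[jP] + r.hbT * y[jPostR] - (r.gappT + r.hfT) * y[jPreR];
  dy[jPostR] = r.hfT * y[jPreR] - (r.hbT + r.gxbT) * y[jPostR];
  double dPre, dPost;
  duty_fractions(q, &dPre, &dPost);
  dy[jxPreR] = 0.5 * dSLdt +
               (q.xPsi / dPre) * (r.fappT * (0.0 - y[jxPreR]) +
                                  r.hbT * (y[jxPostR] - q.x0 - y[jxPreR]));
  dy[jxPostR] = 0.5 * dSLdt +
                (q.xPsi / dPost) * r.hfT * (y[jxPreR] + q.x0 - y[jxPostR]);
  dy[jTCa] = q.kon * ca_uM * (1.0 - y[jTCa]) - q.koff * y[jTCa];
  dy[jSL] = dSLdt;
  dy[jIntf] = 0.0;  // filled by caller for load-dependent modes
}

// [[Rcpp::export(name = ".mech_state_names")]]
CharacterVector mech_state_names_cpp() {
  return CharacterVector(MSTATE_NAMES, MSTATE_NAMES + MNSTATE);
}

// [[Rcpp::export(name = ".mech_rates")]]
List mech_rates_cpp(NumericVector state, NumericVector params) {
  if (state.size() != MNSTATE) stop("mechanics state must have %d elements", MNSTATE);
  MechParams q = mk(params);
  MechRates r = mech_rates(REAL(state), q);
  return List::create(_["knpT"] = r.knpT, _["kpnT"] = r.kpnT,
                      _["fappT"] = r.fappT, _["gappT"] = r.gappT,
                      _["hfT"] = r.hfT, _["hbT"] = r.hbT, _["gxbT"] = r.gxbT,
                      _["sovf"] = r.sovf);
}

// [[Rcpp::export(name = ".mech_derivs")]]
NumericVector mech_derivs_cpp(NumericVector state, double ca_uM, double dSLdt,
                              NumericVector params) {
  if (state.size() != MNSTATE) stop("mechanics state must have %d elements", MNSTATE);
  MechParams q = mk(params);
  NumericVector dy(MNSTATE);
  mech_rhs(REAL(state), ca_uM, dSLdt, q, REAL(dy));
  dy.attr("names") = CharacterVector(MSTATE_NAMES, MSTATE_NAMES + MNSTATE);
  return dy;
}

// [[Rcpp::export(name = ".mech_sovf")]]
double mech_sovf_cpp(double SL, NumericVector params) {
  MechParams q = mk(params);
  if (SL < q.SLmin || SL > q.SLmax)
    stop("SL = %.3f um outside bounds [%.3f, %.3f]", SL, q.SLmin, q.SLmax);
  return sovf_thick(SL, q);
}

// [[Rcpp::export(name = ".mech_duty_fractions")]]
NumericVector mech_duty_cpp(NumericVector params) {
  MechParams q = mk(params);
  double dPre, dPost;
  duty_fractions(q, &dPre, &dPost);
  return NumericVector::create(_["dutyPreR"] = dPre, _["dutyPostR"] = dPost);
}

// Fixed-step integrator driven by a uniformly sampled Ca transient (uM).
// mode: 0 = isotonic (afterload in kPa), 1 = isosarcometric clamp (SL == SL0).
// Strain and SL updates use exponential (exact linear-part) steps so the
// stiff viscous relaxation (viscosity/mass ~ 60 / ms) stays stable at dt 0.1.
// [[Rcpp::export(name = ".mech_run")]]
List mech_run_cpp(NumericVector state0, NumericVector ca_uM, double ca_dt,
                  NumericVector params, int mode, double afterload_kPa,
                  double preload_kPa, double dt, double dt_out) {
  if (state0.size() != MNSTATE) stop("mechanics state must have %d elements", MNSTATE);
  MechParams q = mk(params);
  if (mode == 0 && afterload_kPa <= 0.0) stop("isotonic afterload must be > 0 kPa");
  const long nca = ca_uM.size();
  if (nca < 2) stop("Ca transient needs at least 2 samples");
  const double t_end = (nca - 1) * ca_dt;
  const long total_steps = (long) floor(t_end / dt + 1e-9);
  const long rec_every = std::max(1L, (long) llround(dt_out / dt));
  const long n_rec = total_steps / rec_every + 1;

  double y[MNSTATE], dy[MNSTATE];
  for (int i = 0; i < MNSTATE; ++i) y[i] = state0[i];
  if (mode == 1) y[jSL] = q.SL0;
  // the isotonic rest stop: cell hangs at SL0 against the preload support
  const double SLtop = std::min(q.SLmax, q.SL0);

  NumericVector t_out(n_rec), tension(n_rec), fnorm(n_rec), atp(n_rec),
      sl(n_rec), eql(n_rec), cons(n_rec);
  NumericMatrix occ(n_rec, 4);
  double dPre, dPost;
  duty_fractions(q, &dPre, &dPost);
  const double F_load = (afterload_kPa + preload_kPa) / q.force_scale;

  long rec = 0;
  bool clamped_top = (mode == 0);
  for (long step = 0; step <= total_steps; ++step) {
    double t = step * dt;
    // linear interpolation of the Ca drive
    double u = t / ca_dt;
    long k = (long) floor(u);
    if (k >= nca - 1) k = nca - 2;
    double w = u - k;
    double ca = ca_uM[k] * (1.0 - w) + ca_uM[k + 1] * w;

    MechRates r = mech_rates(y, q);
    double Fa = r.sovf * (y[jxPreR] * y[jPreR] + y[jxPostR] * y[jPostR]) /
                (q.x0 * dPost);
    double Fp = passive_force_c(y[jSL], q);

    if (step % rec_every == 0) {
      t_out[rec] = t;
      fnorm[rec] = Fa;
      // measured axial tension: while latched at the rest stop (or clamped)
      // the cross-bridges bear the force; once the load is lifted the muscle
      // tension equals the afterload (isotonic plateau)
      if (mode == 1 || clamped_top)
        tension[rec] = q.force_scale * Fa;
      else
        tension[rec] = afterload_kPa;
      atp[rec] = r.gxbT * y[jPostR] * r.sovf;
      sl[rec] = y[jSL];
      eql[rec] = y[jSL] / q.SL0;
      cons[rec] = y[jN] + y[jP] + y[jPreR] + y[jPostR];
      occ(rec, 0) = y[jN]; occ(rec, 1) = y[jP];
      occ(rec, 2) = y[jPreR]; occ(rec, 3) = y[jPostR];
      ++rec;
    }
    if (step == total_steps) break;

    // SL dynamics (Eq. of motion: mass * dSL/dt = intf + (SL0 - SL) * visc)
    double dSLdt = 0.0;
    if (mode == 0) {
      double Fnet = F_load - Fa - Fp;  // positive lengthens
      dSLdt = (y[jIntf] + (q.SL0 - y[jSL]) * q.visc) / q.mass;
      // physical bound on shortening/lengthening velocity
      dSLdt = std::min(std::max(dSLdt, -q.max_vel), q.max_vel);
      bool at_top = (y[jSL] >= SLtop - 1e-12);
      bool at_bot = (y[jSL] <= q.SLmin + 1e-12);
      if ((at_top && dSLdt > 0.0) || (at_bot && dSLdt < 0.0)) {
        dSLdt = 0.0;           // held at the stop
        y[jIntf] = 0.0;        // anti-windup of the force integral
        clamped_top = at_top;
      } else {
        clamped_top = false;
      }
      y[jIntf] += dt * Fnet;
    }

    // backward-Euler update of the 4-state chain: (I - dt*A) y+ = y.
    // A's columns sum to zero, so occupancy is conserved exactly and the
    // update is unconditionally stable against strain-boosted rates.
    {
      double A[4][4] = {
        {-r.knpT, r.kpnT, 0.0, 0.0},
        {r.knpT, -(r.kpnT + r.fappT), r.gappT, r.gxbT},
        {0.0, r.fappT, -(r.gappT + r.hfT), r.hbT},
        {0.0, 0.0, r.hfT, -(r.hbT + r.gxbT)}};
      double M[4][5];
      for (int i = 0; i < 4; ++i) {
        for (int jj = 0; jj < 4; ++jj)
          M[i][jj] = (i == jj ? 1.0 : 0.0) - dt * A[i][jj];
        M[i][4] = y[i];
      }
      for (int col = 0; col < 4; ++col) {      // partial-pivot elimination
        int piv = col;
        for (int i = col + 1; i < 4; ++i)
          if (fabs(M[i][col]) > fabs(M[piv][col])) piv = i;
        if (piv != col)
          for (int jj = col; jj < 5; ++jj) std::swap(M[col][jj], M[piv][jj]);
        for (int i = col + 1; i < 4; ++i) {
          double fmul = M[i][col] / M[col][col];
          for (int jj = col; jj < 5; ++jj) M[i][jj] -= fmul * M[col][jj];
        }
      }
      double sol[4];
      for (int i = 3; i >= 0; --i) {
        double acc = M[i][4];
        for (int jj = i + 1; jj < 4; ++jj) acc -= M[i][jj] * sol[jj];
        sol[i] = acc / M[i][i];
      }
      double ssum = sol[0] + sol[1] + sol[2] + sol[3];
      double tot = y[jN] + y[jP] + y[jPreR] + y[jPostR];
      y[jN] = sol[0] * tot / ssum; y[jP] = sol[1] * tot / ssum;
      y[jPreR] = sol[2] * tot / ssum; y[jPostR] = sol[3] * tot / ssum;
    }
    // troponin Ca binding (exact exponential relaxation at fixed Ca)
    {
      double kb = q.kon * ca, krel = kb + q.koff;
      double tinf = kb / krel;
      y[jTCa] = tinf + (y[jTCa] - tinf) * exp(-krel * dt);
    }
    // exponential update for mean strains: dx/dt = a - b x
    {
      double bPre = (q.xPsi / dPre) * (r.fappT + r.hbT);
      double aPre = 0.5 * dSLdt +
                    (q.xPsi / dPre) * r.hbT * (y[jxPostR] - q.x0);
      double ePre = exp(-bPre * dt);
      y[jxPreR] = aPre / bPre + (y[jxPreR] - aPre / bPre) * ePre;
      double bPost = (q.xPsi / dPost) * r.hfT;
      double aPost = 0.5 * dSLdt + bPost * (y[jxPreR] + q.x0);
      double ePost = exp(-bPost * dt);
      y[jxPostR] = aPost / bPost + (y[jxPostR] - aPost / bPost) * ePost;
    }
    // Euler for SL (viscous relaxation time >> dt after the velocity cap)
    if (mode == 0 && dSLdt != 0.0) {
      y[jSL] += dt * dSLdt;
      if (y[jSL] > SLtop) y[jSL] = SLtop;
      if (y[jSL] < q.SLmin) y[jSL] = q.SLmin;
    }
    if (!std::isfinite(y[jSL]) || !std::isfinite(y[jPostR]))
      stop("mechanics integrator failure at t = %.3f ms", t);
  }

  NumericVector final_state(MNSTATE);
  for (int i = 0; i < MNSTATE; ++i) final_state[i] = y[i];
  final_state.attr("names") = CharacterVector(MSTATE_NAMES, MSTATE_NAMES + MNSTATE);
  colnames(occ) = CharacterVector::create("N_xb", "P_xb", "XB_PreR", "XB_PostR");
  return List::create(
      _["time_ms"] = t_out, _["tension_kPa"] = tension, _["force_norm"] = fnorm,
      _["ATP_norm"] = atp, _["SL_um"] = sl, _["eq_length"] = eql,
      _["occupancy_sum"] = cons, _["occupancies"] = occ,
      _["final_state"] = final_state);
}
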