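// Human ventricular myocyte electrophysiology (ten Tusscher-Panfilov 2006
// formulation): membrane potential, 12 sarcolemmal currents, SR calcium
// handling with dyadic subspace and release-channel open fraction.
// Single source of the model equations; exposed both as a right-hand-side
// (for adaptive reference integration from R) and as a fixed-step forward
// Euler + Rush-Larsen integrator (production path).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout (19 states)
enum {
  iV = 0, iM, iH, iJ, iXr1, iXr2, iXs, iR, iS, iD, iF, iF2, iFCass,
  iRbar, iCai, iCaSR, iCaSS, iNai, iKi, NSTATE
};
static const char *STATE_NAMES[NSTATE] = {
  "V", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2", "fcass",
  "Rbar", "Cai", "CaSR", "CaSS", "Nai", "Ki"
};
// gates handled by Rush-Larsen (indices iM..iFCass), 12 of them
static const int NGATE = 12;
static const int GATE0 = iM;

struct TTParams {
  double Cm, Fc, Rgas, Temp, Ko, Cao, Nao, Vc, Vsr, Vss;
  double Bufc, Kbufc, Bufsr, Kbufsr, Bufss, Kbufss;
  double Vmaxup, Kup, Vrel, k1p, k2p, k3, k4, ECsr, maxsr, minsr, Vleak, Vxfer;
  double GNa, GK1, Gto, GKr, GKs, GCaL, knaca, KmNai, KmCa, ksat, gamma_ncx,
         alpha_ncx, knak, KmK, KmNa, GpCa, KpCa, GpK, GbNa, GbCa, pKNa;
  double tauf_vpos_mult;   // tau_f multiplier for V > 0 (steep restitution)
  double tauf_vneg_mult;   // tau_f multiplier for V <= 0 (slowed ICaL recovery)
  double f2_floor;         // plateau floor of f2 inactivation (depth control)
  double tauf2_vneg_mult;  // tau_f2 multiplier for V <= 0 (recovery speed)
  int    s_endo;           // 1 = endocardial s-gate kinetics, 0 = epi/M
};

static double getp(const NumericVector &p, const char *nm) {
  if (!p.containsElementNamed(nm))
    stop("ionic parameter '%s' missing", nm);
  return as<double>(p[nm]);
}

static TTParams make_params(const NumericVector &p) {
  TTParams q;
  q.Cm = getp(p, "Cm"); q.Fc = getp(p, "F"); q.Rgas = getp(p, "R");
  q.Temp = getp(p, "T"); q.Ko = getp(p, "Ko"); q.Cao = getp(p, "Cao");
  q.Nao = getp(p, "Nao"); q.Vc = getp(p, "Vc"); q.Vsr = getp(p, "Vsr");
  q.Vss = getp(p, "Vss");
  q.Bufc = getp(p, "Bufc"); q.Kbufc = getp(p, "Kbufc");
  q.Bufsr = getp(p, "Bufsr"); q.Kbufsr = getp(p, "Kbufsr");
  q.Bufss = getp(p, "Bufss"); q.Kbufss = getp(p, "Kbufss");
  q.Vmaxup = getp(p, "Vmaxup"); q.Kup = getp(p, "Kup");
  q.Vrel = getp(p, "Vrel"); q.k1p = getp(p, "k1p"); q.k2p = getp(p, "k2p");
  q.k3 = getp(p, "k3"); q.k4 = getp(p, "k4"); q.ECsr = getp(p, "ECsr");
  q.maxsr = getp(p, "maxsr"); q.minsr = getp(p, "minsr");
  q.Vleak = getp(p, "Vleak"); q.Vxfer = getp(p, "Vxfer");
  q.GNa = getp(p, "GNa"); q.GK1 = getp(p, "GK1"); q.Gto = getp(p, "Gto");
  q.GKr = getp(p, "GKr"); q.GKs = getp(p, "GKs"); q.GCaL = getp(p, "GCaL");
  q.knaca = getp(p, "knaca"); q.KmNai = getp(p, "KmNai");
  q.KmCa = getp(p, "KmCa"); q.ksat = getp(p, "ksat");
  q.gamma_ncx = getp(p, "gamma_ncx"); q.alpha_ncx = getp(p, "alpha_ncx");
  q.knak = getp(p, "knak"); q.KmK = getp(p, "KmK"); q.KmNa = getp(p, "KmNa");
  q.GpCa = getp(p, "GpCa"); q.KpCa = getp(p, "KpCa"); q.GpK = getp(p, "GpK");
  q.GbNa = getp(p, "GbNa"); q.GbCa = getp(p, "GbCa");
  q.pKNa = getp(p, "pKNa");
  q.tauf_vpos_mult = getp(p, "tauf_vpos_mult");
  q.tauf_vneg_mult = getp(p, "tauf_vneg_mult");
  q.f2_floor = getp(p, "f2_floor");
  q.tauf2_vneg_mult = getp(p, "tauf2_vneg_mult");
  q.s_endo = (int) getp(p, "s_endo");
  return q;
}

// Gate steady states and time constants (Hodgkin-Huxley form).
static void gate_rates(double V, double CaSS, const TTParams &q,
                       double *ginf, double *gtau) {
  // m
  double minf = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2.0);
  double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + exp((V - 50.0) / 200.0));
  ginf[iM - GATE0] = minf; gtau[iM - GATE0] = am * bm;
  // h
  double hinf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2.0);
  double ah, bh;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
  } else {
    ah = 0.057 * exp(-(V + 80.0) / 6.8);
    bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
  }
  ginf[iH - GATE0] = hinf; gtau[iH - GATE0] = 1.0 / (ah + bh);
  // j
  double aj, bj;
  if (V >= -40.0) {
    aj = 0.0;
    bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  } else {
    aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    bj = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  ginf[iJ - GATE0] = hinf; gtau[iJ - GATE0] = 1.0 / (aj + bj);
  // xr1
  double xr1inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  double axr1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  double bxr1 = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  ginf[iXr1 - GATE0] = xr1inf; gtau[iXr1 - GATE0] = axr1 * bxr1;
  // xr2
  double xr2inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  double axr2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  double bxr2 = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  ginf[iXr2 - GATE0] = xr2inf; gtau[iXr2 - GATE0] = axr2 * bxr2;
  // xs
  double xsinf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  double axs = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
  double bxs = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
  ginf[iXs - GATE0] = xsinf; gtau[iXs - GATE0] = axs * bxs + 80.0;
  // r
  double rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  ginf[iR - GATE0] = rinf;
  gtau[iR - GATE0] = 9.5 * exp(-pow(V + 40.0, 2.0) / 1800.0) + 0.8;
  // s (transmural variant: endocardial kinetics differ from epi/M)
  if (q.s_endo) {
    ginf[iS - GATE0] = 1.0 / (1.0 + exp((V + 28.0) / 5.0));
    gtau[iS - GATE0] = 1000.0 * exp(-pow(V + 67.0, 2.0) / 1000.0) + 8.0;
  } else {
    ginf[iS - GATE0] = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    gtau[iS - GATE0] = 85.0 * exp(-pow(V + 45.0, 2.0) / 320.0) +
                       5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  }
  // d
  double dinf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  ginf[iD - GATE0] = dinf; gtau[iD - GATE0] = ad * bd + gd;
  // f (voltage inactivation; steep-restitution sets slow it for V > 0)
  double finf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  double tauf = 1102.5 * exp(-pow(V + 27.0, 2.0) / 225.0) +
                200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
                180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  tauf *= (V > 0.0) ? q.tauf_vpos_mult : q.tauf_vneg_mult;
  ginf[iF - GATE0] = finf; gtau[iF - GATE0] = tauf;
  // f2
  double f2inf = (1.0 - q.f2_floor) / (1.0 + exp((V + 35.0) / 7.0)) +
                 q.f2_floor;
  double tauf2 = 562.0 * exp(-pow(V + 27.0, 2.0) / 240.0) +
                 31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
                 80.0 / (1.0 + exp((V + 30.0) / 10.0));
  if (V <= 0.0) tauf2 *= q.tauf2_vneg_mult;
  ginf[iF2 - GATE0] = f2inf; gtau[iF2 - GATE0] = tauf2;
  // fCass (calcium-dependent inactivation of I_CaL)
  double fcassinf = 0.6 / (1.0 + pow(CaSS / 0.05, 2.0)) + 0.4;
  double taufcass = 80.0 / (1.0 + pow(CaSS / 0.05, 2.0)) + 2.0;
  ginf[iFCass - GATE0] = fcassinf; gtau[iFCass - GATE0] = taufcass;
}

struct Currents {
  double INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK, IpCa, IpK, IbCa, IbNa;
  double Ileak, Iup, Irel, Ixfer, Ocur, kcasr;
  double total() const {
    return INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK + IpCa + IpK +
           IbCa + IbNa;
  }
};

static Currents currents(const double *y, const TTParams &q) {
  Currents c;
  const double V = y[iV], Cai = y[iCai], CaSR = y[iCaSR], CaSS = y[iCaSS];
  const double Nai = y[iNai], Ki = y[iKi];
  const double RTF = q.Rgas * q.Temp / q.Fc;
  const double EK = RTF * log(q.Ko / Ki);
  const double ENa = RTF * log(q.Nao / Nai);
  const double EKs = RTF * log((q.Ko + q.pKNa * q.Nao) / (Ki + q.pKNa * Nai));
  const double ECa = 0.5 * RTF * log(q.Cao / Cai);

  c.INa = q.GNa * pow(y[iM], 3.0) * y[iH] * y[iJ] * (V - ENa);

  double aK1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
  double bK1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) +
                exp(0.1 * (V - EK - 10.0))) /
               (1.0 + exp(-0.5 * (V - EK)));
  c.IK1 = q.GK1 * sqrt(q.Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

  c.Ito = q.Gto * y[iR] * y[iS] * (V - EK);
  c.IKr = q.GKr * sqrt(q.Ko / 5.4) * y[iXr1] * y[iXr2] * (V - EK);
  c.IKs = q.GKs * y[iXs] * y[iXs] * (V - EKs);

  // L-type Ca current (GHK-like driving term); removable singularity at V=15
  double z = 2.0 * (V - 15.0) * q.Fc / (q.Rgas * q.Temp);
  double drive;
  if (fabs(z) < 1e-7) {
    // limit of z*(0.25*CaSS*e^z - Cao)/(e^z - 1) as z -> 0
    drive = 0.25 * CaSS - q.Cao;
  } else {
    drive = z * (0.25 * CaSS * exp(z) - q.Cao) / (exp(z) - 1.0);
  }
  c.ICaL = q.GCaL * y[iD] * y[iF] * y[iF2] * y[iFCass] * 2.0 * q.Fc * drive;

  double eg = exp(q.gamma_ncx * V / RTF);
  double eg1 = exp((q.gamma_ncx - 1.0) * V / RTF);
  c.INaCa = q.knaca *
            (eg * Nai * Nai * Nai * q.Cao -
             eg1 * q.Nao * q.Nao * q.Nao * Cai * q.alpha_ncx) /
            ((pow(q.KmNai, 3.0) + pow(q.Nao, 3.0)) * (q.KmCa + q.Cao) *
             (1.0 + q.ksat * eg1));

  c.INaK = q.knak * q.Ko * Nai /
           ((q.Ko + q.KmK) * (Nai + q.KmNa)) /
           (1.0 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF));

  c.IpCa = q.GpCa * Cai / (Cai + q.KpCa);
  c.IpK = q.GpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
  c.IbNa = q.GbNa * (V - ENa);
  c.IbCa = q.GbCa * (V - ECa);

  // SR calcium fluxes
  c.Ileak = q.Vleak * (CaSR - Cai);
  c.Iup = (Cai > 0.0)
              ? q.Vmaxup / (1.0 + q.Kup * q.Kup / (Cai * Cai))
              : 0.0;
  c.kcasr = q.maxsr - (q.maxsr - q.minsr) /
                          (1.0 + pow(q.ECsr / CaSR, 2.0));
  double k1 = q.k1p / c.kcasr;
  c.Ocur = k1 * CaSS * CaSS * y[iRbar] / (q.k3 + k1 * CaSS * CaSS);
  c.Irel = q.Vrel * c.Ocur * (CaSR - CaSS);
  c.Ixfer = q.Vxfer * (CaSS - Cai);
  return c;
}

// Full right-hand side. istim in A/F (depolarizing stimulus is negative).
static void rhs(const double *y, double istim, const TTParams &q,
                double *dy, Currents *cout = NULL) {
  Currents c = currents(y, q);
  if (cout) *cout = c;
  double ginf[NGATE], gtau[NGATE];
  gate_rates(y[iV], y[iCaSS], q, ginf, gtau);
  dy[iV] = -(c.total() + istim) / 1.0;  // currents already per unit capacitance (A/F)
  for (int g = 0; g < NGATE; ++g)
    dy[GATE0 + g] = (ginf[g] - y[GATE0 + g]) / gtau[g];
  double k2 = q.k2p * c.kcasr;
  dy[iRbar] = -k2 * y[iCaSS] * y[iRbar] + q.k4 * (1.0 - y[iRbar]);

  // rapid-buffering (chain-rule) factors for free Ca pools
  double bc = 1.0 / (1.0 + q.Bufc * q.Kbufc / pow(y[iCai] + q.Kbufc, 2.0));
  double bsr = 1.0 / (1.0 + q.Bufsr * q.Kbufsr / pow(y[iCaSR] + q.Kbufsr, 2.0));
  double bss = 1.0 / (1.0 + q.Bufss * q.Kbufss / pow(y[iCaSS] + q.Kbufss, 2.0));
  double iVcF2 = 1.0 / (2.0 * q.Vc * q.Fc);
  double iVssF2 = 1.0 / (2.0 * q.Vss * q.Fc);
  double iVcF = 1.0 / (q.Vc * q.Fc);
  dy[iCai] = bc * (-(c.IbCa + c.IpCa - 2.0 * c.INaCa) * iVcF2 * q.Cm +
                   (c.Ileak - c.Iup) * q.Vsr / q.Vc + c.Ixfer);
  dy[iCaSR] = bsr * (c.Iup - c.Irel - c.Ileak);
  dy[iCaSS] = bss * (-c.ICaL * iVssF2 * q.Cm + c.Irel * q.Vsr / q.Vss -
                     c.Ixfer * q.Vc / q.Vss);
  dy[iNai] = -(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * iVcF * q.Cm;
  dy[iKi] = -(c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK + istim) *
            iVcF * q.Cm;
}

static void check_state(const NumericVector &s) {
  if (s.size() != NSTATE)
    stop("ionic state must have %d elements, got %d", NSTATE, (int) s.size());
}

static List currents_list(const Currents &c) {
  return List::create(
      _["INa"] = c.INa, _["IK1"] = c.IK1, _["Ito"] = c.Ito, _["IKr"] = c.IKr,
      _["IKs"] = c.IKs, _["ICaL"] = c.ICaL, _["INaCa"] = c.INaCa,
      _["INaK"] = c.INaK, _["IpCa"] = c.IpCa, _["IpK"] = c.IpK,
      _["IbCa"] = c.IbCa, _["IbNa"] = c.IbNa, _["Iion"] = c.total(),
      _["Ileak"] = c.Ileak, _["Iup"] = c.Iup, _["Irel"] = c.Irel,
      _["Ixfer"] = c.Ixfer, _["O"] = c.Ocur);
}

// [[Rcpp::export(name = ".tt06_currents")]]
List tt06_currents_cpp(NumericVector state, NumericVector params,
                       bool check_finite = true) {
  check_state(state);
  TTParams q = make_params(params);
  Currents c = currents(REAL(state), q);
  if (check_finite) {
    const char *nm[12] = {"INa", "IK1", "Ito", "IKr", "IKs", "ICaL",
                          "INaCa", "INaK", "IpCa", "IpK", "IbCa", "IbNa"};
    double val[12] = {c.INa, c.IK1, c.Ito, c.IKr, c.IKs, c.ICaL,
                      c.INaCa, c.INaK, c.IpCa, c.IpK, c.IbCa, c.IbNa};
    for (int i = 0; i < 12; ++i)
      if (!std::isfinite(val[i]))
        stop("non-finite ionic current %s", nm[i]);
  }
  return currents_list(c);
}

// [[Rcpp::export(name = ".tt06_derivs")]]
List tt06_derivs_cpp(NumericVector state, double istim, NumericVector params) {
  check_state(state);
  TTParams q = make_params(params);
  NumericVector dy(NSTATE);
  Currents c;
  rhs(REAL(state), istim, q, REAL(dy), &c);
  dy.attr("names") = CharacterVector(STATE_NAMES, STATE_NAMES + NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(dy[i]))
      stop("non-finite derivative for state %s", STATE_NAMES[i]);
  return List::create(_["dstate"] = dy, _["currents"] = currents_list(c));
}

// [[Rcpp::export(name = ".tt06_state_names")]]
CharacterVector tt06_state_names_cpp() {
  return CharacterVector(STATE_NAMES, STATE_NAMES + NSTATE);
}

// Fixed-step forward Euler with Rush-Larsen exponential updates for the 12
// Hodgkin-Huxley gates. Records V, Cai, CaSR, CaSS, O at dt_out resolution
// plus a full state snapshot at each beat boundary.
// [[Rcpp::export(name = ".tt06_run")]]
List tt06_run_cpp(NumericVector state0, NumericVector params, double bcl,
                  int n_beats, double stim_amp, double stim_dur, double dt,
                  double dt_out) {
  check_state(state0);
  if (n_beats < 1) stop("n_beats must be >= 1");
  if (bcl <= stim_dur || stim_dur <= 0) stop("need BCL > stim duration > 0");
  TTParams q = make_params(params);

  double y[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = state0[i];

  const long steps_per_beat = (long) llround(bcl / dt);
  const long stim_steps = (long) llround(stim_dur / dt);
  const long rec_every = std::max(1L, (long) llround(dt_out / dt));
  const long total_steps = steps_per_beat * (long) n_beats;
  const long n_rec = total_steps / rec_every + 1;

  NumericVector t_out(n_rec), V_out(n_rec), Cai_out(n_rec), CaSR_out(n_rec),
      CaSS_out(n_rec), O_out(n_rec);
  IntegerVector beat_start_idx(n_beats);  // 1-based row index into outputs
  NumericMatrix snapshots(n_beats + 1, NSTATE);  // state at each beat start + end

  double dy[NSTATE], ginf[NGATE], gtau[NGATE];
  Currents c;
  long rec = 0;
  for (long step = 0; step <= total_steps; ++step) {
    long in_beat = step % steps_per_beat;
    int beat = (int) (step / steps_per_beat);
    if (in_beat == 0 && beat < n_beats) {
      beat_start_idx[beat] = (int) (step / rec_every) + 1;
      for (int i = 0; i < NSTATE; ++i) snapshots(beat, i) = y[i];
    }
    if (step == total_steps)
      for (int i = 0; i < NSTATE; ++i) snapshots(n_beats, i) = y[i];

    if (step % rec_every == 0) {
      Currents cc = currents(y, q);
      t_out[rec] = step * dt;
      V_out[rec] = y[iV];
      Cai_out[rec] = y[iCai];
      CaSR_out[rec] = y[iCaSR];
      CaSS_out[rec] = y[iCaSS];
      O_out[rec] = cc.Ocur;
      ++rec;
    }
    if (step == total_steps) break;

    double istim = (in_beat < stim_steps && beat < n_beats) ? stim_amp : 0.0;
    // Heun (predictor-corrector) for the non-gate states, Rush-Larsen with
    // step-averaged rates for the gates: second-order accurate through the
    // sodium upstroke at dt = 0.02 ms
    static const int nongate[7] = {iV, iRbar, iCai, iCaSR, iCaSS, iNai, iKi};
    double yp[NSTATE], dy2[NSTATE], ginf2[NGATE], gtau2[NGATE];
    rhs(y, istim, q, dy, &c);
    gate_rates(y[iV], y[iCaSS], q, ginf, gtau);
    for (int i = 0; i < NSTATE; ++i) yp[i] = y[i];
    for (int k = 0; k < 7; ++k) yp[nongate[k]] += dt * dy[nongate[k]];
    for (int g = 0; g < NGATE; ++g)
      yp[GATE0 + g] = ginf[g] + (y[GATE0 + g] - ginf[g]) * exp(-dt / gtau[g]);
    rhs(yp, istim, q, dy2, NULL);
    gate_rates(yp[iV], yp[iCaSS], q, ginf2, gtau2);
    for (int k = 0; k < 7; ++k)
      y[nongate[k]] += 0.5 * dt * (dy[nongate[k]] + dy2[nongate[k]]);
    for (int g = 0; g < NGATE; ++g) {
      double gi = 0.5 * (ginf[g] + ginf2[g]);
      double gt = 2.0 / (1.0 / gtau[g] + 1.0 / gtau2[g]);
      y[GATE0 + g] = gi + (y[GATE0 + g] - gi) * exp(-dt / gt);
    }
    if (!std::isfinite(y[iV]) || y[iCai] <= 0.0 || y[iCaSR] <= 0.0 ||
        y[iCaSS] <= 0.0 || y[iNai] <= 0.0 || y[iKi] <= 0.0)
      stop("ionic integrator failure at beat %d, t = %.3f ms", beat + 1,
           step * dt);
  }

  NumericVector final_state(NSTATE);
  for (int i = 0; i < NSTATE; ++i) final_state[i] = y[i];
  final_state.attr("names") = CharacterVector(STATE_NAMES, STATE_NAMES + NSTATE);
  colnames(snapshots) = CharacterVector(STATE_NAMES, STATE_NAMES + NSTATE);

  return List::create(
      _["time_ms"] = t_out, _["Vm_mV"] = V_out, _["Cai_mM"] = Cai_out,
      _["CaSR_mM"] = CaSR_out, _["Cass_mM"] = CaSS_out, _["O"] = O_out,
      _["beat_start_idx"] = beat_start_idx, _["snapshots"] = snapshots,
      _["final_state"] = final_state);
}
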