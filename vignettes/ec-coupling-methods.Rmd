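---
title: "Modeling electromechanical alternans in human ventricular myocytes"
author: "cardalt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling electromechanical alternans in human ventricular myocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and what it is for

`cardalt` simulates how beat-to-beat alternation (alternans) in the electrical
activity of a single human ventricular myocyte translates into alternation of
its mechanical output — tension, sarcomere shortening, and the ATP consumed by
cross-bridge cycling — as the pacing interval (basic cycle length, BCL) is
shortened from 1000 ms toward 200 ms.

The pipeline is strictly **one-way excitation–contraction coupling**: an
electrophysiological stage produces a cytosolic Ca²⁺ transient, and that
transient is the sole input to a myofilament mechanics stage. Mechanics never
feeds back on the membrane model. This isolates the question "what do the
myofilaments do with an alternating Ca²⁺ drive?" at the cost of excluding
mechano-electric feedback (see *Limitations*).

## Electrical stage

The membrane model is the ten Tusscher–Panfilov human ventricular myocyte
formulation with a dyadic Ca²⁺ subspace and a regulated SR release channel:

* membrane potential: `dV/dt = −(I_ion + I_stim)/C_m`, with `I_ion` the sum of
  twelve sarcolemmal currents (`I_Na, I_K1, I_to, I_Kr, I_Ks, I_CaL, I_NaCa,
  I_NaK, I_pCa, I_pK, I_bCa, I_bNa`), each gated by Hodgkin–Huxley variables;
* SR calcium handling: leak `I_leak = V_leak (Ca_SR − Ca_i)`, SERCA uptake
  `I_up = V_maxup / (1 + K_up²/Ca_i²)`, calcium-induced calcium release
  `I_rel = V_rel · O · (Ca_SR − Ca_ss)` through the open fraction `O` of the
  release channel, and subspace-to-cytosol transfer
  `I_xfer = V_xfer (Ca_ss − Ca_i)`;
* rapid-equilibrium Ca²⁺ buffering in cytosol, SR and subspace (the free
  concentration is integrated with the buffering chain-rule factor, which is
  the ODE form of the total-concentration balance).

Three transmural variants — endocardial, mid-myocardial (M), epicardial —
differ in the transient-outward conductance `G_to`, the slow delayed-rectifier
conductance `G_Ks`, and (endocardial only) the recovery kinetics of the `s`
inactivation gate. Parameter sets ship as plain-text key–value files under
`inst/extdata/params/` and load through `ionic_params()`.

### The steep-restitution parameterization

Alternans requires a steep dependence of action-potential duration (APD) on
the preceding diastolic interval. The shipped parameter set is a
**steep-restitution reconstruction** built from the base model by modifying
the L-type Ca²⁺ current and the potassium conductances:

* `tauf_vpos_mult = 2`: the voltage inactivation time constant of `I_CaL`
  (`τ_f`) is doubled for `V > 0`, slowing plateau inactivation;
* `f2_floor = 0.10`: the fast inactivation gate `f2` is deepened (its plateau
  steady state drops from 0.33 to 0.10). Because `f2` recovers with
  `τ ≈ 80 ms` at rest, this concentrates APD rate-adaptation at short
  diastolic intervals — the mechanism that produces both the strong APD
  shortening at fast pacing and the near-fusion alternans regime;
* `G_CaL` ×2.1 restores the Ca²⁺ transient amplitude against the deeper
  inactivation; `G_Kr = 0.172` and per-variant `G_Ks` (0.612 / 0.314 / 0.627
  for endo / mid / epi) set the absolute APD level.

These values were **calibrated against the study's printed steady-state
anchors** — the beat-30 APD90 at BCL 1000 ms (286 / 360 / 287 ms), the
endocardial Ca²⁺ extrema (0.73 / 0.098 µM), and the endocardial APD at BCL
280 ms (203 ms) — because the source publication states only that a
restitution slope of 1.8 was used, without listing parameters, and the
published steep-slope set we could reconstruct independently does not
reproduce those anchors. The calibration targets were exclusively printed
values of the study; the alternans onsets were *not* used as calibration
targets (see *Known limitations*).

### Numerics

The production integrator is fixed-step **Heun (predictor–corrector)** for
membrane potential, concentrations and the release-channel recovery variable,
with **Rush–Larsen exponential updates** (step-averaged rates) for the twelve
gates, at `dt = 0.01 ms`. The step was chosen so that one paced beat agrees
with an adaptive stiff reference (`deSolve::lsoda` over the identical
right-hand side, `rtol 1e-6`) within 0.5 mV in `V_m` and 2 % of the Ca²⁺
peak; plain forward Euler at the conventional 0.02 ms step concentrates a
~7 mV error at the sodium upstroke and was rejected. The `I_CaL` driving term
has a removable singularity at `V = 15 mV` handled by its analytic limit.
Traces are recorded at 0.2 ms.

Every pacing run starts **fresh from the published resting state** — not
continued from the previous BCL — so sweep results are independent of
execution order and trivially reproducible. Beat `k` spans
`[(k−1)·BCL, k·BCL)` in stimulus-aligned time; the stimulus is −52 A/F for
1 ms (twice-threshold convention).

## Mechanical stage

The myofilament model is a reduced Rice-style cross-bridge formulation with
the four regulatory/cross-bridge states the study's schematic names:
non-permissive `N_xb`, permissive `P_xb`, pre-rotation `XB_PreR` and
post-rotation `XB_PostR`, with mean-strain ODEs (`xXB_PreR`, `xXB_PostR`), a
single regulatory troponin pool `TCa_Tot`, and sarcomere-length dynamics.

* **Activation**: `N ⇌ P` with forward rate `K_np (TCa_Tot)^{7.5}` and
  backward rate `K_pn (TCa_Tot)^{−7.5}`, implemented by the smooth sigmoid
  `√(1/(1+(perm50/TCa)^{15}))` (identical to the power law away from
  saturation) with the inverse capped at 100 so the backward rate stays
  finite as `TCa_Tot → 0` (floor `1e-4`). The half-activation point
  `perm50 = 0.66` sets the cooperative differentiation between the weak
  endocardial and strong mid-myocardial Ca²⁺ drives.
* **Cycling**: attachment `f_appT`/`g_appT` (the detachment slowed at low
  filament overlap), rotation `h_fT`/`h_bT` with strain-dependent modifiers,
  and ATP-consuming detachment `g_xbT` accelerated when the post-rotation
  strain deviates from its reference `x_0 = 7 nm`. Rates are the reference
  formulation's base-temperature values.
* **Force**: `F_active = SOVF_thick(SL) · (xXB_PreR·XB_PreR +
  xXB_PostR·XB_PostR) / (x_0 · XB_PostR^Max)`, where `SOVF_thick` is the
  piecewise-linear thick-filament single-overlap fraction and `XB_PostR^Max`
  the optimally-activated duty fraction computed from the base rates.
  Tension in kPa is `force_scale · F_active` with `force_scale = 110`, a
  **calibration constant** chosen so the mid-myocardial pseudo-isometric peak
  at BCL 1000 ms lands near the study's 79 kPa; it rescales all tensions
  equally and is configurable.
* **ATP consumption**: `ATP = g_xbT · XB_PostR · SOVF_thick(SL)`
  (normalized, 1/ms), including the strain dependence of `g_xbT`.
* **Length dynamics**: `dSL/dt = (Integral_Force + (SL_0 − SL)·viscosity) /
  mass`, where the force integral accumulates afterload + preload − active −
  passive (titin-like, zero at the rest length `SL_0 = 2.2 µm`)
  contributions. The cell hangs against a rest-length stop: when fully
  relaxed it sits at `SL_0` (equivalent cell length `SL/SL_0 = 1`), and
  shortening begins when active force exceeds the load. Measured tension
  equals the cross-bridge force while latched and the afterload while the
  load is lifted — the isotonic plateau.

Load conditions follow the study: 10 kPa and 0.6 kPa isotonic afterloads and
1000 kPa as the **pseudo-isometric** condition (the afterload is never
exceeded, so `SL` stays within 1 % of `SL_0`). A true isosarcometric clamp
(`dSL/dt ≡ 0`) is provided additionally and used by the oracle tests.

### Mechanics numerics

`dt = 0.1 ms`, driven by linear interpolation of the Ca²⁺ transient. The
four-state chain uses a **backward-Euler** update (a 4×4 solve per step):
the transition matrix's columns sum to zero, so occupancy is conserved to
machine precision and the update is unconditionally stable even when
strain-boosted detachment rates spike during rapid shortening. Mean strains
and troponin use exact exponential relaxation steps; `SL` uses forward Euler
under a physical velocity bound (`±0.05 µm/ms`) with anti-windup of the
force integral at the length stops; strain-modifier exponents are capped at
±30 to avoid overflow in degenerate states.

The mechanics kinetics (troponin on/off rates scaled ×0.45, cycling rates
×0.8 from the base values, `perm50 = 0.66`) were calibrated against the
study's printed isometric twitch anchors: times-to-peak-tension
228 / 190 / 222 ms and the peak-tension proportions 15 : 79 : 22 kPa across
endo : mid : epi at BCL 1000 ms.

## Metrics and alternans detection

Per beat (relative to its stimulus): APD at 90 % repolarization (from maximum
upstroke velocity to the interpolated crossing; the fraction is configurable),
Ca²⁺ extrema, systolic tension `ST` (beat maximum), diastolic tension `DT`
(minimum over the final 5 % of the beat window — the study does not define
the sampling point), time of peak tension `TPT`, systolic equivalent length
(beat minimum), diastolic length `DL` (end of window), time of peak
(minimum) length `TPL`, ATP-rate extrema and time of peak ATP. A beat whose
potential never exceeds 0 mV is flagged as not captured (stimulus blocked,
as happens to the mid-myocardial cell near BCL 238 ms) and its APD is
undefined rather than zero.

Alternans is called on the two recorded steady-state beats (29 and 30):
electrical if `|ΔAPD| > 2 ms`, Ca²⁺/tension if the peak difference exceeds
2 % of the respective beat amplitude, discordant if the long-APD beat pairs
with the small-Ca beat. The thresholds are configurable; the study states
none, so these defaults are reported in the output metadata. The onset BCL
is refined by bisection to 2 ms after a downward coarse scan, because the
study's reported onsets do not lie on its 30 ms grid.

# The synthetic Ca²⁺ generator

`generate_ca()` produces parametric double-exponential transients
(diastolic level, amplitude, time-to-peak, decay constant, beat-to-beat
alternation ratio, optional Gaussian noise, seeded) so the mechanics stage
and metrics are testable without the ionic model. Defaults emulate the
endocardial steady-state transient at BCL 1000 ms (0.098 µM diastolic,
0.73 µM peak, 25 ms rise, 70 ms decay). The waveform family reproduces the
amplitude/timing structure of the electrical stage's output but not its
subtler features (SR-load memory between beats, rate-dependent diastolic
accumulation, subspace kinetics), so mechanics tests driven by it
demonstrate correct transduction of a given Ca²⁺ drive — not the coupled
rate-dependence, which only the full pipeline exercises.

# Problem sizes

The defaults are the study's protocol: 30 stimuli per BCL with beats 29/30
recorded; 28 BCLs (1000 → 220 ms in 30 ms steps, plus 200 ms); three load
conditions. The test suite reuses a cached run per variant at BCL 1000 ms,
probes onsets with ~30 pacing runs per variant, and sweeps the
pseudo-isometric amplitude curve across all 28 BCLs per variant; the full
three-load sweep (252 coupled runs) lives in `analysis/02_ec_coupling_sweep.R`.

# Design choices where the source is silent

* APD fraction: 0.9 (APD90), configurable (`apd_fraction`).
* Fresh-from-rest initialization per BCL rather than a dynamic-restitution
  continuation: reproducible and order-independent.
* Equivalent cell length: `SL/SL_0`, consistent with a fully-relaxed value
  of 1.
* Preload defaults to the passive force at `SL_0`, which is zero by
  construction because passive force is measured about the rest length.
* Ca²⁺ handed between stages in µM at the electrical output resolution;
  linear interpolation in the mechanics stage.

# Known limitations

* **Alternans onset reading.** With the 2 ms beat-29/30 criterion the
  refined onsets read 280 / 370 / 292 ms (endo / mid / epi), 22–48 ms above
  the study's 258 / 340 / 244 ms. The bifurcation opens gradually
  (endocardial `ΔAPD` ≈ 2 ms at 280 ms but ≈ 40 ms only below 260 ms), so an
  instrumental 2 ms threshold latches onto the top of a micro-alternans
  band, whereas reading the onset off an APD-vs-BCL plot (where a split
  becomes visible at ΔAPD ≈ 15–20 ms) lands 15–20 ms lower. The reading is
  also numerically fragile: sub-millisecond solver differences move it by
  ~10 ms. We report the instrumental value and do not tune the threshold.
* **Onset ordering across variants.** The study places the epicardial onset
  (244 ms) below the endocardial one (258 ms). In every parameterization of
  this model family we explored, the epicardial cell's larger `I_to`
  destabilizes repolarization first, putting its onset at or above the
  endocardial one. The transmural APD and Ca²⁺ anchors are reproduced, but
  not this ordering.
* **APD/BCL during alternans.** The ratio exceeds 0.9 only deep in the
  alternans regime (e.g. endocardial BCL ≈ 250 ms: APD 227/124 ms, ratio
  0.92), matching the study's displayed alternans BCLs, not its onset BCLs;
  near onset the ratio is ~0.75.
* One-way coupling only: no stretch-activated currents, no length-dependent
  Ca²⁺ sensitivity beyond filament overlap.
* The cross-bridge scheme is the reduced four-state chain; multi-state
  biochemical cycles, stochastic gating and tissue-level propagation are out
  of scope.
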