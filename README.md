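# cardalt

Electromechanical alternans in human ventricular myocytes: a one-way
excitation–contraction (E–C) coupling pipeline in R.

When a cardiac cell is paced faster and faster, its action potential duration
(APD) and Ca²⁺ transient can start alternating beat to beat (*alternans*) — a
cellular precursor of arrhythmia. `cardalt` asks what that electrical
instability does to the cell's *mechanical* output. It couples

1. an **electrophysiological stage** — the ten Tusscher–Panfilov human
   ventricular myocyte model (`dV_m/dt = −(I_ion + I_stim)/C_m` with twelve
   sarcolemmal currents and full sarcoplasmic-reticulum Ca²⁺ handling:
   `I_leak = V_leak(Ca_SR − Ca_i)`, `I_up = V_maxup/(1 + K_up²/Ca_i²)`,
   `I_rel = V_rel·O·(Ca_SR − Ca_ss)`, `I_xfer = V_xfer(Ca_ss − Ca_i)`), in a
   steep-APD-restitution parameterization, for endocardial, mid-myocardial
   and epicardial cell variants; with
2. a **myofilament mechanics stage** — a Rice-style cross-bridge model
   (`N_xb ⇌ P_xb ⇌ XB_PreR ⇌ XB_PostR` with cooperative Ca²⁺ activation
   `K_np(TCa_Tot)^7.5`), producing normalized active force
   `F_active = SOVF_thick(SL)·(xXB_PreR·XB_PreR + xXB_PostR·XB_PostR)/(x_0·XB_PostR^Max)`,
   contractile ATP consumption `ATP = g_xbT·XB_PostR·SOVF_thick(SL)`, and
   sarcomere-length dynamics
   `dSL/dt = (Integral_Force + (SL_0 − SL)·viscosity)/mass`
   under isotonic (0.6, 10 kPa) and pseudo-isometric (1000 kPa) loads.

Coupling is strictly one way: the electrical stage's cytosolic Ca²⁺ transient
drives the mechanics; nothing feeds back. The package sweeps the basic cycle
length (BCL) from 1000 to 200 ms in 30 ms decrements (30 stimuli per BCL,
beats 29/30 recorded), computes per-beat metrics (APD90, Ca²⁺ extrema,
systolic/diastolic tension and timing, equivalent cell length, ATP-rate
extrema), detects electrical/Ca²⁺/tension alternans with onset refinement to
2 ms, and builds restitution and tension-amplitude curves. It is intended
for cardiac electrophysiology/biomechanics researchers studying the
mechanical signature of alternans at the single-cell level.

## Worked example

```r
library(cardalt)

run  <- run_paced("endo", stimulus_protocol(bcl = 1000, n_beats = 30))
mech <- run_mechanics(ca_transient(run),
                      load_condition("isotonic", afterload = 1000))

i <- beat_window(run, 30)
j <- beat_window(mech, 30)
m <- beat_metrics(mech$trace$time_ms[j],
                  tension_kPa = mech$trace$tension_kPa[j],
                  atp = mech$trace$ATP_norm[j],
                  eq_length = mech$trace$eq_length[j])

beat_apd(run, 30)$apd_ms                       # APD90 of the last beat
range(run$trace$Cai_uM[i])                     # Ca transient extrema
c(m$st, m$tpt, m$dt, m$dl)                     # tension metrics
refine_alternans_onset("endo",
                       coarse_bcls = c(310, 280, 250))$onset_bcl
```

prints (endocardial cell, BCL 1000 ms, pseudo-isometric load):

```
APD90 (beat 30): 286.1 ms
Ca transient:    0.097 - 0.729 uM
Peak tension:    12.8 kPa at 229 ms after the stimulus
Diastolic tension: 0.051 kPa; equivalent cell length: 1.000
Endocardial alternans onset (2 ms refinement): 280 ms
```

i.e. at slow pacing the cell is electrically stable (beats 29/30 agree), its
Ca²⁺ transient spans 0.10–0.73 µM, the twitch peaks at ~13 kPa some 230 ms
after the stimulus and relaxes fully (diastolic tension ≈ 0, equivalent cell
length 1.0). Shortening the BCL below ~280 ms makes APD, Ca²⁺, tension and
ATP consumption alternate beat to beat, with elevated diastolic tension and
incomplete relaxation — the mechanical signature of alternans.

## The analysis workflow

The study's full analyses are numbered scripts under `analysis/`, each a thin
driver over the package functions, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_electrical_restitution.R` | per-variant APD vs BCL table, restitution slope, refined alternans onsets |
| `02_ec_coupling_sweep.R` | the full 3 × 28 × 3 coupled sweep with persisted traces and summary (slow) |
| `03_tension_amplitude.R` | tension amplitude/peak vs BCL under 1000 kPa, with the maximizing BCL |
| `04_alternans_properties.R` | steady vs alternans regime: diastolic tension, minimum ATP rate, diastolic length |

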