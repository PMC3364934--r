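---
title: "Modelling entrainment of the mammalian cell cycle by the circadian clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling entrainment of the mammalian cell cycle by the circadian clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and design

`cdkclock` simulates a mammalian cell (cyclin/Cdk network) driven by a
circadian clock through three molecular channels -- circadian transcription
of *Wee1* (induced by CLOCK-BMAL1), of *p21* (repressed by REV-ERBα) and of
*cyclin E* (repressed, via c-Myc, by CLOCK-BMAL1) -- and provides the
analysis layer that turns simulated trajectories into the standard readouts
of forced-oscillator studies: locked periods, p:q locking ratios, Arnold
tongues over (autonomous period × coupling strength), peak phases within the
light-dark (LD) cycle, and categorical labels for the failure modes
(endoreplication, tetraploid patterns, complex periodicity, quasiperiodic
drift, chaos).

The published systems that motivate this package are large (a 39-variable
cyclin/Cdk network and a 19-variable circadian clock whose equations live in
supplementary material we deliberately do not transcribe).  `cdkclock`
instead ships *reduced reference models* -- a 13-variable Cdk network and a
4-variable clock -- built so that every qualitative feature the analysis
layer relies on is present and testable:

* ordered, transient activation of cyclin D/Cdk4-6, cyclin E/Cdk2,
  cyclin A/Cdk2 and cyclin B/Cdk1;
* a bistable Cdk1 switch (Wee1/Cdc25 double positive feedback), which makes
  Cdk1 peaks "either minute or very large" -- the bimodality the entrainment
  definition rests on;
* growth-factor gating of oscillation onset (quiescence below a critical
  GF), a pRB/E2F balance with quiescence routes, and a tunable period via a
  single global time-scale;
* a clock that free-runs near 24 h, locks exactly to a 16:8 LD cycle, with
  PER peaking at the end of the light phase and CLOCK-BMAL1 (Bn) peaking in
  the dark phase.

All constants that the source study prints (coupling constants, forcing
protocols, switch values) are used verbatim; everything else is a documented
calibration of the reduced models, chosen once and frozen.

# The Cdk network

State: active pRB (`Rb`), E2F, cyclin D/Cdk4-6 (`Md`), cyclin E/Cdk2 (`Me`),
cyclin A/Cdk2 (`Ma`), total and active cyclin B/Cdk1 (`Cb`, `Mb`), Wee1
protein (`W`), active Cdc25 (`C25`), the APC co-activators Cdh1 (`Ch1`) and
Cdc20 (`A20`) as fractions, p21 (`P`) and an optional ATR/Chk1 checkpoint
activity (`X`).  Units are µM and hours.  The network is organised as two
coupled switches:

* **G1/S module.** GF drives cyclin D synthesis (Michaelian, half-activation
  `K_agf` = 0.2 µM).  Cyclin D and cyclin E phosphorylate pRB; free E2F
  (Hill-repressed by active pRB, `K_IRb` = 0.45 µM, exponent 4) drives
  cyclin E and cyclin A synthesis.  Cyclin A antagonises Cdh1, which
  degrades both cyclin A and cyclin B; the E2F → cyclin A → Cdh1 loop with
  the mitotic reset makes G1 a genuine relaxation phase.
* **Mitotic module.** Cyclin B accumulates while Cdh1 is off (`v_cb` =
  0.055 µM/h, the printed value).  Active Cdk1 is produced from the total
  pool by Cdc25 and removed by Wee1; Cdk1 activates Cdc25 and inactivates
  Wee1 (two positive feedbacks, hence hysteresis: the switch arms at low
  Cdk1 under Wee1 control and fires when cyclin B crosses a Wee1-dependent
  threshold).  Cdk1 then activates Cdc20 through a slow zero-order switch;
  full Cdc20 activation crushes cyclin B and cyclin A, Cdk1 collapses below
  the Cdc25-off threshold, Wee1 recovers and Cdh1 re-activates.

Two numerical hazards shaped the calibration.  First, a *graded* Cdc20
branch acts as an integral controller that clamps Cdk1 at the Cdc20
threshold -- a stable "mixed" state that swallows the limit cycle.  The
shipped set avoids it by making the Cdc20 switch zero-order and slow
(`V_a20` = 10 µM⁻¹h⁻¹, `V_i20` = 0.5 h⁻¹, `K` = 0.005) so mitosis
overshoots to full Cdc20 and escapes.  Second, cyclin B needs a finite
ceiling (`k_db` = 0.04 h⁻¹) so that, under strong circadian Wee1, the
raised mitotic threshold is simply unreachable -- this is what produces
clean endoreplication (Cdk2 cycling daily, Cdk1 flat) at high coupling.

p21 inhibits Cdk2 and Cdk1 as quasi-equilibrium activity factors
`1/(1 + P/K)` (`K_ip2` = 4, `K_ip1` = 2 µM) rather than as explicit inactive
complexes; Wee1 also damps Cdk2 with relative weight `rho2` = 0.1 < 1
("Wee1 inhibits Cdk1 more than Cdk2").  The DNA-replication checkpoint is a
reduced stand-in: `X` is activated at rate `k_aatr` proportionally to
S-phase Cdk2 activity and divides the Cdc25 activation rate by
`1 + X/K_xc`; it slows the cycle monotonically (10.7 → 12.4 h at s = 1 as
`k_aatr` goes 0 → 0.075 µM⁻¹h⁻¹) but does not reproduce the full model's
checkpoint-induced tetraploidy.

**Time-scale.** Every Cdk-network derivative is multiplied by a global
dimensionless factor `s`, so the autonomous period obeys `T(s) = T(1)/s`
exactly; `calibrate_timescale()` is therefore exact arithmetic plus a
verification integration.  The printed eps/period pairs of the source study
(21.58 × 20 = 431.6 and 15.37 × 28 = 430.4, equal to 0.3%) are the evidence
that this uniform-scaling reading is faithful.  Clock-driven mRNA balances
are *not* scaled by `s` (they belong to the circadian side); the protein
equations that receive their synthesis terms are.

The default set has `T(1)` ≈ 10.7 h, coefficient of variation of the cycle
< 0.5%, a GF threshold of ≈ 0.37 µM, quiescence with low Cdk1 for
`v_spRB` ≥ 1 µM/h (bifurcation at ≈ 0.955), and mitotic peaks 60-fold above
the interphase Cdk1 floor.  One known deviation: raising the Cdc25 pool
(`v_spbi`) accelerates cycling with an elevated Cdk1 floor instead of
producing the full model's high-Cdk1 quiescent state.

# The circadian clock

State: Per mRNA (`Mp`), PER protein, Rev-Erbα mRNA (`Mr`) and nuclear
REV-ERBα (`Rn`), in nM.  CLOCK-BMAL1 is algebraic:

`Bn = B_tot · K_BP/(K_BP + PER) · K_RB^4/(K_RB^4 + Rn^4)`

A two-stage mRNA/protein loop with monotone kinetics cannot oscillate on its
own (the Jacobian trace is strictly negative), so the PER degradation
saturates *and* is protected at high PER --
`v_dP·P/(K_dP + P + P²/K_st)` -- a reduced account of PER-CRY complex
formation shielding PER from degradation.  This gives the Per loop a
folded nullcline and a robust free-running rhythm (23.56 h for the default
set, within the required 22-26 h band).  Light adds the printed increment
(0.3 nM/h) to Per transcription during the 16 h light phase; the locked
solution has period 24.000 h (interval CV = 0), PER peaking at 14.1 h
(final third of L) and, through the delayed REV-ERBα veto on Bn, the Bn peak
at 23.4 h -- inside the dark phase and 9.3 h from the PER peak (antiphase
within the 12 ± 3 h band).  REV-ERBα peaks 6.2 h after Bn (mRNA
intermediate).  The Bn trough itself sits mid-morning, shaped by the Rn
loop rather than by PER alone.

Amplitudes are calibrations with a purpose: Bn spans 0.23-1.8 nM so the
printed constants K_aw = 2 nM (Wee1 induction, Hill 4) and K_ice = 1 nM
(cyclin E repression, Hill 4) sit on the sensitive flanks of their curves,
and Rn spans 0.03-0.43 nM around the printed K_ip21 = 0.05 nM.  Because Bn
enters the clock only through Bn/K_ar and Rn only through Rn/K_RB, both
scales are exact free parameters; they were the primary knobs for setting
the coupling strength regime.  "Cry deletion" is emulated by clamping Bn to
2 nM: the clock is then arrhythmic, Wee1 mRNA rises by ≈ 33% over its
entrained maximum and the entrained cell slows from 24 h to ≈ 40 h.

# Coupling and protocols

The three channels follow the printed kinetics exactly: Wee1 mRNA is
Hill(4)-induced by Bn (`v_sw`, K_aw = 2 nM) and feeds Wee1 protein at
k_sw = 5 h⁻¹; p21 mRNA is repressed by Rn (K_ip21 = 0.05 nM, exponent 1)
and feeds p21 at v_s1p21 = 50 h⁻¹; cyclin E mRNA is Hill(4)-repressed by Bn
(K_ice = 1 nM) and feeds cyclin E at k_ce2 = 5 h⁻¹.  All mRNA degradations
are Michaelian with the printed V/K pairs (0.5/0.5).  In multi-coupling
(µ) mode the three maximal transcription rates are pinned to 1 µM/h and
multiplied by a single µ; the constructor enforces this.

One protocol decision matters enough to highlight.  The coupling equations
*replace* the constitutive Wee1 synthesis of the autonomous model, and the
printed checkpoint protocol states the basal rate is zero in the coupled
system.  `cdkclock` therefore calibrates the autonomous period with basal
Wee1 synthesis present (`v_swee1` = 0.06 µM/h) and runs the full-strength
Wee1-coupled protocols with `v_swee1` = 0.  This is not a detail: with the
basal floor retained, the nightly Wee1 trough can never drop below the
autonomous level, so coupling can only *delay* mitosis and a 28 h cell can
never be accelerated to 24 h.  With the circadian balance replacing the
basal one, the trough threshold dips below the autonomous one and
entrainment works from both sides: 20 h → 24.000 h and 28 h → 23.997 h at
the printed v_sw = 0.1 µM/h.  The 2:1 regime (38 h → 48.0 h) is found by
scanning v_sw with the basal rate retained, where the 48 h tongue sits at
v_sw ≈ 0.046-0.06 µM/h.

Where the locked mitosis falls in the LD cycle differs between the two
sides of the tongue: the 20 h cell anchors at 8.0 h (second half of L, as
observed in vivo and in the source study), while the 28 h cell anchors on
the rising flank of Wee1 at ≈ 22 h, in the dark phase.  This is a
structural property of the reduced clock -- its Bn minimum is pinned near
the PER peak (≈ 14 h), so the Wee1 *rise* that anchors from-above
entrainment always occurs in the dark -- and is the one phase fact of the
source study the reduced model does not reproduce.

# Classification

`classify_dynamics()` is a decision cascade on the Cdk1/Cdk2 observables
after a transient (default 240 h): quiescent (only sub-prominence or
relative-amplitude-below-5% variation), endoreplication (large 24 h-periodic
Cdk2, all Cdk1 peaks minute), entrained_24 / entrained_48 (both observables
show one large peak per period, interval CV < 2%, mean within 1% and phase
drift < 0.05 h per forcing cycle), tetraploid_pattern (periodic, two large
Cdk2 peaks per Cdk1 peak), complex_periodic (p:q commensurate with the
forcing, or a finite multi-point stroboscopic section), chaotic
(stroboscopic cap exceeded *and* twin-trajectory divergence -- quasiperiodic
sections without divergence map to unlocked), else unlocked.

Choices worth recording:

* "Minute vs large" is relative, never an absolute µM cutoff: a bimodal
  largest-gap split in log-amplitude within Cdk1 (≥ 5-fold separation), with
  a cross-observable fallback (all-minute if the tallest Cdk1 peak is below
  10% of the tallest Cdk2 peak).  This keeps the classifier invariant to a
  uniform rescaling of all amplitudes.
* Because the time-scale calibration makes autonomous periods exactly
  rational multiples of 24 h, an *uncoupled* 16 h cell is genuinely 48 h
  periodic as a compound system and is labelled complex_periodic rather
  than unlocked; regression tests for too-weak coupling therefore assert
  "not entrained" rather than an exact label.
* The synthetic fixture generator (`synthetic_trace()`) builds bump trains
  with known ground truth over periods {12, 24, 36, 48} h, tall/short
  alternation ratios {1, 10, 100} and jitter {0, 1%}; the classifier is
  exact on this grid, which is what a green classifier test does and does
  not establish: it validates the decision cascade on idealised peak
  geometry, not the dynamics that produce it.

# Numerical engine

No ODE solver package is assumed; the integrator is an adaptive embedded
Dormand-Prince 5(4) pair in C++ with step-size control on a mixed
absolute/relative error norm (defaults rel 1e-7, abs 1e-9), exact landing on
output-grid points, event times and LD switch times, and clipping of
truncation-level negative concentrations only.  The shipped reduced models
are only moderately stiff (the Goldbeter-Koshland switches use finite
Michaelis constants), and the tolerance-halving invariant (reported periods
move < 0.1%) holds, so an implicit stiff solver was not needed; the
design keeps the rhs pluggable, and user models supplied as R functions run
through the same stepper.  Compiled and R implementations of every shipped
rhs are cross-checked against each other in the test suite, so the fast
path never silently diverges from the readable one.

# Budget and grids

The default per-cell budget for tongue scans is a 240 h transient plus a
720 h analysis window (≥ 15 cycles of a 48 h lock); full-resolution grids
(period 4-60 h step 2; coupling logarithmic, 12 points per decade) are
practical (a 29 × 16 grid takes a few minutes with the compiled engine),
while the test suite uses documented coarse grids to stay inside its
budget -- the assertions there are area comparisons and tongue-shape facts,
not boundary positions.  Acceptance quantities are recomputed from scratch
by `scripts/acceptance.R` in a few seconds.

# Known limitations

* The reduced models reproduce the qualitative regime structure, not the
  printed tongue boundaries: the weak-coupling tongues are narrower (the
  printed Fig-5-level strengths fall outside them), endoreplication needs
  v_sw ≈ 1 µM/h rather than 0.3, the printed µ values for multi-coupling
  sit below the reduced model's lock window (µ ≈ 0.05 locks Cdk1 at 24 h),
  and the p21-mode 6.5% strength increase does not flip the 48 h lock to
  24 h.
* Where the full system shows forced chaos, the reduced one shows
  quasiperiodic drift (stroboscopic sections fill without twin-trajectory
  divergence).
* The high-Cdk1 quiescent state under raised Cdc25 synthesis does not exist
  in the reduced network, and the from-above entrained phase sits in the
  dark phase (see above).
* Forcing is strictly unidirectional (no mitotic shutdown of clock
  transcription), per scope.
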