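---
title: "A stochastic calcium-spark model of EAD-driven arrhythmias: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic calcium-spark model of EAD-driven arrhythmias: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`eadsim` simulates a phenomenological rabbit ventricular myocyte in which the
only source of beat-to-beat randomness is the recruitment and extinction of
calcium sparks at junctional ryanodine-receptor (RyR) clusters.  The cell
carries `Nb` junctional clusters; `nb(t)` of them host an active spark.  Over
a step `dt` the count evolves by two binomial draws,

\[
n_b(t+\Delta t) = n_b + B(N_b - n_b,\ \alpha_b \Delta t) - B(n_b,\ \beta_b \Delta t),
\]

where the recruitment rate \(\alpha_b = \alpha_0\, p_O\, S(c_{srb})\) requires
an open L-type channel trigger (spark-off open fraction \(p_O\)) and
releasable junctional SR calcium (a Hill load factor
\(S(c) = c^2/(c^2 + K_{sr}^2)\)), and the extinction rate \(\beta_b = 1/30\)
ms\(^{-1}\) encodes a ~30 ms spark lifetime.  In the infinite-cluster limit
the fraction \(p_b = n_b/N_b\) obeys
\(dp_b/dt = \alpha_b (1-p_b) - \beta_b p_b\); this deterministic variant is a
first-class simulation mode, not an approximation bolted on afterwards.

Calcium is tracked in four well-mixed compartments: cytosol and SR, each
split into the neighbourhoods of junctional (J) and non-junctional (NJ)
clusters (`cb`, `ci`, `csrb`, `csri`, all in µM).  Release from J clusters is
\(J_{rb} = g_b\, c_{srb}\, p_b\); SERCA uptake follows a Hill form with
exponent 2; diffusive exchange between J and NJ spaces is linear relaxation
with time constants `tau_c` (cytosol) and `tau_sr` (SR); buffering uses the
instantaneous-buffer approximation with a constant factor per compartment.
Fluxes are expressed per destination-compartment volume, so each update
carries an explicit volume ratio and the buffer-weighted total
\(\sum_k v_k c_k / \beta_k\) is conserved exactly when the membrane fluxes
are switched off — a property the test suite checks to 10⁻⁶ over 10⁴ steps.

The L-type current uses a ten-state Markov scheme: two closed states, one
open state and two inactivated states, duplicated into a "spark-off" group
that senses the average junctional calcium `cb` and a "spark-on" group that
faces the ~100 µM microdomain of an active spark.  Calcium-dependent
inactivation enters through
\(a_{24} = a_{24o} + A_{Ca}\,F_{Ca}(c_b)\) with
\(F_{Ca}(c) = 1/(1 + (c_{th}/c)^2)\); spark-on channels use \(F_{Ca}=1\)
exactly.  The two groups exchange at the spark rates \(\alpha_b,\ \beta_b\)
(all corresponding states by default; an option restricts exchange to
open states).  `ACa = 0.15` is the normal condition; reducing it to
`ACa = 0.09` weakens calcium-induced inactivation, enlarges the late L-type
current and puts the cell in the EAD regime.  The remaining sarcolemmal
currents (INa, IKr, IKs, IK1, Ito, INaK, INaCa) follow standard rabbit
ventricular formulations; the sodium–calcium exchanger senses junctional
calcium, which makes it the main conduit from spark noise to membrane
voltage.

Tissue is a monodomain lattice, \(\partial V/\partial t = -I_{ion}/C_m +
D_V \nabla^2 V\) with \(D_V = 10^{-4}\) cm²/ms and \(\Delta x = 0.015\) cm,
integrated by first-order operator splitting: a reaction substep (the full
cell model, per-cell adaptive `dt` of 0.01–0.1 ms) followed by an explicit
5-point diffusion substep with no-flux boundaries implemented by index
clamping, which keeps the discrete operator exactly conservative.  Every
cell owns a counter-based random stream keyed by `(seed, row, col)`, so
results are independent of traversal order and bitwise reproducible.

## Calibration

The phenomenological constants (volumes, buffering, uptake, release and
L-type scales) are not observable one by one; they were fixed by the
package's calibration procedure (`calibrate()`, cyclic coordinate descent
with a fixed seed) against steady-state single-cell statistics: mean APD90
≈ 237 ms, σ ≈ 6.3 ms and cv ≈ 2.7% at CL = 500 ms with `Nb = 4000`, plus the
constraint that the reduced-inactivation model develops EADs near CL ≈ 500
ms while the normal model shows none up to CL = 552 ms.  The calibrated set
ships as `inst/params/default.yaml`; `inst/params/ead.yaml` differs only in
`ACa`.

Intracellular sodium can be integrated dynamically, but the shipped
presets clamp it at the calibrated operating point (12 mM): with the
exchanger-dominated plateau the APD is strongly sodium-sensitive, and
dynamic sodium equilibrates over far more beats than any protocol here
runs, which would superimpose a slow secular trend on the stationary APD
statistics the model is calibrated to.

Two calibration findings are worth recording.  First, the mean APD is almost
completely insensitive to the release conductance `gb`: over a beat the
released calcium is set by SR loading, so scaling the release rate only
reshapes the transient.  APD fluctuations therefore do not come from
transient-amplitude noise but from the late spark trickle, whose
cluster-count fluctuations perturb the exchanger current during the slow
plateau descent.  Matching cv = 2.7% at `Nb = 4000` required an
exchanger-dominated plateau (large `gnaca`) and a sparse recruitment scale
(`alpha0` ≈ 0.09 ms⁻¹), i.e. few, strong sparks rather than many weak ones.
Second, a useful division of labour: `pca` (L-type scale) sets the plateau
and mean APD, `gk1` shapes only the terminal repolarization, and `gkr`
controls the repolarization reserve that decides where in cycle length the
EAD regime begins.

## What the model does and does not reproduce

With the shipped calibration the package reproduces, and the acceptance
suite recomputes: the APD90 statistics above; noise damping in tissue
(σ(APD) falling monotonically with lattice size, the mean converging to the
deterministic limit); the deterministic-limit check (an `Nb = 10⁶`
stochastic trace stays within 1 mV RMS of the deterministic trace); an
EAD-notch onset near CL ≈ 500 ms in the stochastic dynamic sweep of the
`ACa = 0.09` model with no notches in the normal model; deterministic EAD
alternans (long EAD beats alternating with short beats) with bistable
coexistence of period-1 and alternating attractors; a tissue S1S2
conduction-block threshold near DI ≈ 25 ms on a 60×3 strip; and, in a paced
50×50 sheet, EAD-driven waveback heterogeneity followed by wavebreak within
a few beats of slowing the pacing from CL 420 to 530 ms.

One documented limitation: the single-cell S1S2 restitution curve of the
EAD-regime model rises steeply at *short* diastolic intervals and saturates
smoothly at long ones, instead of rising abruptly near DI ≈ 350 ms.  As a
consequence the spline map's period-1 fixed point loses stability as the
pacing period *decreases* through ≈ 565 ms, with the supercritical root
structure (one unstable period-1 root flanked by a stable period-2 pair)
rather than the subcritical one (two unstable roots collapsing onto the
stable fixed point).  The alternans, bistability and conduction-block
phenomenology are present, but their map-level signature is oriented toward
fast pacing.  Several mechanisms were explored to move the steep region to
long DI (slower L-type recovery, exchanger-sustained plateau bistability,
repositioned activation window); each either destroyed the normal-model
calibration or failed to relocate the knee, and the package reports the map
transition where the model actually has it.

## Protocol and measurement conventions

* **APD**: upstroke = upward crossing of −20 mV within 10 ms of a stimulus
  (re-armed only after V falls below −50 mV, so plateau oscillations are
  never counted as new upstrokes); APD ends at the −40 mV downward crossing
  (`fixed_mV`, the convention for EAD statistics) or at 90% repolarization
  toward the pre-stimulus baseline (`percent_repol`).  Crossings are
  linearly interpolated.  Beats that never repolarize before the next
  upstroke are censored: flagged, reported at the full interval, excluded
  from mean/σ (population convention for σ).
* **EAD detection**: a local minimum followed by a local maximum, both above
  −40 mV, with a rise of at least 2 mV between upstroke and final
  repolarization.
* **Dynamic sweep**: state (including spark streams) is carried across CL
  changes with no reset; `up_then_down` exposes hysteresis.
* **S1S2**: trials restart from the stored state taken just before the last
  S1 beat, so they are mutually independent.  When the S1 steady state is an
  alternans the conditioning parity is chosen so the in-trial conditioning
  beat repolarizes promptly, which keeps the pre-S2 diastolic interval
  defined over the widest S2 range.  The EAD-onset sweep is run on the
  stochastic model (`Nb = 4000`): near onset the deterministic alternans
  beats are smooth, and it is the stochastic excursions between the
  coexisting branches that produce the arrested-repolarization notch the
  detector looks for — which is also how the reference experiment was done.
* **Tissue S1S2**: the reduced-inactivation strip is 2:1 at S1 = 500 ms, so
  the strip is conditioned at S1 = 560 ms, the nearest cycle length with 1:1
  capture.  Blocked S2 beats report the would-be diastolic interval inferred
  from the S1 conduction delay.
* **Wavebreak**: a snapshot frame is flagged when the activation front
  (depolarized cells, ≥ −20 mV, adjacent to recovered cells, ≤ −60 mV)
  splits into two or more connected components of at least 3 cells.  This is
  a reported diagnostic; the snapshots remain the primary record.

## Numerical choices

Explicit integration with a two-level adaptive step: 0.1 ms while
|dV/dt| ≤ 1 mV/ms, ten 0.01 ms substeps otherwise and during the stimulus.
Hodgkin–Huxley gates use Rush–Larsen updates with all voltage-dependent
quantities tabulated on a 0.05 mV grid (linear interpolation) — the standard
monodomain speedup, and deterministic.  The L-type master equation is
advanced explicitly and renormalized at each stimulus; probability is
conserved to 10⁻⁶ over 10⁵ steps.  Binomial spark draws use exact CDF
inversion when the mean is below 30 and a clamped normal approximation
otherwise; a step whose success probability would exceed 1 is subdivided,
preserving the mean rates.  The diffusion substep refuses to run when
\(D_V \Delta t/\Delta x^2 > 1/4\).  Map analysis uses natural interpolating
cubic splines clamped to their endpoint values outside the sampled DI
domain, a 2000-point root grid with bisection to 10⁻⁶ ms, and a period
classification tolerance of 10⁻³ ms.

## Scale of the shipped experiments

The test and acceptance protocols run at reduced but statistically adequate
sizes chosen as the package's defaults: ~800–2000 beats for APD statistics
(the reference used 15 000), 100–200 beats per CL in sweeps, a 60×3 strip
for conduction block, and a 50×50 sheet over ~30 beats for the wavebreak
demonstration (the reference figure used 100×100).  The figure presets in
`preset_config()` accept `full = TRUE` for the larger versions.

## What passing tests do and do not show

The synthetic fixtures (trapezoid APs, sigmoid restitution sets, maps with
planted period-2 orbits) have exact ground truth and validate the
measurement and map machinery, not cardiac physiology.  The model itself is
phenomenological: it emulates spark-count noise, compartment-averaged
calcium and population-averaged L-type gating, and does not represent
spatially resolved subcellular calcium, calcium waves, single-channel
gating, fibre architecture or tissue heterogeneity.  Agreement with the
calibration targets shows the mechanism is quantitatively plausible, not
that parameter values are unique.
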