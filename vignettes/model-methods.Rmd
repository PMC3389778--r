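---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gpmyocyte)
```

`gpmyocyte` simulates a guinea pig ventricular myocyte as a coupled system of
roughly 75 ordinary differential equations spanning four physiological
layers: membrane electrophysiology, local-control Ca^2+^-induced Ca^2+^
release (CICR), sarcoplasmic-reticulum (SR) and cytosolic Ca^2+^ cycling with
isometric force generation, and mitochondrial energetics.  This vignette
explains the model itself: what each layer assumes, which parameters matter,
how the numerics are handled, and where the boundaries of validity lie.

## The local-control release unit

The heart of the model is the Ca^2+^ release unit (CaRU): one sarcolemmal
L-type Ca^2+^ channel (LCC) facing a cluster of five ryanodine receptors
(RyRs, represented by a single channel carrying five times the unitary flux)
across a dyadic subspace.  Both channels are Markov chains — the LCC has ten
states (a four-step activation chain ending in the open state, duplicated in
an inactivated mode entered by Ca^2+^-dependent (CDI) and voltage-dependent
(VDI) inactivation and left by voltage-dependent recovery), the RyR four
(rested, primed, open, inactivated, with Ca^2+^-cooperative priming of
Hill order four and constant-rate opening, inactivation and recovery).
Because the two channels share the dyad, the model integrates the **joint**
40-state occupancy distribution; the joint state index is
`(lcc_state - 1) * 4 + ryr_state`, mirroring the release-unit diagram.  All
40 occupancies are integrated as ODE states and a normalisation check
(`|sum - 1| < 1e-6`) is enforced on every output sample; we deliberately do
not eliminate one state through the closure relation, preferring simple
indexing with drift monitored by the invariant.

Two modelling assumptions make this tractable:

* **Rapid subspace equilibrium.** Diffusion from the dyad to the cytosol is
  fast (transfer rate `xfer_rate`, ~5×10^3^ ms^-1^) compared with every
  other process, so subspace Ca^2+^ is the algebraic steady state of the
  LCC influx (GHK form, linear in subspace Ca^2+^), the RyR release flux
  (proportional to the NSR-subspace gradient) and the transfer flux.  The
  balance is linear in subspace Ca^2+^ for fixed gating, so each of the four
  dyad configurations (closed/closed through open/open) has a closed-form
  concentration, computed in `subspace_ca()`.  A relaxation oracle in the
  test suite integrates the explicit dyadic ODE to convergence and confirms
  the algebraic solution to 0.1%.
* **JSR merged with NSR.** Junctional SR refilling is assumed fast, so no
  separate JSR compartment exists and local luminal depletion is outside the
  model's scope; release terminates through RyR inactivation, not store
  depletion.

Graded release and the monotonically decreasing voltage dependence of
excitation-contraction coupling gain are emergent: RyR priming rates depend
on the subspace Ca^2+^ of the *configuration the dyad is actually in*, so a
single open LCC at strongly depolarised potentials (small unitary flux)
recruits its RyR cluster with low probability, while the same opening on the
falling phase of the plateau (large unitary flux) recruits it reliably.
This is also why the cytosolic Ca^2+^ transient peaks late in the plateau:
early in the action potential (AP) the driving force is small and coupling
fidelity low; as the plateau repolarises, recruitment accelerates.

The deterministic 40-state master equation has an independent stochastic
oracle, `stochastic_pair_oracle()`: a Gillespie simulation of independent
LCC-RyR pairs under identical rate laws.  Tests require ensemble occupancy
frequencies of 2×10^4^ pairs at clamped conditions to agree with the ODE
(and matrix-exponential) solution within three standard errors.

## Sarcolemmal currents

The non-dyadic membrane model follows the guinea pig Luo-Rudy lineage: fast
Na^+^ current (m^3^hj), inward rectifier, plateau K^+^ current, ATP-sensitive
K^+^ current (conductance rises as cytosolic ATP falls, Hill form), Na^+^/K^+^
pump, sarcolemmal Ca^2+^ pump, and Na^+^/Ca^2+^ exchange with the allosteric
cytosolic-Ca^2+^ activation factor `1/(1 + (Km_act/Ca_i)^2)` — the exchanger
is progressively silenced at diastolic Ca^2+^.  The delayed rectifier is
split into rapid and slow components; the slow component ships in two
selectable formulations (`set_iks_variant()`): the reference two-gate form
(one fast, one four-fold slower activation gate) and the older single-gate
form whose squared gate deactivates faster.  Because diastolic deactivation
of the slow delayed rectifier is the rate-limiting process for AP-duration
restitution, the variant choice directly controls the restitution time
constant; the two-gate form is the reference.

An optional fast transient outward K^+^ current (one activation, one slower
inactivation gate; conductance 0.2 mS/µF when enabled via
`enable_ito_fast()`) is provided for cross-species AP-morphology
experiments.  Guinea pig myocytes lack this current, so it defaults to off.

Sign conventions: outward currents positive, `dV/dt = -(ΣI + I_stim)`;
reversal potentials are recomputed from the instantaneous ionic
concentrations on every right-hand-side call.  The stimulus is a rectangular
-80 µA/µF, 0.5 ms pulse (configurable); the choice is a free one, set to
capture reliably without distorting APD, and the stimulus charge is booked
as a K^+^ flux so long simulations conserve charge.

## Ca^2+^ cycling, buffers and force

SERCA follows the forward-reverse Hill pump of the
excitation-contraction/mitochondrial-energetics lineage with a mild ATP
dependence; its reverse term doubles as the SR leak, so the diastolic
SR load is the concentration at which forward pumping at diastolic Ca^2+^
balances the reverse flux.  Cytosolic buffering (calmodulin, high- and
low-affinity troponin sites) and the NSR calsequestrin buffer are dynamic
ODE states rather than rapid-buffer approximations, because the low-affinity
troponin occupancy doubles as the activation signal of the crossbridge
model.  Total SR Ca^2+^ (free plus calsequestrin-bound) is what the
fractional-release metric is computed from.

Force generation uses the tropomyosin/crossbridge scheme of the same
lineage: six states (two non-permissive, permissive, and one- to
three-crossbridge states), with the non-permissive/permissive transition
controlled by the low-affinity troponin occupancy through a steep
(`perm50`, `nperm`) switch, and force-dependent slowing of Ca^2+^ release
from troponin.  Normalised force is the crossbridge-weighted occupancy
scaled by `force_norm`; `fmax_mn / xs_area` (cross-sectional area
0.013 mm^2^) converts it to stress in mN/mm^2^.  Crossbridge detachment
consumes ATP through the acto-myosin ATPase, which is the dominant cytosolic
ATP sink at high workload.

## Mitochondria

The mitochondrial module keeps the structure of the Ca^2+^-regulated
TCA-cycle/oxidative-phosphorylation lineage: eight TCA intermediates with
Michaelis-Menten rate laws, Ca^2+^-activated isocitrate and α-ketoglutarate
dehydrogenases, NADH produced by three dehydrogenases and consumed by
respiration, a FADH~2~ branch through succinate dehydrogenase, proton
pumping maintaining the inner-membrane potential ΔΨ (an ODE state with
capacitance `cmito`), F~1~F~0~ ATP synthesis driven by ΔΨ and matrix ADP,
an adenine nucleotide translocator, and a proton leak.  The respiration and
synthase fluxes use reduced thermodynamic rate laws (saturating substrate
terms gated by logistic functions of ΔΨ) rather than the full six-state
proton-pump algebra of the source models; the pump algebra's behaviour —
respiratory control by ΔΨ and ADP — is preserved, and the reduced forms are
calibrated at the output level (respiration span across pacing rates, NADH
workload transients).  NADH+NAD^+^ and matrix ATP+ADP totals are conserved
algebraically.

Matrix Ca^2+^ enters through the uniporter (Magnus-Keizer activated-carrier
form, driven by ΔΨ) and leaves through the mitochondrial Na^+^/Ca^2+^
exchanger; a mitochondrial Na^+^/H^+^ exchanger (fixed pH gradient) returns
the co-transported Na^+^ and closes the matrix Na^+^ loop, which the test
suite checks by per-beat flux balance.  Matrix Ca^2+^ is strongly buffered
(free fraction `fm_ca` = 3×10^-4^), which is what makes the mitochondria a
beat-to-beat low-pass filter of cytosolic Ca^2+^: matrix free Ca^2+^ ripples
by a few percent per beat while accumulating slowly across minutes of
changed workload.  The uniporter block experiment is a parameter overlay
(`vuni_scale`, validated to [0,1]) applicable to any protocol.

Energy supply and demand are linked by the creatine kinase shuttle: a single
cytosolic creatine kinase equilibrates ATP/ADP with the creatine phosphate
pool, and the translocator exchanges matrix ATP for cytosolic ADP.

## Parameters and provenance

No complete printed parameter table exists for this model configuration;
the reference set shipped in `inst/extdata/parameters.yaml` was assembled
from three sources, recorded per-parameter in a provenance tag:

* `printed` — values stated outright for this configuration (release-unit
  count 339,000; five-RyR cluster flux; cross-sectional area 0.013 mm^2^;
  the 0.2 mS/µF optional transient-outward conductance).
* `cited-source` — values carried over from the lineage models the modules
  derive from (geometry, buffer constants, exchanger affinities, gate
  kinetics).
* `calibrated` — values constrained here by whole-model behaviour: the
  reference set is required to reproduce the printed whole-cell outputs
  (peak I-V relation, steady-state APD, Ca^2+^-transient timing, removal
  flux fractions, fractional release, recirculation fraction, peak RyR open
  probability, dyadic Ca^2+^ levels, respiration span, uniporter-block
  effects).  Where a source value exists but required adjustment to meet a
  printed output, the tag is `calibrated`.

This mirrors how the model was originally built — current amplitudes were
adjusted to match APD, exchanger affinities to diastolic Ca^2+^ and SR-decay
behaviour, mitochondrial rate limits to high-rate ATP supply — so the
calibrated tags mark exactly the places where whole-cell constraints, not
molecular measurements, pin the numbers.

## Numerics

* **Integrator.** Implicit multistep BDF (`deSolve::vode`) with an
  internally generated full Jacobian; relative tolerance 10^-7^ and
  per-state-scaled absolute tolerance 10^-9^ by default.  The adaptive
  stiffness-switching solver in the same library mis-detects the problem
  class here (the release-unit rates span four orders of magnitude) and
  stalls; plain BDF integrates a 1 Hz beat in tens of milliseconds.  A test
  verifies APD90 moves by less than 0.5 ms when both tolerances are
  tightened tenfold.
* **Discontinuities.** Stimulus edges and clamp steps are never integrated
  across: protocols compile to segments whose boundaries coincide with
  every discontinuity, and the solver restarts at each boundary.
* **Clamp modes.** Voltage clamp fixes V (dV/dt = 0, V set at segment
  entry); AP clamp imposes a piecewise-linear waveform (V integrated from
  the table slope, currents evaluated at the interpolated V).
* **Output grid.** Uniform 1 ms sampling by default; all integral metrics
  (flux fractions, recirculation, charge bookkeeping) use trapezoidal
  quadrature on the output grid.
* **Steady-state pacing.** Beats repeat until the scaled end-diastolic state
  change falls below 10^-4^ (cap 1000 beats).  Slow variables (Na^+^,
  matrix Ca^2+^, NADH) converge last; the shipped initial state
  (`inst/extdata/state_1hz.csv`) was produced by long pre-pacing so that
  analyses restart near the attractor.
* **Degenerate inputs.** Concentrations are floored at 10^-12^ mM inside
  the right-hand side; non-finite rates abort with the offending state
  identified; unnormalised occupancy inputs to the flux functions are
  contract violations, not warnings.

## Interpretation choices worth knowing

* **Open-open subspace maximum.** The algebraic subspace Ca^2+^ of the
  open-LCC/open-RyR configuration is a *conditional* quantity: it is defined
  at every instant whether or not any dyad occupies that configuration, and
  at diastolic potentials (maximal single-channel driving force) it takes
  values that no dyad ever realises because the configuration probability is
  essentially zero there.  The reported metric (`subspace_oo_peak()`)
  therefore conditions on occupancy: the maximum is taken over samples where
  the open-open occupancy is within half of its per-beat maximum, i.e.
  during actual release events, which places it on the AP plateau.
* **Recirculation fraction.** Computed as integrated SERCA resequestration
  over resequestration-plus-NCX-export during relaxation.  At steady state
  this ratio equals the SR-derived share of the Ca^2+^ cycled into the
  transient; the small sarcolemmal-pump flux is booked with the slow
  processes, which is why the recirculation fraction sits a few points above
  the SERCA share of total removal.
* **Restitution convention.** The S1-S2 diastolic interval is measured from
  the APD90 crossing of the S1 beat to the S2 stimulus; APD is measured from
  the maximum-upstroke-velocity time to the chosen repolarisation fraction
  (stimulus-referenced measurement is available via `apd(..., ref =
  "stimulus")`).  Both conventions for the Ca^2+^-transient delay are
  available from `transient_metrics()` (time-to-peak from the stimulus, and
  delay from the V peak).
* **"Accumulated force".** The frequency staircase reports both the peak
  stress of the last beat at each rate and its beat-averaged stress
  (`force_accum`), since either reading of the protocol is defensible.

## What the synthetic inputs do and do not capture

The AP-clamp machinery accepts any two-column waveform;
`synthetic_ap_waveform()` generates idealised guinea-pig-like (slow plateau,
no notch) and canine-like (spike-notch-dome) waveforms used by the tests.
These reproduce the morphological features that matter for release timing —
plateau height and early-repolarisation depth — but not beat-to-beat
variability, electrotonic loading or recording noise of experimental
waveforms, so clamp tests demonstrate the model's sensitivity to AP shape,
not fidelity to any particular recorded cell.

## Known limitations

* No subsarcolemmal compartment: exchanger and pump sense bulk cytosolic
  Ca^2+^.
* No local JSR depletion; release terminates by RyR inactivation only, so
  Ca^2+^-release restitution is shallow (a premature beat shortens APD far
  more than it changes the transient).
* The slow delayed rectifier's kinetics couple APD restitution to the
  frequency-dependence of APD; with the restitution time constant
  calibrated, the APD span across the 3000–300 ms cycle-length staircase is
  compressed relative to measurements (the qualitative staircase —
  monotonic APD shortening, positive force staircase, Na^+^ accumulation —
  is preserved).
* Blocking 75% of the uniporter depresses the mitochondrial Ca^2+^
  transient strongly (≈ −60%) but raises the cytosolic transient only
  ≈ +10%, not the several-fold larger effect seen with acute uniporter
  blockers: with the per-beat mitochondrial return bolus calibrated to
  12.7% of removal, the uniporter simply does not carry enough of each
  beat's Ca^2+^ to dominate the cytosolic amplitude.
* Excitation-contraction coupling gain declines monotonically above
  +10 mV but passes through a shallow maximum near +5..+10 mV rather than
  declining from 0 mV onward.
* The reverse-mode SERCA term that sets the diastolic SR load also sets the
  SR rest-decay rate, which is consequently faster (tens of seconds) than
  the ≈ 80 s the model family reports.
* Mitochondrial ADP under/overshoots are smaller than experimental NADH
  transients suggest (no ADP compartmentation); the steady-state NADH
  redox level varies more steeply with pacing rate than in the source
  lineage.
* β-adrenergic signalling, ROS, the permeability transition pore and
  tissue-level coupling are out of scope.

## Problem sizes used in the shipped analyses

The packaged tests and the acceptance script run the complete protocols at
the sizes a desk-scale reproduction needs: steady-state pacing capped at
300 beats; the voltage-step family at 5 mV spacing (1 mV for the
graded-release continuity check); fourteen S1-S2 diastolic intervals; three
simulated minutes per staircase step; 500 s workload transitions; and
2×10^4^ Gillespie pairs for the stochastic oracle.
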