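# gpmyocyte

An integrative computational model of the guinea pig ventricular myocyte for
R.  The package couples four layers that are usually modelled separately:

* **Electrophysiology** — the guinea pig action potential with the
  Luo–Rudy-lineage complement of membrane currents (fast Na⁺, rapid and slow
  delayed rectifiers, inward rectifier, plateau and ATP-sensitive K⁺
  currents, Na⁺/K⁺ pump, Na⁺/Ca²⁺ exchange with allosteric Ca²⁺ regulation,
  sarcolemmal Ca²⁺ pump, background currents, and an optional fast transient
  outward current for cross-species experiments).
* **Local-control Ca²⁺-induced Ca²⁺ release** — each of the ~339,000 release
  units couples one L-type Ca²⁺ channel (LCC) to a five-RyR cluster through
  a dyadic subspace whose Ca²⁺ is at rapid equilibrium and therefore
  algebraic.  The joint LCC×RyR gating is a 40-state Markov chain
  (10 LCC × 4 RyR states) integrated as ordinary differential equations, so
  graded SR Ca²⁺ release and the monotonically decreasing voltage dependence
  of excitation–contraction coupling gain *emerge* from channel biophysics
  instead of being built in.
* **Ca²⁺ cycling and force** — SERCA uptake into a merged network-SR
  compartment with calsequestrin buffering, dynamic cytosolic buffers, and a
  six-state tropomyosin/crossbridge model producing isometric force and
  consuming ATP.
* **Mitochondrial energetics** — a Ca²⁺-regulated TCA cycle (eight
  intermediates), NADH-driven respiration and proton-motive force, F₁F₀ ATP
  synthesis, adenine nucleotide translocation, the Ca²⁺ uniporter and
  mitochondrial Na⁺/Ca²⁺ and Na⁺/H⁺ exchangers, linked to the cytosol by a
  creatine kinase shuttle.

The distinguishing behaviour of the local-control formulation is that the
timing of Ca²⁺ release follows the shape of the action potential: at the
strongly depolarised potentials early in the guinea pig plateau the
single-channel driving force is small and coupling fidelity low, so release
builds slowly and the Ca²⁺ transient peaks late in the plateau, with force
peaking after repolarisation.  The model reproduces this, together with the
measured partition of cytosolic Ca²⁺ removal among SERCA, Na⁺/Ca²⁺ exchange
and the sarcolemmal pump, and per-beat fractional SR release; restitution,
rate staircases, workload transitions and uniporter-block experiments ship
as first-class protocols (the methods vignette records where the
reconstruction deviates quantitatively from the measured values).

## Worked example

Pace the reference cell to steady state at 1 Hz and characterise the beat:

```r
library(gpmyocyte)

p  <- gp_parameters()
ss <- pace_to_steady_state(p, bcl = 1000, y0 = gp_initial_state("paced_1hz"))
ss
#> <gp_steady: BCL 1000 ms, 2 beats, converged (residual 1.7e-05)>

beat <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 1), p,
                          y0 = ss$state)

apd(beat$time, beat$V)                      # action potential duration (ms)
#> [1] 187.2
transient_metrics(beat$time, beat$cai, beat$V)$delay_from_v_peak
#> [1] 122                                    # Ca peak lags the V peak (ms)
100 * fractional_release(beat)              # % of SR Ca released this beat
#> [1] 32.3
100 * max(beat$p_ryr_open)                  # peak RyR open probability (%)
#> [1] 2.85
ff <- integrated_flux_fractions(beat)       # removal split, Ca-peak -> diastole
round(100 * c(ff$serca, ff$ncx, ff$sl_pump), 1)
#> [1] 65.4 29.4  5.2
```

`autoplot(beat)` shows the stacked AP / Ca²⁺ / subspace-Ca²⁺ / force panels.
Voltage-clamp experiments work the same way:

```r
iv <- ecc_gain_curve(p, y0 = ss$state)      # -40..+60 mV step family
iv$test[which.min(iv$i_cal_peak)]           # test potential of the I-V extremum
autoplot(iv)                                # normalised LCC vs RyR flux peaks
```

and the S1–S2 restitution protocol returns a tibble ready for the
single-exponential fit:

```r
rest <- run_s1s2_restitution(s1s2_protocol(), p, y0 = ss$state)
fit  <- fit_single_exponential(rest$di, rest$apd)
glance(fit)$tau                             # restitution time constant (ms)
#> [1] 121
```

Mechanistic perturbations are parameter overlays: `gp_parameters(vuni_scale
= 0.25)` blocks 75% of the mitochondrial Ca²⁺ uniporter,
`set_iks_variant(p, "zeng95")` switches to the faster-deactivating slow
delayed-rectifier formulation, and `enable_ito_fast(p)` adds the fast
transient outward current that reshapes the early action potential.

A thin command-line wrapper over the same functions ships in
`inst/cli/run.R` (`Rscript run.R pace --bcl 1000 --beats 10 --out pace.csv`).

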