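---
title: "Dynamic gap-junction gating in fibroblast-myocyte coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic gap-junction gating in fibroblast-myocyte coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Cardiac fibrosis surrounds working myocytes with electrically quiet
fibroblasts. When the two cell types couple through gap junctions (GJs),
the fibroblast acts as a leaky capacitor hanging off the myocyte: it drains
charge during the upstroke and early plateau and injects depolarising
current during diastole. Most simulation studies treat the junction as an
ohmic resistor of fixed conductance. Real GJ channels, however, gate with
the transjunctional voltage `V_j`, and during an action-potential (AP)
upstroke `V_j` transiently approaches the full AP amplitude. `fmgap` exists
to quantify what that gating does to fibroblast-myocyte (F-M) coupling:
which part of the gap junctional current it removes, and for which fibrosis
densities and coupling conductances the effect matters.

# The model

## Coupled pair

One ventricular myocyte is coupled to `N` identical fibroblasts in a star
topology (no fibroblast-fibroblast connections):

```
C_myo dV_myo/dt = -I_myo + sum_i I_gap,i + I_stim
C_fib dV_fib,i/dt = -I_fib,i - I_gap,i
I_gap,i = G_j,i * (V_fib,i - V_myo)
```

`I_gap > 0` depolarises the myocyte and hyperpolarises the fibroblast by
the same amount, so charge is conserved at every junction by construction
(one of the test invariants). Units are mV, ms, pA, pF and nS throughout,
so `G*V` is pA and `I/C` is mV/ms; currents cross module boundaries as
cell totals, never per-capacitance.

The myocyte is the Luo-Rudy 1991 (LR1) guinea-pig ventricular model --
fully published, and the classic substrate for mechanistic F-M pair
analyses -- behind a `myocyte_model()` interface so another AP model can be
slotted in without touching the engine. Whole-cell capacitance is 153.4 pF
(the standard 100 um x 11 um cell geometry). The fibroblast is either the
passive RC model (`C_f dV_f/dt = -G_f (V_f - E_f)`) or an active
MacCannell-type membrane with an inward rectifier, a delayed-rectifier K+
current (gates `r`, `s`), an Na+/K+ pump and a background Na+ conductance,
with dynamic intracellular Na+ and K+.

## Four-state V_j gating

A GJ channel is two hemichannels (connexons) in series. Each hemichannel
switches between a high- (H) and a low-conductance (L) state -- neither is
fully closed -- giving four channel states HH, HL, LH, LL. The state
conductances are series combinations `g = gA*gB/(gA+gB)` of the per-side H
or L unitary conductances, and `V_j` divides across the two hemichannels in
proportion to their resistances. Gating is *contingent* by default: the
voltage each gate senses depends on the partner's state through that
divider (an independent-gating switch is provided for comparison). Each
gate's closing and opening rates are exponential in the sensed voltage:

```
rate_HL = lambda * exp( A_close * (P*v - V0))
rate_LH = lambda * exp(-A_open  * (P*v - V0))
```

so the single-gate equilibrium is a Boltzmann with midpoint `V0` and slope
`1/(A_open + A_close)`. A junction of `N_C` channels is propagated as
mean-field occupancy fractions `f_HH..f_LL` through the four-state master
equation, and its conductance is `G_j = N_C * sum f_s g_s`. Stochastic
single-channel gating is deliberately out of scope: the coupling analyses
here use fraction-based conductance, and at `N_C` of tens to hundreds the
mean-field description is the quantity of interest.

The *static* model is the degenerate case `G_j = N_C * g_HH`, i.e. the
dynamic model's maximum; `freeze_gates = TRUE` turns the dynamic model into
exactly that, which the tests exploit as an equivalence oracle.

## Parameter choices and calibration

Unitary conductances follow single-channel measurements: Cx43 100 pS main
/ 25 pS residual per hemichannel (so 50 pS open-channel -- 60 channels give
the 3 nS of the reference pair configuration), Cx45 32 / 8 pS. No
published table fixes the gate-rate parameters, so they are the package's
own calibration, chosen once against the measured steady-state constraints
and then frozen:

* `V0` per isoform is tuned so the *population* half-inactivation voltage
  (midpoint between the `V_j = 0` maximum and the residual plateau; the
  curves have nonzero residuals, so half-of-maximum would be the wrong
  definition) lands inside the measured ranges -- 55-60 mV for Cx43
  (`V0 = 31` gives 57.4 mV) and 23-30 mV for Cx45 (`V0 = 13` gives
  26.9 mV). Note `V0` is a single-gate midpoint in *hemichannel* voltage;
  the series divider and contingent feedback map it nonlinearly to the
  population value, hence the numerical tuning.
* Slopes `1/(A_open + A_close)` are ~7 mV (Cx43) and ~5.6 mV (Cx45),
  within the range of published Boltzmann fits, with the closing rate
  carrying most of the voltage dependence (`A_close >> A_open`) so that
  inactivation accelerates steeply at upstroke-scale `|V_j|` while
  recovery near `V_j = 0` stays slow (~150 ms).
* `lambda` sets the absolute speed and is invisible to every steady-state
  constraint. It was chosen (0.003/ms for Cx43, 0.008/ms for Cx45, the
  faster-gating isoform) so that gating engages within the first few
  milliseconds of an upstroke-scale `|V_j|` excursion -- the regime the
  early/late current decomposition probes.
* Rate exponents are clamped at +/-6, a saturation guard: physically,
  transition rates level off rather than growing without bound, and
  numerically it bounds the fastest gating time constant at ~1 ms.
* Heterotypic orientation: side A = Cx43 (myocyte side), side B = Cx45
  (fibroblast side), with side B sensing the negative of its voltage drop
  (the connexons face each other). Because Cx45 is both more sensitive and
  lower-conductance (so it takes ~76% of `V_j` in the open state), the
  heterotypic curve inactivates preferentially at negative `V_j` -- which
  is the polarity the junction actually sees during the myocyte upstroke
  (`V_j = V_fib - V_myo` swings to about -100 mV).

The MacCannell fibroblast is reproduced from its published formulation;
its background Na+ conductance plays the role it plays in the original --
the free parameter that balances ion homeostasis at the stated resting
potential. With the recalled published value (0.0095 nS/pF) this
implementation's fixed point sits ~2 mV depolarised of -49.6 mV, so
`g_bNa` is calibrated to 0.0086 nS/pF, which holds both the 30-s and the
long-run membrane potential within 1 mV of -49.6 mV. The approach to rest
is slow and two-phased (gate `s` relaxes over seconds, the ion
concentrations over minutes), which is why the resting-potential check
integrates 30 s rather than reading an early plateau.

## Stimulus

Pacing is rectangular: 2-ms pulses at 1 Hz, amplitude 22 pA/pF = 1.5x the
LR1 diastolic threshold measured for that pulse width (~14.6 pA/pF).
Single-beat analyses (everything involving the first-beat early peak) use
one pulse; AP-morphology comparisons are insensitive to beat number in
this non-accumulating model, so the default analyses use the first beat.

# Derived quantities

* **AP metrics**: resting potential is the diastolic minimum preceding
  the upstroke; APD50/90 run from the maximal-dV/dt time to 50%/90%
  repolarisation toward that resting value; the plateau is mean `V_myo`
  between the APD20 and APD50 crossings. Traces without a 40-mV
  deflection report "no AP" rather than numbers.
* **Early/late gap-current decomposition**: the early, transient-outward-
  like component is the largest `|I_gap|` within 10 ms of the upstroke
  (phase 1 of a guinea-pig-class AP; configurable), the late component is
  `I_gap` at the APD50 time (a representative plateau point; the
  literature fixes no number here, so the choice is declared rather than
  inferred).
* **delta I_gap,peak** is the signed difference of early-peak magnitudes,
  dynamic minus static, computed from paired runs whose configurations
  match in everything but the GJ model; it can only be <= 0, since gating
  only inactivates away from the static maximum. The default sweep grid --
  F-M ratios {1, 2, 4, 6, 8} crossing the normal (<= 2) to diseased (> 2)
  fibrosis range, conductances {0.5, 1, 2, 3, 4, 6, 8} nS spanning
  culture-measured F-M coupling -- locates the largest |delta| at high
  ratio and intermediate (2-4 nS) conductance. The mechanism is a
  compromise: at low `G_j` there is little current to lose; at high `G_j`
  the fibroblast tracks the myocyte so closely that `V_j` collapses before
  the gates engage.

# The 1D strand

`strand_config()` builds a discrete chain of LR1 cells (100 um long,
2500 nS myocyte-myocyte junctions, giving 83 cm/s -- the right scale for a
ventricular strand) rather than a continuum PDE; this matches the
cell-network framing of F-M studies and keeps runs at desk scale.
Stimulation drives the first three cells (one cell cannot overcome the
axial load at physiological coupling); activation is the interpolated
upward -20 mV crossing, and CV comes from regressing activation time on
position over the central 50% of the strand. Depolarised, inexcitable
cells that drift across the threshold are not counted as activated, and
any unactivated cell in the window flags conduction block instead of a
velocity.

Fibroblasts enter in one of two topologies, and the distinction turned out
to be the scientifically decisive design choice in this module:

* **inserted** (default for density sweeps): fibroblasts are interspersed
  *in* the conduction path -- seeded Bernoulli counts per myocyte-myocyte
  junction, each inserted cell linked by 750-nS junctions (tissue-level
  F-M coupling, weaker than myocyte-myocyte). The wave must cross
  inexcitable bridges, so CV falls monotonically with the F-M ratio; with
  the default depolarised fibroblast (E_f = -20 mV, G_f = 2 nS) the
  resting depolarisation adds Na+-channel inactivation and the strand
  blocks outright at high density, while with E_f = -80 mV the resting
  potential is untouched and the decline continues smoothly -- the
  interspersed-coculture phenomenology.
* **attached**: fibroblasts hang off individual cells as load, the
  conduction path stays purely myocyte. Here modest chronic
  depolarisation *speeds* conduction (supernormality: the foot of the
  wave starts closer to threshold) until LR1's inward-rectifier
  characteristic gives way and the strand jumps to a depolarised,
  inexcitable state. There is no stable resting branch between ~-75 mV
  and ~-30 mV in this model, so a graded CV decline via resting
  depolarisation is not reachable in the attached topology -- the
  biphasic cell-attached phenomenology, reproduced rather than suppressed.

Attached strands are initialised from the equilibrated coupled-pair
resting state (a 2-s settle per distinct attachment count), because the
chronic load is what the CV measurement is about; inserted strands get a
250-ms whole-strand settle before the stimulus. Both are exact-reproducible
given the seed.

# Numerical choices

* Integration: `deSolve::lsoda`, rtol 1e-6, atol 1e-8 everywhere;
  `hmax` bounded near the stimulus width so pulses are never stepped
  over. Halving the tolerances or doubling the output sampling moves no
  reported quantity beyond its test tolerance.
* Strand Jacobians are banded: states are laid out cell block by cell
  block (myocyte, then its fibroblasts and GJ fractions), so the
  bandwidth is one block and 700-state strands stay cheap.
* Stationary GJ distributions come from a direct linear solve of the
  master equation's null space (with the normalisation row appended);
  time integration is reserved for transients. The two routes agree to
  1e-6 over random `V_j`, which the tests assert.
* `N_C = round(G_j,max / g_HH)` makes the static comparison use exactly
  the dynamic model's realised maximum; paired static/dynamic runs match
  conductance through `realized_gj_max()`, not the requested value.
* The modified-Boltzmann fit (two-sided, shared maximum and residual)
  reports both the raw sigmoid midpoints and the fitted curve's own
  midpoint crossings; the two differ when the branches overlap near
  `V_j = 0` (about 3 mV for Cx45), and only the crossing is comparable
  with the direct half-inactivation estimator.

# Problem sizes

The shipped analyses are sized for a desk machine: single-beat pair runs
(~450 ms) for all early-peak work, a 3 x 7 (ratio x conductance) grid for
the sweep's acceptance summary (the full 5 x 7 default remains available),
60-cell strands with 3 seeds per ratio for CV statistics, and 30-s
integrations for the fibroblast resting potential. These sizes are the
package's defaults because the quantities they estimate are already
converged at that scale: 80-cell strands move CV by < 2%, denser sweep
grids move the argmax conductance not at all.

# What the simulations do and do not show

The generator of "data" here is the model itself; no external recordings
are read. Passing tests therefore demonstrate internal consistency with
the published calibration constraints (resting potentials, half-
inactivation ranges, monotonicities, conservation laws), not agreement
with any particular experiment. Known limitations:

* LR1 is a guinea-pig model with a single lumped Ca2+ current; absolute
  APD and plateau values are model-specific, and Ca2+-driven phenomena
  (alternans, EADs) are outside what this engine can attribute reliably.
* Under sustained fibroblast depolarisation LR1 produces isolated ectopic
  upstrokes followed by depolarisation block, not a sustained limit
  cycle; `detect_spontaneous()` is exercised on that behaviour. Models
  with richer pacemaking dynamics would show trains of spontaneous APs at
  intermediate coupling, as reported for human-cell simulations.
* Mean-field fractions ignore channel-number fluctuations; at very small
  `N_C` (sub-nS junctions) a stochastic description would add noise the
  package deliberately does not model.
* The 1D inserted strand compresses a 2D interspersed coculture into
  serial bridges; it reproduces the monotone CV decline and high-density
  block, but the E_f dependence of the *shape* of that decline is weaker
  in 1D than reported for sheets.
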