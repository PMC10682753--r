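---
title: "Building, optimizing and generalizing single-neuron e-models with emforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building, optimizing and generalizing single-neuron e-models with emforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emforge)
```

## The modelling problem

A single-neuron electrical model (e-model) is a multi-compartment cable
model of a reconstructed morphology carrying Hodgkin–Huxley-style membrane
mechanisms, whose free parameters — mostly maximal conductance densities
(S/cm²) and the intracellular calcium decay constant (ms) — are fitted so
that scalar electrophysiological features (e-features) extracted from
simulated voltage responses match those measured in patch-clamp recordings
of the corresponding electrical type (e-type). emforge implements the whole
workflow: feature extraction with rheobase normalization, multi-objective
evolutionary optimization, somatic and dendritic validation, sensitivity
and currentscape analysis, and a generalization rule that decides which
morphologies of a population an optimized e-model transfers to.

Because no experimental dataset ships with the package, every stage is
exercised on synthetic material: toy morphologies, a library of generic
HH-style channels, and "recordings" produced by simulating a known
ground-truth model. This makes the full pipeline reproducible on a laptop
and gives every test an exact oracle; what it cannot show is robustness to
the idiosyncrasies of real recordings (electrode drift, seal quality,
missing sweeps, inter-animal variability beyond simple parameter jitter).

## Feature extraction and rheobase normalization

Spikes are detected as upward crossings of −30 mV whose onset lies inside
the stimulus window; peaks, afterhyperpolarization (AHP) minima and all
derived features follow the registry definitions documented in
`feature_registry()` (windows such as "the 100 ms before stimulus onset"
for the resting baseline, or "the last 10% of the stimulus" for steady
states, are pinned by the registry and enforced against independent
brute-force oracles in the test suite). `ISI_values` is summarized as the
mean inter-spike interval so every registry entry is a scalar.

Different cells have different input resistances, so absolute stimulus
amplitudes are not comparable across cells. Extraction therefore computes
each cell's rheobase — the lowest amplitude among its IDrest/IDthresh
sweeps that elicits a spike — and expresses every sweep as a percentage of
it. A target at, say, 150% of rheobase with the default 10% tolerance then
averages features over all sweeps whose relative amplitude falls in the
closed window [140, 160]%. Sweeps are first averaged within each cell and
the cell means averaged with equal weight, so cells with many sweeps do not
dominate.

Targets carry a mean and a standard deviation; the per-feature objective is
the Z score |model − mean| / sd. When a target's sd is zero (one
contributing cell, or identical synthetic cells) it is floored at
`0.05 × |mean| + 1e-6` and flagged. We interpret the floor as a minimal
biological coefficient of variation: a much smaller floor (we probed
0.1%) turns the cost landscape into a set of clipped plateaus — almost any
candidate exceeds the 250-point clip on almost every feature and the
resting-potential gate (below) demands sub-millivolt accuracy before any
firing protocol is even scored — which defeats evolutionary search. Five
percent is the order of the narrowest feature CVs seen across cells of one
e-type and keeps the landscape informative without blurring the optimum.

## The simulator

The cable solver discretizes each section into `ceiling(length /
max_seg_length)` iso-potential segments (myelinated sections, being passive
and nearly capacitance-free, use coarse 250 µm segments) and advances the
tree by backward Euler with Hines elimination, with gate states updated by
exact exponential relaxation toward their voltage- (or calcium-) dependent
steady state evaluated at the previous step's voltage. The default step is
0.025 ms; at that resolution halving dt does not change spike counts on the
fixture models, and the per-segment current balance (capacitive + ionic +
axial − injected) closes to 10⁻⁶ nA, which the tests assert. Gate steady
states and relaxation factors are tabulated on a 0.05 mV grid over
[−150, 80] mV and linearly interpolated; the tabulation error is far below
the 0.05 mV accuracy asserted against the analytic RC response. A
simulation whose voltage leaves ±1000 mV is marked diverged and surfaces
upstream as a maximally-scored (not crashed) evaluation.

Channel kinetics use sigmoid steady states and Gaussian-bell time
constants; the shipped library (transient Na, delayed-rectifier and slow K,
Ih, high-threshold Ca, Ca-activated K, and a stochastic Kv) is a set of
package fixture choices spanning the usual functional classes, not a claim
about any published kinetics. The stochastic channel draws its open count
binomially per step (channel count = gbar·area / single-channel
conductance); in deterministic mode it is defined to reproduce the plain
channel exactly, and the mean over stochastic seeds converges to the
deterministic trace, both asserted in tests. The NMDA fraction of synaptic
conductances uses the conventional sigmoidal magnesium block
1/(1 + exp(−0.062 V)·[Mg]/3.57) with [Mg] = 1 mM.

## Model evaluation

`evaluate_emodel()` follows the four-step scheme. (1) The resting membrane
potential from a 500 ms zero-stimulus run. (2) The input resistance from a
fixed −0.04 nA, 3 s step. If either deviates from its target by more than
three standard deviations the evaluation stops and every remaining target
receives the clipped maximum score of 250 — clipping keeps the arithmetic
finite and ranks broken models below all viable ones. (3) Bisection
searches for the holding current that brings the soma to the target holding
potential (tolerance 0.1 mV, ≤30 iterations) and for the threshold current
eliciting at least one spike during a 2 s step (bracket width 0.001 nA);
both searched currents are themselves scored targets. (4) Every relative
protocol is rescaled by the found rheobase, simulated on top of the holding
current, and scored. Validation protocols route features to phases: sAHP
sag features are measured on the afterhyperpolarization that follows the
brief depolarizing step, and IDHyperpol sag features on the hyperpolarizing
phase while firing features use the depolarizing phase. The routing is
applied identically when extracting targets from recordings and when
measuring the model, so the two sides of every Z score use the same window.

The threshold search's spiking predicate can exit a probe simulation as
soon as the somatic voltage exceeds 0 mV inside the stimulus window; this
is an optimization only — the tests compare the bisection result against an
exhaustive ascending scan that never takes the fast path.

During scoring, `evaluate_emodel()` runs both searches at finer resolution
(0.025 mV holding tolerance, 2.5·10⁻⁴ nA threshold bracket) than the
stand-alone search defaults. The searched rheobase rescales every protocol,
so its quantization otherwise propagates roughly one percent of amplitude
noise into every downstream feature — enough to put a stall floor under the
evolutionary search. The synthetic-recording generator searches each
pseudo-cell's rheobase under exactly the evaluation-time conditions (same
pre-stimulus delay and precision), which is what makes the ground-truth
model's self-evaluation exactly zero on noiseless fixtures.

## Optimization

Free parameters are searched with an indicator-based evolutionary algorithm
(IBEA): objectives are normalized per generation by a robust range (pool
minimum to 75th percentile, capped at 2 — a failed individual carrying a
clipped score would otherwise define the whole scale and compress every
viable individual onto a sliver of it, erasing the indicator's resolution
exactly where selection matters), the pairwise additive-ε indicator
I(x, y) is the smallest shift by which x weakly dominates y, fitness is
F(x) = Σ_{y≠x} −exp(−I(y, x)/(c·κ)), and
environmental selection repeatedly removes the worst individual while
adding its contribution back to the survivors. Variation is
simulated-binary crossover (η = 10, p = 0.7) and bounded polynomial
mutation (η = 20, p = 1/n). Parameters are encoded in native units — the
genome is never rescaled — and the canonical budget is 256 offspring × 100
generations, with the best model defined as the minimum summed score over
every individual ever evaluated.

The indicator scaling κ deserves a note. The textbook setting κ = 0.05
proved too flat for the 20–35-objective problems here: with many
objectives, pairwise ε-indicator differences are small and the exponential
fitness barely distinguishes candidates, so desk-scale runs (32 offspring ×
20 generations) stalled far from the optimum. κ = 0.01 sharpens selection
and reliably drives the same budget into the few-percent error regime; it
is the package default and remains configurable.

For e-types with stochastic channels the optimization runs in two stages:
stage 1 disables stochasticity and fits all free parameters on the full
feature set minus the burst number; stage 2 starts from the stage-1
optimum, frees only the stochastic channel conductances, re-enables
stochastic gating and fits burst-number and ISI targets.

`recovery_protocol_suite()` is the compact objective set used by the
package's parameter-recovery experiment: two IDrest amplitudes with seven
firing features each, the high-rate AP waveform step (including the
absolute spike peak, which pins the sodium conductance more sharply than
the onset-referenced amplitude), the hyperpolarizing IV step (sag → Ih),
and the special RMP/Rin/holding/threshold targets. Each fixture conductance
has a distinct signature in this set, which is what makes "recover the
ground truth within 10%" a well-posed check at a 32 × 20 budget.

## Validation and analysis

Dendritic validation injects a 5 ms, 2 nA somatic step and measures the
back-propagating AP amplitude at every dendritic segment midpoint up to
900 µm (apical) / 150 µm (basal) of path distance, and activates 1.5 nS
(apical) / 0.2 nS (basal) double-exponential synaptic conductances at each
dendritic segment, reporting the soma-to-dendrite EPSP amplitude ratio.
Both profiles are fitted with y = A·exp(−x/λ) by Levenberg–Marquardt
(minpack.lm); constant or non-decaying profiles are flagged
ill-conditioned rather than fitted. The λ values obtained on the toy
morphology are properties of that fixture; they are not comparable to any
published cell because they depend entirely on the morphology and channel
distribution.

Sensitivity analysis decreases one parameter at a time by 10, 50 and 90%,
records per-feature absolute score changes against the control, and
reports the ordinary least-squares slope of those differences versus the
perturbation percentage, with the control point (0, 0) included as a
regression point; slopes above 1 are flagged sensitive. The currentscape
decomposition records every mechanism's somatic membrane current under a
150%-rheobase step and normalizes inward and outward currents separately
per time step, so each sign class sums to one wherever its total is
nonzero.

## Generalization

An optimized e-model is applied to a candidate morphology by re-running the
complete four-step evaluation — including a fresh holding and threshold
search — and accepting the pair only if every feature score s_c stays
strictly below max(5, 5·s_e), where s_e is the score of the model's own
exemplar morphology for the same feature. Morphologies on which the
threshold search fails are rejected with reason "subthreshold"; this is the
regime the dendritic fixture reaches when its axon initial segment is
shrunk far enough that the AIS sodium conductance can no longer trigger a
spike within the search bounds. Acceptance fractions are reported per
m-type × e-type cell, alongside a per-combination table of AIS and proximal
dendritic surface areas (first 40 µm of axon; dendritic path length up to
500 µm).

## Synthetic data: what the generator emulates

`generate_recordings()` emulates a patch-clamp session on n pseudo-cells:
each is the ground-truth model with conductances jittered by a fractional
Gaussian (default SD 5%, the scale of within-e-type variability), its own
rheobase found by threshold search using the same pre-stimulus delay as the
sweeps (so the 100% IDthresh sweep is by construction the lowest spiking
sweep and every relative bin is populated), the canonical session protocols
(2 s IDrest/IDthresh at 10 kHz, 50 ms APWaveform at 50 kHz, 3 s IV steps,
Ramp/sAHP/IDHyperpol for validation), and additive Gaussian recording noise
(default 0.25 mV, typical of a good whole-cell recording). Pseudo-cells
whose jitter abolishes spiking are resampled. The generator does not
emulate holding-current drift, bridge-balance errors, temperature
variation, or e-type heterogeneity beyond conductance jitter; passing tests
therefore demonstrate the correctness of the pipeline, not its robustness
to those artifacts.

The single-compartment ground truth (soma 30 µm, leak 10⁻⁴ S/cm² at
−80 mV, NaT/Kdr/Kslow/Ih with free conductances bounded a factor 2.5
around the truth, the expert-bound style used for real fits) fires tonically with adaptation, AHP and an Ih sag at a
rheobase near 0.09 nA. The dendritic ground truth places a nearly passive
soma under a strongly excitable 60 µm AIS (replaced axon, 1,000 µm myelin),
with passive Ih-bearing dendrites and a heavier leak (4·10⁻⁴ S/cm²); the
heavier leak keeps direct somatic depolarization from ever crossing the
spike-detection threshold, so firing genuinely requires the AIS — the
mechanism behind the subthreshold rejection of AIS-shrunken clones.

## Problem sizes

The shipped tests and the acceptance script run the workflow at desk
scale: two noiseless pseudo-cells for target extraction, 32 offspring × 20
generations × 3 seeds for the recovery experiment, 100 randomized traces
for the feature oracles, 10–30 clones for generalization. These sizes were
chosen so the whole suite exercises every code path in minutes while the
statistical checks (recovery in at least 2 of 3 seeds, acceptance
monotone in clone jitter over 5 repetitions) retain enough replication to
be meaningful.

## Known limitations

Temperature/Q10 corrections are folded into the time-constant curves; the
channel library is generic; synaptic transmission is a deterministic
conductance transient (no release stochasticity or short-term plasticity);
clone generation rescales and jitters but does not exchange arbors between
morphologies; and the spike detector is a plain threshold-crossing rule, so
a sufficiently large passive depolarization is indistinguishable from a
spike — the fixtures are built so that regime does not arise in scored
protocols.
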