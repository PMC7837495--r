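---
title: "Multicompartmental Golgi cell models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicompartmental Golgi cell models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(golgicell)
```

# Scope

`golgicell` builds conductance-based multicompartmental models of cerebellar
Golgi cells — the main inhibitory interneurons of the granular layer — and
exposes the full workflow around them: morphology handling, ion channel and
calcium dynamics, an implicit cable solver, dynamic synapses, a protocol
battery, evolutionary conductance fitting with staged validation, and a
calcium-threshold predictor of spike-timing dependent plasticity (STDP) at
the mossy fiber synapses. This vignette documents the model, its
assumptions, the numerical choices, and the places where the design was
genuinely open.

# The cell model

## Morphology

Morphologies are read from SWC (`read_swc()`) or synthesized
(`make_surrogate()`). Sections are maximal unbranched runs of same-typed
points; dendrites are split into *basal* (granular layer) and *apical*
(ascending into the molecular layer) by the position of their centroid
relative to a configurable Purkinje-cell-layer boundary (default: soma
centroid + 20 um along y), and the first stretch of axon leaving the soma —
or a basal dendrite; both arrangements occur in the reconstructed cells —
is relabeled as the axon initial segment (AIS). A geometric convention worth
noting: a branch leaving the soma keeps its own calibre; the soma
attachment point contributes position only, as in standard reconstruction
imports.

The surrogate generator emulates the published reconstructions: a ~20 um
soma, five basal dendrites branching in the granular layer, two apical
dendrites ascending ~300-500 um into the molecular layer, and a ~400 um
axon. Defaults were chosen once to give a total dendritic length of
~2-2.5 mm, twenty basal sections (so that twenty ascending-axon synapses
can be placed one per section), at least ninety apical compartments at a
10 um grid (so that 89 parallel fiber synapses fit one per compartment),
and a passive input resistance in the reported 339 +/- 128 MOhm range. The
AIS is 25 um long and 2.4 um thick; a shorter, thinner initial segment
cannot carry enough HCN conductance at the published densities to produce
the validated 4.4-10 mV sag, so the geometry (which the source tables do
not constrain) was set accordingly.

`discretize()` cuts each section into an odd number of equal cylinders no
longer than `max_seg_length` (center-sampled voltage, standard second-order
spatial accuracy), choosing diameters that conserve the membrane area
exactly. Two working grids are used throughout: 40 um (~90 compartments)
for intrinsic protocols and fitting, 10 um (~340 compartments) for synaptic
placement and plasticity.

## Passive properties

Axial resistivity 122 Ohm cm; specific capacitance 1 uF/cm^2 (2.5 in
dendrites); leak 3e-5 S/cm^2 (1e-6 in the axon); leak reversal -55 mV;
working temperature 32 C with Q10 corrections on all kinetic rates.

## Channels

The channel complement and its per-section maximum conductances follow the
published placement map exactly (`default_channel_registry()`): Nav1.6 in
every section at graded density (AIS 0.172 > soma 0.149 >> dendrites >
axon, S/cm^2), Kv1.x/Kv3.4/Kv4.3/Kca3.1/Cav2.2/Cav3.1 in the soma, Kv3.4
also in the axon, Kv7.x/HCN1/HCN2/Cav2.2/Kca1.1 in the AIS, Cav2.2, Kca1.1
and Kca2.2 in basal dendrites, and Cav2.3/Cav3.1/Kca1.1/Kca2.2 in apical
dendrites. Reversal potentials: Na +60, K -80, HCN -20, Ca +137.5 mV
(fixed, no GHK).

The *gating equations* are not printed in the source literature (they are
cited from earlier cerebellar models), so this package ships its own
parameterized kinetics (`default_channels()`): Boltzmann steady states with
bell-shaped time constants for HH channels, and exponential
voltage/calcium-dependent transition rates for Markov schemes. These
defaults were calibrated — once, as a set — so that the *published
conductance values* reproduce the validated cell-level behaviours:
pacemaking at ~4-5 Hz with ISI CV < 0.05, a near-linear f-I curve, a
7-9 mV sag at -0.2 nA abolished by HCN block, low-frequency resonance,
AIS-first spike initiation with strong basal (~60-65%) and weak apical
(~10-15%) backpropagation, and slow oscillatory firing when Cav2.2 or
Kca2.2 are blocked. Every parameter is overridable, and a per-section
override (`"Nav1.6@apical_dendrite"`) lets a channel carry different
kinetics in one section: the apical variant of Nav1.6 has a faster onset of
fast inactivation, so the slowly rising backpropagating depolarization
inactivates the channels before they regenerate — the mechanism behind the
strong basal/apical asymmetry.

Nav1.6 is a nine-state Markov scheme: the eight states of coupled m^3 h
activation/inactivation plus a slow-inactivated state entered from the
activated configurations and recovering at hyperpolarized potentials. Slow
inactivation contributes spike-frequency adaptation during current steps,
prevents stable depolarization plateaus, and is what converts the
Cav2.2-blocked cell into a slow (~1 Hz) oscillatory burster rather than a
plateau-locked or silent cell. Kca1.1 (BK) is a four-state scheme with two
sequential calcium bindings and a voltage-dependent opening step; Kca2.2
(SK) a four-state calcium-gated scheme whose sub-micromolar activation
builds the slow AHP and the burst-pause pattern.

## Calcium

Each compartment carries a submembrane shell (0.2 um): calcium enters
through the calcium channels (and the NMDA fraction), binds parvalbumin
and calmodulin, and is extruded by a saturating pump whose surface density
follows the published per-section values (soma 1e-7, AIS and axon 1e-8,
basal 5e-9, apical 2e-9 mol/cm^2 — following the methods text where it and
the summary table disagree). The pump turnover (8e-7/ms) is the free
parameter of the extrusion model; it was set so that the somatic transient
clears within ~5 ms (feeding BK/Kca3.1 spike repolarization) while
dendritic transients decay over tens of milliseconds (feeding the SK
adaptation and pause currents); the apical shell, with the lightest pump,
carries the slowest calcium waves, as expected for the slow apical
dynamics.

# Numerics

The solver integrates the cable equation with backward Euler at a fixed
0.025 ms step on the Hines-ordered tree (exact linear-time elimination),
with channel states updated after each voltage step: HH gates by an
exponential integrator (exact for constant voltage), Markov schemes by an
implicit propagator. For voltage-only Markov schemes the backward-Euler
propagator matrix is tabulated on a 0.05 mV grid and interpolated — the
standard table optimization of compiled neuron simulators. Voltage clamp is
a large series conductance (default 0.01 MOhm). Each run is preceded by a
settling period (default 100-500 ms) from -70 mV with all gates and Markov
schemes initialized at their steady state.

Accuracy choices worth knowing: the integrator is first order, so the free
pacemaker period shifts by ~1% between dt = 0.025 and 0.005 ms (spike
counts are preserved); the tree solve agrees with a dense linear solve to
1e-10; the action potentials of the shipped kinetics are narrow (~0.1 ms at
half height at the soma), a consequence of the fast activation rates needed
for robust AIS initiation at 32 C.

# Synapses

Presynaptic dynamics follow the resource/utilization (Tsodyks-Markram)
model with the published parameters per pathway (PF and ascending axon:
p 0.4, tau_rec 35.1 ms, tau_fac 55 ms, facilitating, paired-pulse ratio
~1.10 at 50 Hz; mossy fiber: p 0.43, tau_rec 5, tau_fac 8, PPR ~1.04 —
neither facilitating nor depressing; inhibition: p 0.5, tau_rec 15,
tau_fac 4). The facilitation variable is decayed and then incremented at
each event (the shipped convention for the update order); release is
computed event-driven in closed form and agrees with fine-step integration
of the underlying ODEs to 1e-6.

Receptors are three-state (closed/open/desensitized) schemes driven by a
normalized biexponential transmitter pulse (0.1 ms rise, ~1 ms decay). The
schemes themselves are not printed in the source literature; the shipped
rates are calibrated so the printed amplitudes are met: a single PF-AMPA
EPSC of ~25 pA at -70 mV (G_max 1200 pS), a GABA-A IPSC of ~3.5 pA at
-80 mV (G_max 2600 pS, reversal -70 mV), and a maximal NMDA current of
~5.5 pA (G_max 10000 pS, NR2B-like slow kinetics, 10% of the current
converted to calcium influx). NMDA conductance is gated by the standard
Boltzmann magnesium unblock with 1 mM Mg and a voltage sensitivity of
0.072/mV (within the published 0.06-0.08 range; the steeper value within
that range sharpens coincidence detection and the NMDA binding rate was
recalibrated against the 5.5 pA check).

Placement rules (`place_synapses()`): PF on apical compartments, at most
one per compartment; ascending axon one per basal section; MF on basal
compartments at least 20 um of path from the soma; inhibition on both
dendrite classes. Placement is the only stochastic element of the package
and is seeded.

# Protocol battery

`run_fi()`, `measure_sag()`, `measure_rebound()`, `measure_phase_reset()`,
`measure_resonance()`, `synapse_threshold()`, `run_psth()` and
`switch_off()` implement the stimulation battery. Definitions that the
source leaves qualitative were fixed as follows: spikes are -20 mV upward
crossings reported at the peak; AP height and AHP depth are referenced to
the -20 mV crossing; the pause is the first post-stimulus interspike
interval minus the mean baseline ISI; the resonance output is the mean
intra-burst instantaneous rate over eight 50%-duty cycles per repetition
frequency (zero when no cycle contains two spikes); the synaptic-threshold
protocol first finds the minimal silencing current by bisection and holds
at 1.3 times it.

Two behaviours of the published models are *not* reproduced by the shipped
kinetics, and the tests assert correspondingly weaker properties: (i)
blocking Cav3.1 does not abolish rebound firing — any T-type window strong
enough to drive a rebound burst loads the calcium shells and recruits
SK/Kca3.1, which suppresses firing instead; the rebound is expressed as
transiently accelerated resumption carried by the HCN tail. (ii) Synaptic
bursts evoke a single time-locked spike followed by a long pause rather
than a multi-spike burst; with one locked spike, twenty ~3.5 pA inhibitory
synapses measurably shape neither the burst count nor the pause, so the
tests assert time-locking, the burst-pause structure and lag-insensitivity
of the pause. Similarly, the synaptic threshold counts are higher than the
published 2-3 synapses: with ~25 pA EPSCs on a ~0.2 nF cell, unitary
somatic EPSPs are ~0.4 mV and several synapses are needed even from the
just-silenced state.

# Conductance fitting and validation

The genome is the vector of per-section maximum conductances, bounded by
the published ranges. `optimize_conductances()` is a seeded generational
GA — tournament selection, uniform crossover, per-gene Gaussian mutation
with sigma 10% of the range, elitism — scoring the summed z-error of the
six template features (AP width, AP height, AHP depth, ISI CV, mean
frequency, spike count) over three 2-second current steps (0.2, 0.4,
0.6 nA). Missing features score a fixed penalty of 10; simulation failures
score the penalty rather than crashing. The published optimizations ran
576 individuals for 10 generations on an HPC system; the desk-scale
defaults here are population 16 for 6 generations (and the acceptance
script uses 12 x 4), which this package treats as its standard regime. The
template targets shipped in `default_objective()` are documented
approximations (the source's template values are not printed); the
recovery tests build their objective from a reference model's own features
instead, so they do not depend on the approximate template.

`validate_model()` implements the three-step triage: (1) spontaneous rate
in [2, 15] Hz with ISI CV < 0.3 and driven rates inside a configurable
experimental envelope (the envelope defaults are documented
approximations); (2) sag depth in [4.4, 10] mV at -0.2 nA for 1000 ms;
(3) slow oscillatory firing (at most 5 Hz, neither silence nor a
depolarized plateau) under 90% Cav2.2 block, with the SK/BK reductions
reported alongside. All steps always run; failures are report rows.

# STDP prediction

The plasticity module follows the calcium-control hypothesis: the peak
NMDA-driven calcium transient at a mossy fiber synapse is mapped through a
sigmoidal transfer function with the inversion point at 0.75 uM and a rate
of change of 10/uM, saturating at +/-50%. The transient is measured by
recording the NMDA calcium current at one MF synapse while a PF burst
(5 impulses at 100 Hz) is delivered at a timing offset dt (positive dt =
MF event first), then integrating that current through a rapidly
equilibrating synaptic microdomain — endogenous buffering ratio 8 with a
2 ms clearance time lumping extrusion and diffusion — and multiplying by
the 3x store amplification described for neighbouring granule cell
dendrites. The domain parameters were calibrated once so that the MF-alone
case sits below the inversion point, the bAP-before-MF side below it, and
the MF-before-bAP side above it; the calcium response grows and saturates
with the number of active parallel fibers (11 to 81). These calibrations
parameterize a computation whose constants the source supplement does not
print.

# What the surrogate tests do and do not show

The surrogate generator produces morphologies with realistic section
counts, lengths and calibres, but not the full anatomical variability of
reconstructed cells (no tortuous axonal plexus, no reconstruction
artifacts, schematic branch angles). Passing the battery on surrogates
shows that the model machinery — solver, channels, synapses, protocols,
fitting — reproduces the validated behaviours under the published
parameters on Golgi-like geometry; it does not certify any individual
reconstructed cell. Reading real SWC reconstructions through `read_swc()`
plus `classify_sections()` is the supported path for that.

# Worked example

```{r example}
morph <- make_surrogate(seed = 1) |> discretize(40)
model <- cell_model(morph)
spontaneous_rate(model)
measure_sag(model)
validate_model(model)
curve <- stdp_curve(model, dt_grid = seq(-40, 40, by = 20))
plot_stdp(curve)
```
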