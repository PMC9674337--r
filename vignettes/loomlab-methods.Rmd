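---
title: "loomlab: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{loomlab: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
stage models, which parameters matter, where the design was genuinely
open and what we chose, and what the passing tests do and do not show.
Code chunks are illustrative and not evaluated at build time; every
empirical statement below is computed by the test suite or by
`scripts/acceptance.R`.

## Stimulus model

A square of half-size l approaching at constant speed v < 0 subtends
the half-angle θ(t) = arctan((l/|v|)/|t|) at time t before projected
collision; the single kinematic parameter l/|v| is given in
milliseconds (default 80 ms, the mid value of the behavioral range).
Stimuli are rendered directly in eye-centered angular coordinates
(azimuth/elevation, degrees); the physical screen distance is not
modeled. Defaults: 240 Hz frame rate (DLP refresh), 80° screen at
0.5°/pixel, looms from t = −2 s to collision with a 0.2 s hold. At
−2 s the square subtends 4.6° (about two facets); near collision it
outgrows the screen and is clipped with a warning — that clipping is
part of the stimulus, not an error.

Four contrast classes are provided: black squares on a white
background, white on black, and checkerboard (8×8 checkers scaling
with the square) or five concentric alternating squares on a 50%
background.

**Coherence scrambling.** The displacement law of the original
scrambling procedure is defined in prior work and not restated in the
source; we chose r(c) = r_max·(1 − c/100) with r_max half the screen
extent, implemented as a random bijection of 2.5° coarse cells built
from repeated random transpositions, each accepted only if both cells
stay within r of their true positions (at c = 0 the permutation is
unrestricted). The permutation is fixed per seed and constant across
frames, so every cell keeps its own luminance time course and the
per-frame luminance multiset is exactly preserved — the property the
tests assert. For coherence-series experiments every stimulus,
including the 100% coherent one, is first coarse-pixelated
(`coarse = TRUE`), so the series differs only in spatial arrangement.

**Facet sampling.** Facet centers sit on a square lattice at 2°
spacing (the eye's resolution); the acceptance profile is Gaussian
with half-width at half-maximum equal to the spacing, truncated at
3σ. The profile shape is not constrained by data; a Gaussian is the
conventional choice for photoreceptor acceptance functions.

## ON/OFF encoding

The photoreceptor-to-medulla transform is specified only by citation
in the source literature, so we model it minimally: a
difference-of-exponentials band-pass filter (τ_fast = 10 ms,
τ_slow = 100 ms) on each facet's luminance, half-wave rectified into
ON (positive) and OFF (negative, sign-flipped) channels, followed by a
threshold (0.01 drive units) standing in for medullary spiking. The
downstream analyses depend on event counts, timing order, and mapping
— not on the transform's exact shape — which is why this minimal form
suffices.

Visually driven events are drawn as an inhomogeneous Poisson process
with intensity gain·max(drive − threshold, 0) per facet and frame.
Because the expectation is linear in the gain, calibration to the
80,000 excitatory / 7,000 inhibitory event budgets is exact in
expectation and realized counts fluctuate by only ~√N (≈0.35%).
The calibration stimulus is the black coherent l/|v| = 80 ms loom;
the source does not state which loom produced the budget figures, and
the behavioral mid value is the natural choice.

**Inhibition.** The construction of the inhibitory drive is not given
in the source. We pool the rectified drive of *both* channels over all
facets, lag it by 30 ms, and scale it to the inhibitory budget; pooling
only the opposite-polarity channel would leave the budget ill-defined
for solid looms, whose opposite channel is essentially silent.
Inhibitory events carry the wide-field marker (no facet id) and are
routed by polarity: OFF inhibition to field C, ON inhibition to
field B. Spontaneous events (500 Hz excitatory, 30 Hz inhibitory,
homogeneous Poisson) carry the OFF-pathway label, i.e. the pathways
active in the dark-loom configuration.

## Reduced compartmental model

The full reconstruction this work descends from has 2518 compartments
(1352 in field A, 455 in field C). We use a deliberate reduction — 174
compartments: a 12×10 field A grid isomorphic to the facet lattice, 30
positioned field C compartments, 10 in field B, and 4/5/5 in
trunk/SIZ/axon — because the claims exercised here rest on the passive
architecture (field C proximal, field A distal beyond the trunk) and
on the event mapping, not on morphological detail.

A reduction this size has one consequence that matters: the reference
event counts and synaptic conductances are absolute, so the reduced
cell must present a realistic total membrane conductance or the loom's
~1 µS of synaptic drive collapses the driving force everywhere.
Compartment dimensions were therefore chosen to give LGMD-like
electrical bulk (R_a = 60 Ω·cm, g_pas = 0.25 mS/cm² ≈ 4 kΩ·cm²
membrane, SIZ input resistance ≈ 4 MΩ).

**Channels.** Kinetics live in the cited prior models, not the source
itself, so standard HH-style formulations are used with sigmoid
steady-states and fixed or bell-shaped time constants: fast Na⁺ and
delayed-rectifier K⁺ at SIZ/axon, HCN (E_h = −35 mV) confined to field
A and absent from field C, inactivating K_D in field A dendrites,
M-type K⁺ in the axon, and low-threshold Ca²⁺ with a Ca²⁺-activated K⁺
conductance near the SIZ. Densities and the Na⁺ activation midpoint
were tuned by a scripted sweep with two targets: (a) a quiet resting
state near −64 mV with no spontaneous firing, and (b) a reference-loom
firing profile peaking near projected collision (≈28 spikes, peak IFR
≈200 spikes/s at t ≈ −0.09 s). The tuned set ships in
`inst/extdata/channelset-default.yaml` and is versioned there.

**Field C link calibration.** The one deliberately calibrated
electrotonic parameter is the axial-resistance scale of the segment
connecting field C to the trunk (`c_link_ra_scale = 3.25`). It was
chosen so that relocating all loom-evoked excitation to random field C
compartments and removing 60% of it reproduces the all-field-A spike
count within ±1 spike — the equivalence the passive-attenuation
account prescribes. With that single scale fixed, the removal-fraction
sweep (`find_removal_fraction()`) recovers ≈60% from scratch, the
split curve peaks at even splits, clustering monotonically reduces
firing, and the coherence series declines — none of those outcomes is
separately adjusted.

**Numerics.** The branched cable equation is integrated with an
implicit, unconditionally stable Crank–Nicolson scheme: one
Hines-ordered tridiagonal-tree factorization per step at dt = 0.02 ms
with half the membrane and axial operator on each side of the step,
gating variables updated by Rush–Larsen exponential steps, and
alpha-synapse conductances advanced by an exact two-state recursion in
half steps so the voltage solve sees the midpoint conductance (events
only add impulse increments, so arbitrarily many synapses cost
O(compartments) per step). Halving dt changes the reference-loom spike count by at most
one spike, and a passive two-compartment EPSP matches a dense-output
`deSolve::lsoda` oracle to better than 0.1 mV. Spikes are upward
crossings of −20 mV at the axon with a 2 ms refractory period; the IFR
convolves the spike train with a normalized 20 ms-SD Gaussian.
Simulations start 0.4 s before the first event so the
initial-condition transient (simulations start at −64 mV rather than
the exact steady state) never contaminates spike counts.

## Design choices where the source was open or in tension

* **Split-experiment inhibition.** The stated protocol moves a
  matching percentage of inhibition from field C to field B as
  excitation moves to field C; yet the split curve's endpoints are
  anchored to the reference simulations, in which inhibition stays at
  its natural field C site. In a 30-compartment field C the two
  readings diverge: relocated inhibition in a compact parallel field B
  compounds with the field C shunt and inverts the curve. Both
  behaviors are implemented (`move_inhibition` in `map_events()`); the
  curve-shape experiments use the endpoint-anchored configuration
  (`move_inhibition = FALSE`), which reproduces the mid-split maximum.
  This is a reduced-morphology artifact, not a claim about the full
  model.
* **Axial-resistance matching.** Matching *single-EPSP* amplitudes
  between fields (factor ≈ 24) does not equalize full-budget
  responses: 80,000 events concentrated on 30 compartments saturate
  their driving force in a way single events never probe. The
  manipulation is therefore calibrated on responses
  (`match_budget_factor()`, factor ≈ 3.5 on top of the tuned link),
  which is also how the original manipulation was stated ("as much
  excitation was needed... to elicit the same response").
* **Clustered recruitment sigmoid.** Only the 80 µm steepness is
  stated. We let the recruitment front grow linearly with the
  stimulus half-angle up to R_max = 150 µm and weight each
  compartment by 1/(1 + exp((d − d_front)/80 µm)); "narrower
  clustering" scales front and steepness together.
* **Ca²⁺ charge fraction.** The Ca²⁺ share of excitatory current is
  not measurable here; `energy_report()` back-computes it (≈0.06) so
  the ion-pump route reproduces the count-based estimate
  E_syn·N_syn·N_spk exactly. It is a calibration, exposed as a
  parameter, not a stoichiometric measurement.
* **Per-EPSP potential.** The averaging potential behind the 0.34 pC
  per-EPSP figure is implicit in the source; −50 mV (a
  loom-representative depolarized level) reproduces it and is the
  package default. The simulation-based route (integrated synaptic
  current) is also available and agrees within ~15%, the difference
  being the driving-force variation over the loom.
* **Loom duration for the mean current.** 27 nC at 5 nA implies
  5.4 s; that duration is used for the mean-current figure only.

## Synthetic data: what it emulates, what it does not

The movie generator reproduces the acquisition geometry (5 Hz,
0.9 µm/pixel), stylized crescent/blob field masks visible at baseline
(dye-filled dendrites — this structure is what gives registration its
anchors), retinotopic sweeps in register with a stimulus-position
track, uniform loom-like activation, additive Gaussian noise, linear
baseline drift, and integer-pixel breathing translation. Every
generator returns its ground truth (activation centroids, shifts,
amplitudes), and recovery tests consume only the data.

It does **not** model calcium-indicator kinetics (buffering, dye
saturation), shot noise statistics, uneven dye fill, or non-rigid
motion. Passing recovery tests therefore show the *analysis* is
correct and well-conditioned at realistic noise, not that real
recordings would behave as cleanly. Likewise, animal-derived effect
sizes (jump probabilities and timing shifts, per-field dF/F ratios,
pharmacological reductions, measured CoM magnitudes) depend on
recordings that are not available at desk scale; the pipeline
measures such quantities from data and the tests verify it recovers
injected ground truth, nothing more.

## Problem sizes

The shipped defaults are sized for a single CPU: 80° screen at
0.5°/pixel (160×160×528 frames), 1681 facets, 174 compartments, 2.2 s
looms at dt = 0.02 ms (≈2 s of compute per simulation), removal-fraction
sweeps over 5 mapping seeds. These sizes are the package's study
conditions; the full suite and the acceptance script each run in
minutes.

## Known limitations

* Late-phase burst structure is not reproduced: in the experimental
  data incoherent checkered looms increase late bursting while peak
  firing falls; the reduced model reproduces the peak-rate decline but
  its burstiness does not rise, presumably because the Ca_T/K_Ca
  interplay near the SIZ is only coarsely tuned.
* Field A's random-vs-retinotopic equivalence (which requires removing
  the active dendritic conductances) is out of scope and not asserted.
* The coherence series' firing decline partly reflects facet-level
  pooling of scrambled coarse cells reducing suprathreshold drive, in
  addition to the loss of retinotopic order; the two contributions are
  not separated here.
* SWC round-trips preserve geometry, topology and region labels, but
  not electrical parameters or the grid metadata.
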