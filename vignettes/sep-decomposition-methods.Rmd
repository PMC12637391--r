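---
title: "Modeling and decomposing the whisker-flick SEP: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and decomposing the whisker-flick SEP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepdecomp)
```

# The problem

A whisker flick evokes a stereotyped EEG waveform over rodent somatosensory
cortex — the somatosensory evoked potential (SEP), a positive deflection
(P1, here 8–16 ms post-stimulus) followed by a negative deflection (N1,
early phase 16–40 ms). Which neural populations generate these components
cannot be measured in vivo, but in a simulated cortical column every
compartment's transmembrane current is known, so the question becomes
tractable: the EEG is a weighted sum of all transmembrane currents, and the
weights (the lead field) follow from the reciprocity theorem.

`sepdecomp` implements this analysis chain at desk scale: a synthetic
layered column driven by virtual thalamic fibers, a cable-equation network
simulation that records per-compartment transmembrane currents, analytic
EEG/LFP forward models, a spike-replay decomposition that attributes the
SEP to presynaptic populations, postsynaptic populations, and
presynaptic→postsynaptic pathways, CSD and dipole-moment analyses for
internal consistency, and P1/N1 waveform statistics.

# The synthetic column

The stand-in circuit emulates the structure that the decomposition
analysis assumes, not the biophysical detail of a reconstructed cortex.

* **Geometry.** Depth `z` runs from 0 at the pia downward, with layer
  boundaries L1 0–150, L2/3 150–500, L4 500–750, L5 750–1100, L6
  1100–1500 µm. Cells sit at lateral radii 25–250 µm from the column axis.
* **Morphologies.** Pyramidal cells are ball-and-stick: a 10 µm-radius
  soma plus a single apical cable (5 segments) pointing to the pia. This is
  the minimal shape producing a dipolar current pattern — a current
  entering at one depth must leave at another, which is all the EEG can
  see. Interneurons and the L5 perisomatic-targeting (PeriTC) basket cells
  are soma-only; a point source with no return path generates no
  extracellular signal, matching the observation that inhibitory
  *postsynaptic* contributions are negligible.
* **Populations.** Excitatory and inhibitory populations in L2/3–L6, a
  PeriTC population in L5, and 100 virtual thalamic (VPM) fibers that carry
  no compartments. Default size ≈ 290 cells (`scale` multiplies all
  counts) — a deliberate ~1000× reduction from the reference circuit.
* **Connectivity.** Bernoulli connections per projection with 1–6 synapses
  per connection. Synapse placement follows one of two profiles:
  `distributed` (probability ∝ membrane area) or `perisomatic` (within
  50 µm path distance of the soma). Thalamocortical synapses onto
  pyramidal cells use a proximal profile (80 µm) because TC input
  predominantly targets basal/proximal dendrites; with the synaptic sink
  deep and the return current superficial, the early evoked deflection is
  surface-positive, which is what makes P1 positive. TC synapses onto L6
  pyramids are distributed over the apical cable, giving the slow
  surface-negative component that feeds the N1. Basket-type inhibition is
  perisomatic in both variants.
* **The two variants.** `default_circuit_config("original")` vs
  `default_circuit_config("sm")` differ in exactly one parameter: the
  placement profile of the L5 PeriTC → L5 pyramidal projection
  (distributed vs perisomatic). This isolates the connectivity rewiring
  under study; everything else, including all seeds, is shared.
* **Delays.** Every synapse's delay is
  `base_delay + (distance from the bottom of L6 to the synapse)/velocity`
  with defaults 1 ms and 300 µm/ms, so deep targets are reached first.
* **Stimulus.** A flick activates exactly 10% of the fibers (selection
  re-drawn per stimulus); each active fiber draws an inhomogeneous Poisson
  train from a piecewise-constant PSTH, by default a 0.5 Hz baseline plus
  a Gaussian bump (peak 80 Hz, center 5 ms, σ 2 ms) on 1 ms bins. The
  PSTH bin width and smoothing of the reference in vivo histograms are not
  published; these defaults are declared choices, not inferences.

# Membrane dynamics

Units are ms/mV/µS/nA/nF throughout, chosen so the cable equation carries
no conversion factors.

* **Model.** Passive cable (Cm 1 µF/cm², Rm 20 kΩ·cm², Ra 150 Ω·cm,
  E_leak −70 mV) with an exponential-integrate-and-fire soma
  (ΔT 2 mV, V_T −54 mV, threshold −50 mV, reset −65 mV, refractory
  2.5 ms). On each spike a stereotyped 1 ms biphasic current (±3 nA sine)
  is injected at the soma. The amplitude is the capacitive current of an
  action-potential upstroke for this soma (12.6 pF × ~240 V/s): spikes
  must leave a visible high-frequency signature in the EEG — the
  replay-timing noise central to the decomposition's error analysis —
  without dominating the synaptically generated waveform.
* **Synapses.** Single-exponential conductances (excitatory τ 2 ms, E 0 mV;
  inhibitory τ 8 ms, E −80 mV) with probabilistic release. A `current`
  synapse model (amplitude frozen at the resting driving force) is
  available for linearity tests, together with a `detect` spike mode
  (threshold crossings are recorded but cause no reset or current), so a
  fully linear circuit can still emit spikes for the replay bookkeeping.
* **Background noise.** Ornstein–Uhlenbeck conductance at the soma
  (τ 3 ms, sd/mean = 0.4, clipped at 0, reversal 0 mV) stands in for
  unmodeled synaptic input. The configured mean (default 1.25 nS) refers
  to a 10⁴ µm² reference membrane and scales with each cell's area, so
  small interneurons are not swamped. The default was calibrated once to
  give sparse, irregular background firing (~0.5–3 Hz excitatory, higher
  for interneurons) before any evoked-response analysis.
* **Integration.** Fixed-step backward Euler at 0.025 ms. Synaptic
  conductances decay analytically between event increments and are known
  at the end-of-step time, so each voltage update is a per-neuron
  tridiagonal solve; neurons with equal compartment counts are solved
  simultaneously by a Thomas algorithm vectorized across neurons. The EIF
  spike-initiation current is evaluated explicitly and capped near
  threshold (the reset takes over past the cap). Currents are reported
  every 0.1 ms.
* **Transmembrane currents.** Reported as the net axial current arriving
  at each compartment — what arrives axially must leave through the
  membrane, capacitive displacement included — which makes the per-neuron
  sum of reported currents *exactly* zero at every step. This
  charge-conservation identity is what licenses the gauge freedom of the
  lead field.

# Reproducible stochasticity

The decoupled-replay analysis requires that noise paths and synaptic
release outcomes be identical between a connected simulation and its
replay. Global-state RNGs cannot guarantee this, so:

* release outcomes are keyed counter-hash draws
  `u(trial_seed, synapse id, presynaptic spike index)` — a replayed train
  regenerates exactly the outcomes of the connected run;
* the OU noise uses one seeded stream per trial covering all cells in a
  fixed order, identical across run modes by construction;
* every structural random choice (morphology jitter, connectivity,
  placement, fiber selection) draws from a scoped stream keyed by the
  master seed and a purpose tag, so circuits are bit-reproducible and
  the caller's RNG state is never touched.

# Forward models

* **EEG (reciprocity).** The weight of a compartment for an electrode pair
  is the potential a unit current driven between the electrodes would
  create at the compartment: in a homogeneous medium
  `w = 1/(4πσ)(1/r_rec − 1/r_ref)` (σ 0.3 S/m by default; reference
  optionally at infinity). The recording-minus-reference subtraction is
  folded into one scalar per compartment, and weights files round-trip
  through a plain-text format (full double precision) so externally
  computed lead fields, e.g. from a finite-element head model, can be
  used unchanged. The default electrode sits 1.5 mm above the pia on the
  column axis. Because each neuron's currents sum to zero, weights are
  defined only up to a constant (gauge freedom); `gauge_shift` centers
  the range over a population on zero for interpretation, provably
  without changing any signal.
* **LFP (line source).** Each cable segment contributes the analytic
  potential of a uniform line current,
  `(4πσL)⁻¹ [asinh(h/ρ) − asinh(l/ρ)]`, with somata as point sources; the
  laminar array spans the column at exactly 80 µm spacing.
* **Per-neuron contributions.** The weighted currents are summed within
  neurons before summing across them, so every signal carries a
  per-neuron contribution matrix whose column sum equals the total to
  machine precision — the backbone of every population attribution.

# SEP protocol

A campaign mirrors the study protocol: 10 trials, each with its own seed
for noise and fiber selection; two stimuli per trial 150 ms apart; the
response to the *second* stimulus is extracted (accommodation control);
a second-order Butterworth band-pass (1–500 Hz) is applied; trials are
averaged; traces are normalized to the original variant's P1 peak when
variants are compared. Two choices the protocol source leaves open are
made explicitly here: the filter is applied zero-phase
(forward–backward, reflection padding) so P1/N1 latencies are not
shifted, and because a 1 Hz high-pass cannot remove a standing offset
within a ~100 ms window, the conventional pre-stimulus baseline
subtraction is applied afterwards. Averaging after filtering commutes
with the linear filter up to edge effects, which the padding absorbs.

# The decomposition

The presynaptic contribution of population X is `network EEG − decoupled
EEG(X)`, where the decoupled run replays every *other* population's
recorded spikes at their recorded times into a circuit whose
newly generated spikes are not transmitted; X's efferents stay silent.
Restricting the per-neuron difference to postsynaptic population Y gives
the pathway contribution X→Y (per-neuron pairing between the runs is
enforced by construction — both runs share the compartment ordering).
Summing a population's own per-neuron contributions gives its
postsynaptic contribution. The thalamic contribution uses the same
subtraction with all cortical spikes replayed and thalamic synapses
silent; fibers have no compartments, so they have no postsynaptic
contribution by assumption.

Multi-synaptic attribution is out of scope by design: the difference
isolates only the monosynaptically elicited currents (plus their return
currents) of the excluded population.

**Validity.** On a fully passive circuit with current-based synapses the
whole map from spike trains to currents is linear, the decomposition is
exact, and the residual `total − Σ presynaptic − thalamic` vanishes to
solver precision (`linear_circuit_config()` packages these conditions;
its low detection threshold only feeds the replay bookkeeping). With
conductance synapses and spiking somata the residual is nonzero: the
decoupled run's membrane potentials differ, so its *intrinsic* spikes
shift in time, and the difference of two spike signatures at slightly
different times is a high-frequency transient. The residual's spectral
power above 100 Hz therefore exceeds that below — the package asserts
this property, and `validate_linear_sum` reports both the relative RMS
residual and the band-power ratio.

# CSD, dipole moment, and self-consistency

The standard CSD estimator is the second spatial difference
`−σΔ²φ/h²` with the Vaknin boundary correction (duplicated edge
potentials). The step-iCSD estimator assumes the CSD is homogeneous in
cylindrical disks (radius ρ, thickness = electrode spacing) and inverts
the analytic disk forward matrix, evaluated in closed form; the
condition number is reported and a singular matrix is an error. The
dipole-moment density is the trapezoidal integral `∫ z·CSD dz` over the
electrode span, reported in nA·m/mm² and evaluated by default at the
time of peak rectified current density; `dipole_moment_series` returns the
full time course, whose peak is the quantity that predicts the peak EEG
(in a small column the peak-current time can be quadrupole-dominated, so
the two times need not coincide).

The self-consistency argument estimates the EEG from the LFP-derived
dipole as `πr²·p·Ê` for a patch of radius `r` and dipole-aligned lead
field `Ê`. Two parameters must match the configuration that generated
the LFP: `Ê` is computed from the same analytic electrode model
(`dipole_lead_field`, the depth gradient of the reciprocity weight —
~58 V/mm/A for the default electrode, much larger than a skull-mounted
electrode behind bone would see), and ρ is matched to the synthetic
column's actual source radius (250 µm) rather than the 500 µm
appropriate when neighboring columns contribute. With these the
dipole-route estimate agrees with the directly computed EEG within a
factor of ~2, which is the meaningful desk-scale statement of internal
consistency. The published worked example (0.023 nA·m/mm², ~4 V/mm/A,
seven columns → 1.3×10⁻⁷ V) is reproduced by `eeg_from_dipole` /
`circuit_eeg_estimate` as pure unit arithmetic.

# Waveform features

P1 is the maximum in 8–16 ms, N1 the minimum in 16–40 ms. N1 counts as
defined only when the trough drops below baseline by more than the
baseline noise (3 SD) and 1% of the P1 excursion — a flat or purely
positive trace reports P1 only. The FWHM of N1 is measured from the
pre-stimulus baseline to the trough (the half level is baseline −
depth/2), with the two crossings nearest the trough linearly
interpolated; the nearest-crossing rule reads an oscillatory recovery as
a single deflection. FWHM is invariant under amplitude scaling, so
normalization does not affect it. Onset detection is the first sample
exceeding baseline + 3 SD.

Pathway attribution of the N1 width removes one pathway trace from the
total, re-measures the FWHM, and reports `FWHM − FWHM_removed` per
pathway; with two circuit variants, `Δ_{x→y} = ΔFWHM − ΔFWHM_{x→y}`
attributes the *difference* in width. Pathways whose removal leaves no
defined N1 are flagged and excluded. The spike-compression manipulation
(`compress_spikes`) moves all PeriTC spikes between 10 and 40 ms
post-stimulus to 15 ms before replay, testing whether inhibitory spike
*timing* alone reshapes the SEP.

# What the synthetic data can and cannot show

The generator reproduces the structural features the analysis depends
on: layered dipolar sources, depth-dependent delays, stimulus-locked
thalamic drive, frozen stochasticity between run modes, and a
single-parameter connectivity difference between variants. It does not
reproduce reconstructed morphologies, ion-channel diversity, synaptic
short-term dynamics, or the ~210,000-neuron scale, so absolute
amplitudes are smaller than published values (EEG ~10⁻⁷ V is of the
right order because it scales with source synchrony; the LFP, which
lacks the spatial averaging of thousands of nearby cells, is ~50×
smaller) and waveform widths carry large trial-to-trial variability. In
particular, the rewired variant robustly shows a *larger* N1 (its
perisomatic inhibition has the stronger weight gradient between soma and
apical dendrite), but the published ~25% width narrowing is within
desk-scale trial noise — the worked-example statistics are therefore
checked as arithmetic on the published widths, not re-derived from the
small circuit. Passing tests certify the correctness of the machinery
(forward models, decomposition identities, feature definitions), not the
biological fidelity of the stand-in column.

# Numerical and scale choices

Simulations run at dt 0.025 ms with 0.1 ms reports; a 10-trial campaign
with five decoupling targets on the ~290-cell default circuit is ~60
simulations of ~270 ms each and completes in a few minutes on one core.
The validation analyses use a ~170-cell circuit and a single stimulus.
Tie-breaks and degenerate inputs are handled explicitly: zero-rate PSTHs
yield empty spike records; `n = 0` placements return empty tables;
neurons with fewer than two compartments contribute a weights range of
0; an electrode on a cable axis is an error for the line source, as is a
compartment coinciding with an electrode for the point source.
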