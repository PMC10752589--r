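---
title: "Modelling direction selectivity in the bipolar-starburst circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling direction selectivity in the bipolar-starburst circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Starburst amacrine cells (SACs) turn spatially distributed glutamatergic
input from bipolar cells (BCs) into direction-selective dendritic calcium
signals. One candidate mechanism — "space-time wiring" — proposes that
sustained, delayed BC types contacting the proximal dendrites and
transient, short-latency types contacting the distal dendrites implement a
Hassenstein–Reichardt-style correlator along each dendrite: for outward
motion the slow proximal signal and the fast distal signal arrive at the
dendritic tip together and sum; for inward motion they disperse.

`stwiring` implements this circuit end to end: a presynaptic
receptive-field (RF) model that converts moving-bar and flash stimuli into
per-synapse conductance waveforms; a branched-cable SAC with voltage-gated
calcium channels and dendritic calcium pools; an evolutionary algorithm
(EA) that tunes presynaptic kinetics and postsynaptic biophysics for
directional performance; an EA-based method that recovers RF parameters
from multi-velocity motion waveforms; and the imaging-analysis pipeline
(ROI segmentation, functional clustering, filtered back-projection RF
mapping) with synthetic-data generators that stand in for recordings.

## The presynaptic receptive-field model

Each BC is a point neuron with Gaussian center and surround components
(FWHM in µm) positioned at its synapse's location on the SAC. Stimuli live
in a 1-mm 1-D arena sampled at 1 ms; a bar of speed $v$ (mm/s, numerically
equal to µm/ms) is `speed × dwell_time` wide so that every arena position
is stimulated for exactly the dwell time (2 s by default).

At each time step the fraction of each component's Gaussian mass covered
by the stimulus, $area_t \in [0,1]$, is evaluated with the erf closed form
(normalized to unit total mass within the arena; a dense Riemann-sum
oracle verifies this to $10^{-6}$ in the tests). The temporal stages are
first-order recursions with constants expressed in 1-ms steps:

$$RF_{c,t} = \left(RF_{c,t-1} + \frac{area_{c,t} - RF_{c,t-1}}{\tau_{rise}}\right)\cdot ad_{t-1},
\qquad ad_t = \max\!\left(0,\; ad_{t-1} - \frac{RF_{c,t}}{\tau_{decay}}\right)$$

$$RF_{s,t} = RF_{s,t-1} + \frac{area_{s,t}\cdot strength_s - RF_{s,t-1}}{\tau_{rise,s}},
\qquad RF_{full,t} = A\,\frac{RF_{c,t} + RF_{s,t}\cdot rev_s}{RF_{c,t} + RF_{s,t} + R_{in}}$$

Adaptation starts at 1 and never recovers within a trial; state is reset
between trials. The surround enters the denominator fully but the
numerator only through the reversal fraction $rev_s \in [0,1]$, so
$rev_s = 0$ is pure shunting inhibition. $R_{in} = 0.1 \times$ the unit
total center mass, i.e. 0.1 on the normalized scale. With $A \le 1$ these
rules keep $RF_{full} \in [0,1]$, which the tests assert as an invariant.
Rise/decay constants below one time step are clipped to 1 to keep the
recursions stable. A ninth parameter, `delay`, shifts the activation trace
in time; the onset shift due to the cell's position under a moving bar
emerges from the overlap computation itself, so no explicit position
shift is applied.

Fluorescent glutamate sensors low-pass the release signal. The sensor
filter is a causal difference of exponentials,
$k(\tau)=e^{-\tau/F_{decay}}-e^{-\tau/F_{rise}}$ with 10/50 ms defaults
and peak normalized to 1 (its maximum sits near 20.1 ms). It is
implemented exactly as the difference of two first-order recursive
filters, which equals the untruncated discrete convolution to machine
precision and is an order of magnitude faster than an explicit FIR.

## The compartmental SAC

Morphologies come from SWC files or from `generate_synthetic_sac()`, which
builds a radially symmetric tree (6 primaries, 3 branch orders, ~120 µm
radius by default) with the standard thin-dendrite normalization (0.2 µm
beyond 30 µm from the soma). Sections are discretized by the d-lambda rule
(10% of the 100-Hz length constant, odd segment counts). The passive
membrane uses 4e-4 S/cm² leak, 1 µF/cm², −60 mV reversal and 150 Ω·cm
axial resistivity.

The solver is a backward-Euler Hines elimination on the branched tree
(default 0.1 ms step; synaptic conductance waveforms sampled at 1 ms are
interpolated linearly). Voltage-gated calcium current uses an $m^2$
activation stand-in for the N-type channel — half-activation −10 mV plus a
tunable offset, 6 mV slope, 1 ms gating time constant, ohmic driving force
toward +60 mV — because only the threshold-vicinity nonlinearity matters
for the directional readout, and the EA-tunable voltage offset (±30 mV)
absorbs kinetic differences. Gating uses a lookup table with linear
interpolation (0.05 mV resolution), which changes peak responses by less
than the mesh-refinement tolerance. Each compartment carries a calcium
pool, $dCa/dt = -(Ca - Ca_{rest})/\tau_{Ca} + k\,|I_{Ca}|$ with
$\tau_{Ca} = 50$ ms and $Ca_{rest} = 100$ nM; the influx gain
$k = 500\ \mathrm{nM\,cm^2\,mA^{-1}\,ms^{-1}}$ was set once so that evolved
outward peaks land near the 500 nM optimum of the fitness metric.
Verified closed forms: single-compartment RC deflection and
conductance-divider steady state ($10^{-6}$), finite-cable cosh
attenuation ($10^{-4}$), transfer-impedance reciprocity ($10^{-6}$), and
calcium steady state $Ca_{rest} + kI\tau$ ($10^{-6}$). Halving both the
mesh and the time step moves peak somatic voltage by under 1%.

Synapses (200 by default) are placed uniformly over dendritic length
within 110 µm of the soma; each drives a conductance
$g(t) = g_{max} \cdot RF_{full}(t)$ with 0 mV reversal, the standard
glutamatergic choice. Calcium is read out at terminal compartments within 30 µm
of the horizontal axis; a site's outward direction is the sign of its
x-position relative to the soma.

## Evolutionary training

A genome holds one or two 9-parameter presynaptic RFs plus five
postsynaptic parameters (leak 1e-5–1e-3 S/cm², axial resistance 50–300
Ω·cm, calcium-channel density and ±30 mV voltage offset, synaptic
conductance 0.01–1 nS), 23 free parameters in the full scenario. The
channel-density bound (1e-4–1e-2 S/cm²) is a package default, wide enough
that the density is effectively set by the fitness landscape. Fitness is the mean over stimulus velocities of the site-mean
directional metric $DSI \cdot e^{-(R_{out}-Ca_{opt})^2/Ca_{opt}^2}$ with
$Ca_{opt} = 500$ nM, which rewards robust calcium amplitudes and
suppresses the brittle threshold-riding solutions that a pure-DSI
objective finds; a `dsi_only` objective is available for comparison.

Each generation keeps the two best genomes verbatim and refills every
other slot from one of the two elites, chosen by a fair coin, followed by
mutation: every parameter is
multiplied by $\mathcal{N}(1, 0.05)$ and shifted by
$\mathcal{U}(-0.015, 0.015)$ of its bound range, then clipped. The
additive term is scaled by the range because a raw-unit ±0.015 would be
invisible on parameters like axial resistance; this is configurable.
Scenarios: `full`, `identical` (one shared RF), `single_free` (one
parameter free to differ), `compartmentalization` (perisomatic
axial/membrane-resistance factors), `cluster_pair` (fixed library RFs,
postsynaptic-only evolution) and `annuli` (10-µm bins each assigned a
library cluster, assignments resampled with 5% probability per
generation).

Desk-scale study conditions, used by the tests and the acceptance script:
synthetic SAC, population 8, 10 generations, velocities 0.5 and 1 mm/s,
three (tests) or two (script) seeds. At this scale the full scenario
reaches mean DSI in the 10–25% range while the identical-RF scenario
stays several-fold lower; individual seeds are noisy (a 10-generation run
can fail to leave the low-DSI regime), so comparisons aggregate over
seeds. Full-scale runs (population 16, 100 generations, five velocities,
reconstructed morphologies) reproduce the regime where the full scenario
roughly triples identical-RF tuning, but take hours of CPU.

## RF estimation from motion waveforms

`fit_rf_to_motion()` reuses the EA engine to minimize the mean squared
error between peak-normalized, sensor-filtered model waveforms and target
waveforms across five velocities. Targets and outputs are peak-normalized
because recorded cluster waveforms are normalized; absolute amplitude is
therefore unidentifiable and flagged as such in the fit summary. Repeats
(10 by default) from independent seeds quantify identifiability; the
returned estimate is the lowest-MSE repeat, whose parameters are the best
constrained. Rise and adaptation constants trade off along a shallow MSE
valley, so per-repeat scatter in `center_rise` exceeds the scatter of the
functional kinetics (flash-response rise time), which is tightly
recovered; the center FWHM is identified to a few percent on noiseless
targets. The default budget (population 24, 120 generations) was chosen
by watching MSE convergence on synthetic targets. The fitted model's
*pre-filter* activation is the deconvolved drive that feeds the circuit
scenarios, and `predict_flash()` provides held-out validation: flashes
are never part of the training set.

## Imaging analysis

`select_active_pixels()` keeps pixels exceeding 20% dF/F.
`segment_rois()` clusters pixel waveforms (correlation distance, Ward
linkage), raises the cluster count until every spatially connected
component spans ≤ 10 µm, and drops ROIs whose pixel peak amplitudes vary
with CV > 1. `preprocess_trace()` applies a first-order Butterworth
(normalized critical frequency 0.1, zero-phase), a 5-sample rolling
average (a package default), baseline subtraction and peak
normalization. Motion responses to the two
directions are aligned by shifting each so its half-maximum rise time
lands on the mean of the two rise times — this cancels the RF-position
dependence of response timing — and averaged.

Functional clustering is agglomerative (`ward.D2`) with Euclidean
(ON-like) or maximum (OFF-like) distance on the aligned waveforms,
optionally after discarding low-variance time points. The cluster count
comes from the within-cluster variance curve via a reproducible elbow
rule: the point furthest from the chord on the *log*-variance curve
(variance falls over orders of magnitude before flattening at the noise
floor; on a linear scale the chord criterion locks onto the first large
drops). The log-chord rule replaces the expert judgement that usually
accompanies elbow plots with a reproducible criterion. Clusters are
relabelled by decreasing transiency index, implemented as
$TI = 1 - \mathrm{mean}/\mathrm{peak}$ so that sustained plateaus score
near 0 and sharp transients near 1, matching the stated semantics.

RF maps from oriented-bar protocols (five 36°-spaced orientations, 32
positions at 10 µm) are reconstructed by filtered back-projection with a
Ram-Lak filter; projections are padded with a crossfade between their end
values so a uniform projection filters to exactly zero instead of leaving
wrap-around artifacts. Five angles undersample the angular spectrum; the
tests quantify that a uniform input stays flat and that a 100-µm Gaussian
RF is recovered within 10% FWHM, but widths approaching the ~310 µm
mapped span are truncated and under-estimated — consistent with treating
map-based widths as a validation for narrow RFs only. A 2-D Gaussian
least-squares fit supplies $\sigma_x$ and
$FWHM = 2\sqrt{2\ln 2}\,\sigma_x$.

## Synthetic data: what it emulates and what it does not

`gen_cluster_library()` provides deterministic ON (7) and OFF (6) cluster
libraries spanning the observed qualitative spectrum: sharp transients,
transients with elevated tails, sustained plateaus, a deep-shunt
spike-and-plateau shape, and two wide-center clusters (380 and 200 µm for
ON) with the longest processing delays. Design constraints, fixed once:
every cluster has a unique center width so lag-versus-width analyses have
unambiguous ground truth; delays grow with width (mirroring the empirical
association between long flash lags and wide RFs); surrounds are purely
shunting so that motion-response onset is governed by the excitatory
center; and all 0.5 mm/s waveforms differ pairwise by normalized RMS
≥ 0.1 so that recovery tests are non-vacuous. With these defaults the
motion-onset lag decreases strictly with center half-width
(Pearson r ≈ −1.0), wide clusters release before the bar arrives, and
flash lags are exactly width-independent.

`gen_roi_dataset()` draws cluster labels from the library prevalences,
scatters RF positions over the central arena, and adds iid Gaussian noise
(SD 0.1 of unit peak = SNR 10) plus per-ROI amplitude scatter.
`gen_movie()` renders disc footprints into a pixel grid (1.28 µm pixels,
~50 Hz) with optional Gaussian blur and pixel noise, retaining the
pixel-to-source truth map. These generators do not emulate scanner
artifacts, photobleaching, drift, overlapping neuropil signals, or
direction-asymmetric release — so passing recovery tests demonstrates
that the analysis chain is self-consistent at realistic noise levels, not
that it is robust to every failure mode of real two-photon data.

## Numerical choices and limitations

- The spatial-overlap computation uses the erf closed form of the
  truncated Gaussian mass and the sensor filter uses decaying
  exponentials; both are verified against independent brute-force oracles
  (dense Riemann integration; direct discrete convolution).
- The surround recursion is a low-pass toward `strength × area`,
  paralleling the center recursion and keeping the surround bounded by
  its strength.
- Response onset is the first crossing of 5% of peak after baseline
  subtraction — a configurable package convention. Lag magnitudes depend
  on the threshold, so the tests assert orderings and signs rather than
  magnitudes.
- DSI comparisons at desk scale use small populations and few
  generations; they preserve orderings, not the full-scale magnitudes.
- The EA is a local searcher; repeated seeds (and the identifiability
  guard in the fit summary) are the defence against parameter-level
  degeneracy, and functional quantities (flash kinetics, FWHM) are the
  recommended readouts.
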