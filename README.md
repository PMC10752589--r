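# stwiring

Models of direction selectivity in the retinal bipolar-to-starburst
amacrine cell (SAC) circuit, built around the "space-time wiring"
hypothesis: sustained, delayed bipolar cells contacting proximal SAC
dendrites and transient, short-latency cells contacting distal dendrites
act as a Hassenstein–Reichardt-style correlator, preferring motion
outward from the soma.

The package is aimed at retinal circuit modellers and imaging labs who
want to (a) simulate bipolar→SAC integration under moving-bar stimulation,
(b) ask which presynaptic receptive-field (RF) properties maximize
directional tuning, (c) recover center-surround RF parameters from
glutamate-imaging waveforms recorded under motion, and (d) run the
associated imaging analysis (ROI segmentation, functional clustering, RF
mapping) — all exercisable on synthetic data, with no downloads.

## What is inside

- **Presynaptic RF model** — 9-parameter center-surround Gaussian RF with
  first-order rise dynamics, non-recovering adaptation, divisive
  center-surround interaction
  (`RF_full = A (RF_c + RF_s·rev) / (RF_c + RF_s + R_in)`), a response
  delay, and the iGluSnFR-style difference-of-exponentials sensor filter
  (10/50 ms). Moving bars sweep a 1-mm arena at 0.25–4 mm/s with 2-s dwell.
- **Compartmental SAC** — SWC morphologies (read/write, synthetic
  generator), d-lambda discretization, backward-Euler Hines cable solver
  (Rcpp), N-type-style calcium channels, dendritic calcium pools, synapse
  placement within 110 µm of the soma, current injection, and perisomatic
  resistance manipulations.
- **Directional metrics** — `DSI = (R_out − R_in)/(R_out + R_in)` on peak
  dendritic calcium, the calcium-penalized directional metric
  (`DSI·exp(−(R_out − 500)²/500²)`), transiency index, half-max rise
  times, bidirectional alignment, and motion/flash response lags.
- **Evolutionary training** — elitist EA (keep 2, mutate by
  `N(1, 0.05)` scaling plus ±0.015-of-range uniform shifts) over 23 free
  parameters; scenarios for identical RFs, single-free-parameter models,
  compartmentalization variants, fixed cluster pairs, and 10-µm annuli
  with 5% per-generation cluster swaps.
- **RF estimation from motion** — EA fits of the RF model to
  multi-velocity waveforms by MSE, with repeat-based identifiability
  reporting and held-out full-field-flash validation.
- **Imaging pipeline** — dF/F pixel selection (>20%), waveform-based ROI
  segmentation (≤10 µm, pixel-CV filter), Butterworth + rolling-average
  preprocessing, ward.D2 functional clustering with a log-scale elbow
  rule, filtered back-projection RF maps from oriented bars, and 2-D
  Gaussian fits (`FWHM = 2√(2 ln 2)·σx`).
- **Synthetic data** — deterministic ON (7-cluster) and OFF (6-cluster)
  waveform libraries spanning transient-to-sustained kinetics with two
  wide-field clusters, labelled ROI datasets at chosen SNR, pixel movies
  with ground truth, and oriented-bar response tables.

## Worked example: why motion lag is not flash lag

Wide RF centers start overlapping a moving bar long before the bar
reaches the cell, so wide clusters respond early to motion — but a
full-field flash engages every RF instantly, so flash lag only reflects
processing delay:

```r
library(stwiring)

lib <- gen_cluster_library("ON7")       # 7 deterministic clusters
st  <- make_bar_stimulus(0.5)           # 0.5 mm/s bar, 1-mm arena

widths <- sapply(lib$rf, `[[`, "center_width")
lags <- sapply(lib$rf, function(p) {
  y <- apply_sensor_filter(simulate_bc_response(p, st, rf_x = 500))$rf_filtered
  motion_onset_lag(y, st, rf_x = 500)   # onset relative to bar arrival
})
round(rbind(width_um = sort(widths), lag_ms = lags[order(widths)]))
#>          [,1] [,2] [,3] [,4] [,5] [,6] [,7]
#> width_um   50   65   90  110  140  200  380
#> lag_ms    -69  -84 -128 -177 -218 -363 -765
cor(widths / 2, lags)
#> [1] -0.9984014
```

Motion-onset lag decreases strictly with the RF half-width (r ≈ −1) and
the wide clusters release hundreds of milliseconds before the bar
arrives, while their flash lags are set purely by the delay parameter.
Training the circuit model at desk scale shows the space-time wiring
effect directly:

```r
morph <- generate_synthetic_sac(seed = 1)
full  <- train_ds_model(scenario_spec("full", velocities = c(0.5, 1)),
                        morph, generations = 10, n_pop = 8, seed = 1)
ident <- train_ds_model(scenario_spec("identical", velocities = c(0.5, 1)),
                        morph, generations = 10, n_pop = 8, seed = 1)
c(full = mean(full$dsi), identical = mean(ident$dsi))
#>        full   identical
#> 0.215631012 0.009570794
```

A circuit free to differentiate proximal from distal bipolar kinetics
reaches a mean DSI of ~22% across velocities in ten generations (a few
minutes of CPU), an order of magnitude above the same model constrained
to a single shared RF; full-scale runs (population 16, 100 generations,
five velocities) take hours and reach higher absolute tuning.

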