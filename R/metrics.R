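#' Direction selectivity index
#'
#' \eqn{DSI = (R_{out} - R_{in}) / (R_{out} + R_{in})} on peak responses
#' (here, peak dendritic calcium) for outward vs inward motion.
#'
#' @param r_out,r_in non-negative peak responses; not both zero.
#' @return value in \[-1, 1\].
#' @export
dsi <- function(r_out, r_in) {
  if (any(r_out < 0) || any(r_in < 0)) stop("peak responses must be >= 0", call. = FALSE)
  s <- r_out + r_in
  if (any(s == 0)) stop("DSI undefined when both responses are zero", call. = FALSE)
  (r_out - r_in) / s
}

#' Directional metric with calcium-amplitude penalty
#'
#' Scales the DSI by a Gaussian penalty on the outward calcium peak,
#' \eqn{DSI \cdot e^{-(R_{out} - Ca_{opt})^2 / Ca_{opt}^2}}, which rewards
#' robust signals near the optimal level `ca_opt` and suppresses solutions
#' that maximize DSI by driving calcium toward zero.
#'
#' @param dsi_value a DSI in \[-1, 1\].
#' @param r_out outward peak calcium (nM).
#' @param ca_opt optimal outward calcium level (nM, default 500).
#' @export
directional_metric <- function(dsi_value, r_out, ca_opt = 500) {
  stopifnot_positive(ca_opt, "ca_opt")
  dsi_value * exp(-(r_out - ca_opt)^2 / ca_opt^2)
}

#' Full width at half maximum of a Gaussian
#'
#' @param sigma Gaussian standard deviation (> 0).
#' @return \eqn{2\sqrt{2\ln 2}\,\sigma}.
#' @export
fwhm_from_sigma <- function(sigma) {
  stopifnot_positive(sigma, "sigma")
  2 * sqrt(2 * log(2)) * sigma
}

#' Transiency index
#'
#' `TI = 1 - mean/peak` within the stimulation window: ~1 for a sharp
#' transient, ~0 for a sustained plateau.
#'
#' @param trace numeric response vector.
#' @param window indices of the stimulation window (default: all samples).
#' @export
transiency_index <- function(trace, window = seq_along(trace)) {
  y <- trace[window]
  if (length(y) == 0) stop("empty window", call. = FALSE)
  pk <- max(y)
  if (!is.finite(pk) || pk <= 0) stop("transiency undefined for non-positive peak", call. = FALSE)
  1 - mean(y) / pk
}

#' Half-maximum rise time
#'
#' First upward crossing of 50% of the trace's peak, linearly interpolated
#' between samples.
#'
#' @param trace numeric response vector.
#' @param t optional time axis (defaults to 0-based sample index).
#' @return crossing time in the units of `t`.
#' @export
half_max_rise_time <- function(trace, t = seq_along(trace) - 1) {
  threshold_crossing(trace, t, frac = 0.5)
}

threshold_crossing <- function(trace, t, frac) {
  pk <- max(trace)
  if (!is.finite(pk) || pk <= 0) stop("trace has no positive peak", call. = FALSE)
  thr <- frac * pk
  above <- which(trace >= thr)
  if (length(above) == 0) stop("trace never crosses threshold", call. = FALSE)
  i <- above[1]
  if (i == 1) return(t[1])
  # linear interpolation between samples i-1 and i
  t[i - 1] + (thr - trace[i - 1]) / (trace[i] - trace[i - 1]) * (t[i] - t[i - 1])
}

#' Align responses to the two motion directions
#'
#' Shifts the leftward and rightward motion responses so that each trace's
#' half-maximum rise time lands on the mean of the two rise times, then
#' averages them. The output's half-rise sits exactly between the two input
#' rise times, which removes the dependence of response timing on the RF's
#' spatial position and leaves only response kinetics.
#'
#' @param trace_l,trace_r numeric responses to the two directions, sampled
#'   on the same regular grid.
#' @param dt sample interval (ms).
#' @return the aligned, averaged trace (numeric vector).
#' @export
align_bidirectional <- function(trace_l, trace_r, dt = 1) {
  rl <- half_max_rise_time(trace_l) * dt
  rr <- half_max_rise_time(trace_r) * dt
  ref <- (rl + rr) / 2
  a <- shift_trace(trace_l, ref - rl, dt)
  b <- shift_trace(trace_r, ref - rr, dt)
  (a + b) / 2
}

# Onset = first crossing of `onset_frac` of peak after baseline subtraction.
response_onset <- function(trace, t, onset_frac = 0.05, baseline_n = 1) {
  base <- mean(trace[seq_len(max(1, baseline_n))])
  threshold_crossing(trace - base, t, onset_frac)
}

#' Response lag relative to motion arrival
#'
#' Interval between the response onset (first crossing of `onset_frac` of
#' peak) and the time the bar's leading edge sweeps over the RF position.
#' Negative lags mean the response starts before the bar reaches the cell --
#' the signature of a spatially extensive RF center.
#'
#' @param trace numeric response trace sampled at `stim$dt`.
#' @param stim a bar stimulus spec.
#' @param rf_x RF position in um.
#' @param onset_frac onset threshold as a fraction of peak (default 0.05).
#' @return lag in ms (may be negative).
#' @export
motion_onset_lag <- function(trace, stim, rf_x, onset_frac = 0.05) {
  if (stim$kind != "bar") stop("motion lag requires a bar stimulus", call. = FALSE)
  tt <- seq(0, stim$duration, by = stim$dt)[seq_along(trace)]
  arrival <- if (stim$direction > 0) rf_x / stim$speed else (stim$arena_width - rf_x) / stim$speed
  response_onset(trace, tt, onset_frac) - arrival
}

#' Response lag relative to a flash onset
#'
#' @inheritParams motion_onset_lag
#' @param stim_onset flash onset time (ms) on the trace's time axis.
#' @param dt sample interval in ms.
#' @export
flash_lag <- function(trace, stim_onset = 0, onset_frac = 0.05, dt = 1) {
  tt <- (seq_along(trace) - 1) * dt
  response_onset(trace, tt, onset_frac) - stim_onset
}
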