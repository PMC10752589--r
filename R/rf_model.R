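#' Center-surround receptive-field parameters
#'
#' The bipolar cell is modelled as a point neuron with a spatiotemporal
#' center-surround receptive field (RF). Nine parameters describe one RF:
#' spatial widths (FWHM, um) of the Gaussian center and surround, low-pass
#' rise constants and a center adaptation (decay) constant in units of 1-ms
#' time steps, the surround strength and reversal (both in \[0, 1\]), an
#' overall amplitude in \[0, 1\], and a pure response lag (`delay`, ms).
#'
#' @param amplitude overall response amplitude, in \[0, 1\].
#' @param center_width,surround_width FWHM of the Gaussian center/surround (um).
#' @param center_rise,center_decay,surround_rise temporal constants in time
#'   steps (1 ms each); values below 1 are clipped to 1 for stability.
#' @param surround_strength surround drive scale, in \[0, 1\].
#' @param surround_reversal fraction of the surround conductance that is
#'   excitatory; 0 means pure shunting inhibition. In \[0, 1\].
#' @param delay pure response lag applied to the activation trace (ms, >= 0).
#' @return An object of class `rf_params` (a named list).
#' @examples
#' rf_params(center_width = 50, center_rise = 20, center_decay = 400)
#' @export
rf_params <- function(amplitude = 1, center_width = 50, surround_width = 150,
                      center_rise = 20, center_decay = 400,
                      surround_rise = 50, surround_strength = 0.3,
                      surround_reversal = 0, delay = 0) {
  p <- list(amplitude = amplitude, center_width = center_width,
            surround_width = surround_width, center_rise = center_rise,
            center_decay = center_decay, surround_rise = surround_rise,
            surround_strength = surround_strength,
            surround_reversal = surround_reversal, delay = delay)
  validate_rf_params(p)
  structure(p, class = "rf_params")
}

validate_rf_params <- function(p) {
  for (nm in c("amplitude", "surround_strength", "surround_reversal")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("`%s` must be in [0, 1]", nm), call. = FALSE)
    }
  }
  for (nm in c("center_width", "surround_width", "center_rise",
               "center_decay", "surround_rise")) {
    stopifnot_positive(p[[nm]], nm)
  }
  if (p$delay < 0) stop("`delay` must be >= 0", call. = FALSE)
  invisible(p)
}

#' Fraction of a Gaussian RF component covered by the stimulus
#'
#' Computes the spatial overlap between the stimulus footprint at time `t`
#' and a Gaussian RF component of the given FWHM centred at `rf_x`. The
#' Gaussian mass is normalized to unit total within the arena, so full
#' coverage gives exactly 1. The overlap uses the erf-based closed form of
#' the Gaussian integral over the stimulated interval(s).
#'
#' @param width component FWHM in um (> 0).
#' @param rf_x RF center position in um (inside the arena).
#' @param stim a [make_bar_stimulus()] / [make_flash_stimulus()] spec.
#' @param t time(s) in ms (vectorized).
#' @return numeric vector of fractions in \[0, 1\], one per `t`.
#' @export
rf_area_fraction <- function(width, rf_x, stim, t) {
  stopifnot_positive(width, "width")
  if (rf_x < 0 || rf_x > stim$arena_width) {
    stop("`rf_x` must lie within the arena", call. = FALSE)
  }
  sigma <- fwhm_to_sigma(width)
  total <- pnorm(stim$arena_width, rf_x, sigma) - pnorm(0, rf_x, sigma)
  if (is.null(stim$mask_intervals) && stim$kind == "bar") {
    # vectorized fast path for unmasked bars
    edge <- if (stim$direction > 0) stim$speed * t else stim$arena_width - stim$speed * t
    if (stim$direction > 0) {
      lo <- pmax(edge - stim$bar_width, 0); hi <- pmin(edge, stim$arena_width)
    } else {
      lo <- pmax(edge, 0); hi <- pmin(edge + stim$bar_width, stim$arena_width)
    }
    hi <- pmax(hi, lo)
    frac <- (pnorm(hi, rf_x, sigma) - pnorm(lo, rf_x, sigma)) / total
  } else {
    frac <- vapply(t, function(tt) {
      iv <- stim_intervals(stim, tt)
      if (nrow(iv) == 0) return(0)
      sum(pnorm(iv[, 2], rf_x, sigma) - pnorm(iv[, 1], rf_x, sigma)) / total
    }, numeric(1))
  }
  pmin(pmax(frac * stim$intensity, 0), 1)
}

#' Simulate a bipolar cell's activation trace
#'
#' Runs the per-millisecond RF recursion: the center and surround areas
#' engaged by the stimulus drive low-pass filters; the center is scaled by a
#' non-recovering adaptation state; center and surround are combined by a
#' conductance-style divisive interaction,
#' \deqn{RF_{full} = A \frac{RF_c + RF_s \cdot rev}{RF_c + RF_s + R_{in}}}
#' with \eqn{R_{in} = 0.1 \times area_{c,\infty}} (the unit total center
#' mass). The `delay` parameter shifts the resulting trace in time. The
#' onset timing relative to the bar's arrival at `rf_x` emerges from the
#' spatial overlap computation itself.
#'
#' @param p an [rf_params()] object.
#' @param stim a stimulus spec.
#' @param rf_x RF center position in um (defaults to the arena midpoint).
#' @return An `activation_trace`: a data.frame with columns `t` (ms),
#'   `area_center`, `area_surround`, `rf_center`, `adaptation`,
#'   `rf_surround`, `rf_full`.
#' @examples
#' p <- rf_params(center_width = 60, center_rise = 15, center_decay = 300)
#' tr <- simulate_bc_response(p, make_bar_stimulus(0.5))
#' range(tr$rf_full)
#' @export
simulate_bc_response <- function(p, stim, rf_x = stim$arena_width / 2) {
  validate_rf_params(p)
  tt <- seq(0, stim$duration, by = stim$dt)
  ac <- rf_area_fraction(p$center_width, rf_x, stim, tt)
  as_ <- rf_area_fraction(p$surround_width, rf_x, stim, tt)
  st <- bc_recursion(ac, as_, p)
  out <- data.frame(t = tt, area_center = ac, area_surround = as_,
                    rf_center = st$rf_center, adaptation = st$adaptation,
                    rf_surround = st$rf_surround, rf_full = st$rf_full)
  if (p$delay > 0) {
    for (ch in c("area_center", "area_surround", "rf_center",
                 "rf_surround", "rf_full")) {
      out[[ch]] <- shift_trace(out[[ch]], p$delay, stim$dt)
    }
    out$adaptation <- shift_trace(out$adaptation - 1, p$delay, stim$dt) + 1
  }
  if (anyNA(out$rf_full) || any(!is.finite(out$rf_full))) {
    stop("bipolar RF recursion diverged; parameters: ",
         paste(names(p), unlist(p), sep = "=", collapse = ", "), call. = FALSE)
  }
  class(out) <- c("activation_trace", "data.frame")
  out
}

# Core recursion, vectorized over cells: ac/as_ may be matrices (time x cell),
# p a list whose entries are scalars or per-cell vectors. Rise/decay
# constants below 1 time step are clipped to 1 to keep the update stable.
bc_recursion <- function(ac, as_, p) {
  ac <- as.matrix(ac); as_ <- as.matrix(as_)
  n_c <- ncol(ac)
  out <- bc_recursion_cpp(ac, as_,
                          rep_len(p$center_rise, n_c),
                          rep_len(p$center_decay, n_c),
                          rep_len(p$surround_rise, n_c),
                          rep_len(p$surround_strength, n_c),
                          rep_len(p$surround_reversal, n_c),
                          rep_len(p$amplitude, n_c),
                          0.1)  # R_in = 0.1 x unit total center mass
  lapply(out, drop)
}

# Vectorized multi-cell responses: one column of rf_full per RF position.
# Used by the compartmental visual trials and the synthetic-data generators.
bc_response_matrix <- function(p, stim, rf_x) {
  tt <- seq(0, stim$duration, by = stim$dt)
  sigma_c <- fwhm_to_sigma(p$center_width)
  sigma_s <- fwhm_to_sigma(p$surround_width)
  ac <- vapply(rf_x, function(x) rf_area_fraction(p$center_width, x, stim, tt),
               numeric(length(tt)))
  as_ <- vapply(rf_x, function(x) rf_area_fraction(p$surround_width, x, stim, tt),
                numeric(length(tt)))
  rf <- as.matrix(bc_recursion(ac, as_, p)$rf_full)
  if (p$delay > 0) rf <- apply(rf, 2, shift_trace, shift = p$delay, dt = stim$dt)
  list(t = tt, rf_full = as.matrix(rf))
}

#' Glutamate-sensor temporal filter
#'
#' Convolves an activation trace with the causal difference-of-exponentials
#' kernel \eqn{k(\tau) = e^{-\tau/F_{decay}} - e^{-\tau/F_{rise}}} that
#' emulates iGluSnFR binding/unbinding dynamics. The kernel is normalized to
#' unit peak; its maximum sits at
#' \eqn{\tau^* = \ln(F_{decay}/F_{rise}) F_{rise} F_{decay}/(F_{decay}-F_{rise})}
#' (about 20.1 ms for the 10/50 ms defaults). Output length equals input
#' length.
#'
#' @param trace an `activation_trace` (filters the `rf_full` channel, added
#'   as column `rf_filtered`) or a plain numeric vector.
#' @param f_rise,f_decay filter rise and decay times, ms (`f_decay > f_rise > 0`).
#' @param dt sample interval of `trace` in ms (taken from the trace if present).
#' @return same shape as the input: a trace with an `rf_filtered` column, or
#'   a numeric vector.
#' @export
apply_sensor_filter <- function(trace, f_rise = 10, f_decay = 50, dt = 1) {
  stopifnot_positive(f_rise, "f_rise")
  if (f_rise >= f_decay) stop("`f_rise` must be smaller than `f_decay`", call. = FALSE)
  if (is.data.frame(trace)) {
    dt <- if (nrow(trace) > 1) trace$t[2] - trace$t[1] else dt
    trace$rf_filtered <- sensor_convolve(trace$rf_full, f_rise, f_decay, dt)
    return(trace)
  }
  sensor_convolve(trace, f_rise, f_decay, dt)
}

sensor_kernel <- function(f_rise, f_decay, dt) {
  tau <- seq(0, 8 * f_decay, by = dt)
  k <- exp(-tau / f_decay) - exp(-tau / f_rise)
  k / max(k)
}

# The sampled difference-of-exponentials kernel is implemented exactly as
# the difference of two first-order recursive filters (the geometric-series
# form of the convolution), normalized to unit kernel peak.
sensor_convolve <- function(y, f_rise, f_decay, dt) {
  ed <- as.numeric(stats::filter(y, exp(-dt / f_decay), method = "recursive"))
  er <- as.numeric(stats::filter(y, exp(-dt / f_rise), method = "recursive"))
  tau_pk <- log(f_decay / f_rise) * f_rise * f_decay / (f_decay - f_rise)
  # peak of the sampled kernel (discrete grid around the analytic maximum)
  tg <- dt * (floor(tau_pk / dt) + c(0, 1))
  pk <- max(exp(-tg / f_decay) - exp(-tg / f_rise))
  (ed - er) / pk
}
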