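#' Visual stimulus specifications
#'
#' Stimuli are defined over a one-dimensional 1-mm arena sampled at
#' \eqn{\Delta t = 1} ms. A moving bar is described by its speed (mm/s, which
#' equals um/ms), direction (+1 for left-to-right, -1 for right-to-left) and
#' dwell time: the bar is long enough that every arena position is stimulated
#' for exactly `dwell_time` seconds (bar width = speed x dwell time). A flash
#' covers the whole arena for its duration.
#'
#' @param speed bar speed in mm/s (> 0).
#' @param direction +1 (left to right) or -1 (right to left).
#' @param arena_width arena width in um.
#' @param dwell_time time each position stays stimulated, in seconds.
#' @param dt time step in ms.
#' @param intensity stimulus intensity in \[0, 1\] (background is 0).
#' @param mask_intervals optional list of `c(x0, x1)` um ranges held at
#'   background regardless of the bar position.
#'
#' @return An object of class `stimulus_spec` with fields `kind`, `speed`,
#'   `direction`, `arena_width`, `dwell_time`, `bar_width`, `duration` (ms),
#'   `dt`, `intensity`, `mask_intervals`.
#' @examples
#' st <- make_bar_stimulus(speed = 0.5)
#' st$bar_width   # 1000 um: 0.5 um/ms * 2000 ms dwell
#' @export
make_bar_stimulus <- function(speed, direction = 1, arena_width = 1000,
                              dwell_time = 2, dt = 1, intensity = 1,
                              mask_intervals = NULL) {
  stopifnot_positive(speed, "speed")
  stopifnot_positive(arena_width, "arena_width")
  stopifnot_positive(dwell_time, "dwell_time")
  stopifnot_positive(dt, "dt")
  if (!direction %in% c(1, -1)) stop("`direction` must be +1 or -1", call. = FALSE)
  if (intensity < 0 || intensity > 1) stop("`intensity` must be in [0, 1]", call. = FALSE)
  bar_width <- speed * dwell_time * 1000   # um (speed mm/s == um/ms)
  duration <- (arena_width + bar_width) / speed  # ms until trailing edge exits
  structure(list(
    kind = "bar", speed = speed, direction = direction,
    arena_width = arena_width, dwell_time = dwell_time,
    bar_width = bar_width, duration = duration, dt = dt,
    intensity = intensity, mask_intervals = mask_intervals
  ), class = "stimulus_spec")
}

#' @rdname make_bar_stimulus
#' @param duration flash duration in seconds.
#' @export
make_flash_stimulus <- function(duration = 4, arena_width = 1000, dt = 1,
                                intensity = 1) {
  stopifnot_positive(duration, "duration")
  stopifnot_positive(arena_width, "arena_width")
  structure(list(
    kind = "flash", speed = NA_real_, direction = NA_real_,
    arena_width = arena_width, dwell_time = NA_real_,
    bar_width = NA_real_, duration = duration * 1000, dt = dt,
    intensity = intensity, mask_intervals = NULL
  ), class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  if (x$kind == "bar") {
    cat(sprintf("<stimulus_spec: bar %.3g mm/s dir %+d, arena %g um, bar %g um, %g ms>\n",
                x$speed, x$direction, x$arena_width, x$bar_width, x$duration))
  } else {
    cat(sprintf("<stimulus_spec: flash %g ms, arena %g um>\n", x$duration, x$arena_width))
  }
  invisible(x)
}

# Stimulated x-intervals (um) at time t (ms), within the arena, before masking.
# Returns a 2-column matrix of [lo, hi] intervals (possibly 0 rows).
stim_intervals <- function(stim, t) {
  if (stim$kind == "flash") {
    if (t >= 0 && t <= stim$duration) {
      iv <- matrix(c(0, stim$arena_width), 1)
    } else {
      iv <- matrix(numeric(0), 0, 2)
    }
  } else {
    if (stim$direction > 0) {
      edge <- stim$speed * t                 # leading edge position
      lo <- edge - stim$bar_width
      hi <- edge
    } else {
      edge <- stim$arena_width - stim$speed * t
      lo <- edge
      hi <- edge + stim$bar_width
    }
    lo <- max(lo, 0); hi <- min(hi, stim$arena_width)
    iv <- if (hi > lo) matrix(c(lo, hi), 1) else matrix(numeric(0), 0, 2)
  }
  if (!is.null(stim$mask_intervals) && nrow(iv) > 0) {
    for (m in stim$mask_intervals) {
      iv <- interval_subtract(iv, m[1], m[2])
    }
  }
  iv
}

interval_subtract <- function(iv, m0, m1) {
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(iv))) {
    a <- iv[i, 1]; b <- iv[i, 2]
    if (m1 <= a || m0 >= b) { out <- rbind(out, c(a, b)); next }
    if (m0 > a) out <- rbind(out, c(a, m0))
    if (m1 < b) out <- rbind(out, c(m1, b))
  }
  out
}

# Indicator s(x, t) evaluated on a spatial grid (used by tests/oracles).
stim_indicator <- function(stim, x, t) {
  iv <- stim_intervals(stim, t)
  s <- numeric(length(x))
  for (i in seq_len(nrow(iv))) s[x >= iv[i, 1] & x <= iv[i, 2]] <- stim$intensity
  s
}
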