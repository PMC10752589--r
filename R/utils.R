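# shared internal helpers

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
# Keeps generators deterministic per seed without clobbering the global stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Shift a regularly sampled trace by `shift` time units (positive = later),
# linear interpolation, zero padding at the ends.
shift_trace <- function(y, shift, dt) {
  n <- length(y)
  t <- seq_len(n)
  approx(x = t + shift / dt, y = y, xout = t, rule = 1)$y -> out
  out[is.na(out)] <- 0
  out
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
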