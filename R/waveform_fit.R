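# Generic elitist EA loop over a numeric objective (maximized). Reuses the
# same selection/mutation machinery as the circuit training.
ea_optimize <- function(objective, bounds, n_pop = 16, generations = 60,
                        seed = 1) {
  with_seed(seed, {
    pop <- list(params = init_population(bounds, n = n_pop, seed = seed + 1),
                annuli = NULL, fitness = rep(NA_real_, n_pop))
    history <- numeric(generations)
    for (gen in seq_len(generations)) {
      for (i in which(is.na(pop$fitness))) {
        pop$fitness[i] <- objective(setNames(pop$params[i, ], colnames(pop$params)))
      }
      history[gen] <- max(pop$fitness)
      if (gen < generations) pop <- step_generation(pop, bounds)
    }
    best_i <- which.max(pop$fitness)
    list(best = setNames(pop$params[best_i, ], colnames(pop$params)),
         fitness = pop$fitness[best_i], history = history, population = pop)
  })
}

#' Define an RF-fitting task from motion waveforms
#'
#' @param waveforms list of numeric target traces, one per velocity,
#'   sampled at 1 ms; each is the sensor-filtered, peak-normalized response
#'   of one functional cluster to a bar at the matching velocity.
#' @param velocities bar speeds (mm/s), same length as `waveforms`.
#' @param rf_x RF position used to generate model waveforms (um).
#' @param f_rise,f_decay sensor filter times (ms).
#' @param n_repeats number of independent fit repeats.
#' @param seed root seed; repeat `i` uses `seed + i`.
#' @export
fit_task <- function(waveforms, velocities = c(0.25, 0.5, 1, 2, 4),
                     rf_x = 500, f_rise = 10, f_decay = 50,
                     n_repeats = 10, seed = 1) {
  if (length(waveforms) != length(velocities)) {
    stop("one waveform per velocity required", call. = FALSE)
  }
  if (length(velocities) < 2) stop("at least 2 velocities required", call. = FALSE)
  if (any(!vapply(waveforms, function(w) all(is.finite(w)), logical(1)))) {
    stop("target waveforms must be finite", call. = FALSE)
  }
  list(waveforms = waveforms, velocities = velocities, rf_x = rf_x,
       f_rise = f_rise, f_decay = f_decay, n_repeats = n_repeats, seed = seed)
}

# normalize a trace to unit peak (zero traces pass through unchanged)
peak_normalize <- function(y) {
  pk <- max(y)
  if (pk > 0) y / pk else y
}

# model waveform for one velocity: simulated RF response through the
# sensor filter, peak-normalized
model_motion_waveform <- function(p, velocity, rf_x, f_rise, f_decay,
                                  n_out = NULL) {
  stim <- make_bar_stimulus(velocity)
  rf <- bc_response_matrix(p, stim, rf_x)$rf_full[, 1]
  y <- sensor_convolve(rf, f_rise, f_decay, stim$dt)
  if (!is.null(n_out)) y <- y[seq_len(n_out)]
  peak_normalize(y)
}

fit_mse <- function(p, task) {
  tot <- 0
  for (i in seq_along(task$velocities)) {
    target <- peak_normalize(task$waveforms[[i]])
    if (max(target) > 0) {
      y <- model_motion_waveform(p, task$velocities[i], task$rf_x,
                                 task$f_rise, task$f_decay,
                                 n_out = length(target))
    } else {
      # a silent target cannot constrain a normalized shape: compare the
      # raw sensor-filtered output so the fit drives the amplitude down
      stim <- make_bar_stimulus(task$velocities[i])
      rf <- bc_response_matrix(p, stim, task$rf_x)$rf_full[, 1]
      y <- sensor_convolve(rf, task$f_rise, task$f_decay, stim$dt)[seq_along(target)]
    }
    tot <- tot + mean((y - target)^2)
  }
  tot / length(task$velocities)
}

#' Estimate center-surround RF parameters from motion waveforms
#'
#' Fits the 9-parameter RF model to multi-velocity motion waveforms by
#' minimizing the mean squared error between peak-normalized,
#' sensor-filtered model responses and the targets, using the same elitist
#' EA as the circuit training. Repeated fits from independent seeds
#' quantify identifiability; because targets are peak-normalized, the
#' absolute amplitude is not identifiable and is reported as such.
#'
#' @param task a [fit_task()].
#' @param n_pop,generations EA size.
#' @return a `fit_result`: `estimates` (data.frame, one row per repeat),
#'   `mse` per repeat, `best` ([rf_params()] of the lowest-MSE repeat),
#'   `summary` (mean and SD per parameter).
#' @export
fit_rf_to_motion <- function(task, n_pop = 24, generations = 120) {
  bounds <- param_bounds("presynaptic")
  pre_names <- bounds$name
  as_rf <- function(v) do.call(rf_params, as.list(setNames(v, pre_names)))
  fits <- vector("list", task$n_repeats)
  mses <- numeric(task$n_repeats)
  for (r in seq_len(task$n_repeats)) {
    opt <- ea_optimize(function(v) -fit_mse(as_rf(v), task), bounds,
                       n_pop = n_pop, generations = generations,
                       seed = task$seed + r)
    fits[[r]] <- opt$best
    mses[r] <- -opt$fitness
  }
  est <- as.data.frame(do.call(rbind, fits))
  summary <- data.frame(parameter = pre_names,
                        mean = colMeans(est), sd = apply(est, 2, sd))
  # amplitude is unidentifiable for normalized targets
  summary$identifiable <- summary$parameter != "amplitude"
  structure(list(estimates = est, mse = mses,
                 best = as_rf(unlist(fits[[which.min(mses)]])),
                 summary = summary, task = task),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %d repeats, best MSE %.3g, center FWHM %.1f +/- %.1f um>\n",
              length(x$mse), min(x$mse),
              mean(x$estimates$center_width), sd(x$estimates$center_width)))
  invisible(x)
}

#' Predict the full-field flash response of a fitted RF
#'
#' Flash responses are not part of the motion training set, so they serve
#' as held-out validation of the fitted RF model.
#'
#' @param p an [rf_params()].
#' @param duration flash duration (s).
#' @param f_rise,f_decay sensor filter times (ms).
#' @param normalize peak-normalize the output.
#' @return data.frame with `t` (ms) and `response`.
#' @export
predict_flash <- function(p, duration = 4, f_rise = 10, f_decay = 50,
                          normalize = TRUE) {
  stim <- make_flash_stimulus(duration)
  tr <- simulate_bc_response(p, stim)
  y <- apply_sensor_filter(tr, f_rise, f_decay)$rf_filtered
  if (normalize) y <- peak_normalize(y)
  data.frame(t = tr$t, response = y)
}

#' Validate fitted RFs against flash responses
#'
#' Compares, per cluster, the flash rise time, flash lag and center FWHM of
#' the fitted model against values measured from validation traces.
#'
#' @param result a `fit_result`.
#' @param validation numeric flash trace (sampled at 1 ms from flash onset)
#'   to compare against.
#' @param measured_fwhm optional independently measured center FWHM (um).
#' @return data.frame with model vs measured flash rise time (ms), flash
#'   lag (ms) and center FWHM (um).
#' @export
evaluate_fit <- function(result, validation, measured_fwhm = NA_real_) {
  pred <- predict_flash(result$best)$response
  n <- min(length(pred), length(validation))
  data.frame(
    quantity = c("flash_rise_time_ms", "flash_lag_ms", "center_fwhm_um"),
    model = c(half_max_rise_time(pred[seq_len(n)]),
              flash_lag(pred[seq_len(n)]),
              result$best$center_width),
    measured = c(half_max_rise_time(validation[seq_len(n)]),
                 flash_lag(validation[seq_len(n)]),
                 measured_fwhm))
}
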