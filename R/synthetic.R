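#' Synthetic functional-cluster library
#'
#' Builds a library of bipolar RF parameter sets emulating the qualitative
#' spectrum of glutamate release clusters recorded on SAC dendrites: a
#' transient wide-field cluster with a long processing delay (C1), a second
#' wide cluster (C4), and narrow-field clusters grading from transient and
#' short-lag to sustained and delayed. Libraries are sorted by transiency
#' index (most transient first) and carry per-cluster prevalences.
#'
#' @param kind `"ON7"` (7 clusters), `"OFF6"` (6), or `"custom"`.
#' @param seed RNG seed (reserved for `custom` jitter; the named libraries
#'   are deterministic).
#' @param custom for `kind = "custom"`: list of [rf_params()].
#' @return a `cluster_library`: list with `rf` (list of [rf_params()]),
#'   `prevalence`, `transiency` (of the 0.5 mm/s waveform), `kind`, and
#'   `meta` describing the generating distributions.
#' @export
gen_cluster_library <- function(kind = c("ON7", "OFF6", "custom"), seed = 1,
                                custom = NULL) {
  kind <- match.arg(kind)
  # Archetypes: each cluster has a unique center width (so lag-vs-width
  # analyses have ground truth), a delay that grows with width (wide RFs
  # carry the longest flash lags), and a distinct waveform shape at the
  # 0.5 mm/s reference velocity.
  base <- switch(kind,
    ON7 = list(
      # wide transient with a long processing delay (C1-like)
      rf_params(center_width = 380, surround_width = 560, center_rise = 10,
                center_decay = 150, surround_rise = 60,
                surround_strength = 0.35, delay = 80),
      # sharp narrow transient
      rf_params(center_width = 50, surround_width = 150, center_rise = 8,
                center_decay = 90, surround_rise = 40,
                surround_strength = 0.50, delay = 10),
      # transient with an elevated, slowly decaying tail
      rf_params(center_width = 65, surround_width = 190, center_rise = 25,
                center_decay = 320, surround_rise = 50,
                surround_strength = 0.10, delay = 15),
      # second wide cluster (C4-like), transient
      rf_params(center_width = 200, surround_width = 420, center_rise = 20,
                center_decay = 250, surround_rise = 80,
                surround_strength = 0.30, delay = 55),
      # wide-ish plateau with a late surround-driven sag
      rf_params(center_width = 140, surround_width = 340, center_rise = 25,
                center_decay = 2000, surround_rise = 250,
                surround_strength = 0.25, delay = 35),
      # sustained plateau (negligible adaptation and surround)
      rf_params(center_width = 90, surround_width = 260, center_rise = 20,
                center_decay = 2000, surround_rise = 120,
                surround_strength = 0.02, delay = 20),
      # fast spike followed by a deep shunt to a low sustained level
      rf_params(center_width = 110, surround_width = 300, center_rise = 8,
                center_decay = 280, surround_rise = 60,
                surround_strength = 0.80, delay = 25)),
    OFF6 = list(
      rf_params(center_width = 55, surround_width = 160, center_rise = 8,
                center_decay = 90, surround_rise = 40,
                surround_strength = 0.50, delay = 10),
      rf_params(center_width = 70, surround_width = 200, center_rise = 25,
                center_decay = 320, surround_rise = 50,
                surround_strength = 0.10, delay = 15),
      rf_params(center_width = 95, surround_width = 270, center_rise = 20,
                center_decay = 2000, surround_rise = 120,
                surround_strength = 0.02, delay = 20),
      rf_params(center_width = 120, surround_width = 320, center_rise = 8,
                center_decay = 280, surround_rise = 60,
                surround_strength = 0.80, delay = 25),
      rf_params(center_width = 160, surround_width = 380, center_rise = 25,
                center_decay = 2000, surround_rise = 250,
                surround_strength = 0.25, delay = 40),
      # wide transient, longest delay
      rf_params(center_width = 260, surround_width = 480, center_rise = 12,
                center_decay = 180, surround_rise = 70,
                surround_strength = 0.35, delay = 65)),
    custom = custom)
  if (is.null(base) || length(base) < 2) {
    stop("a cluster library needs at least 2 clusters", call. = FALSE)
  }
  prevalence <- switch(kind,
    ON7 = c(0.10, 0.20, 0.18, 0.08, 0.16, 0.15, 0.13),
    OFF6 = c(0.22, 0.10, 0.20, 0.18, 0.16, 0.14),
    custom = rep(1 / length(base), length(base)))
  # reference waveform at 0.5 mm/s, sensor-filtered; sort by transiency
  stim <- make_bar_stimulus(0.5)
  waves <- lapply(base, function(p) {
    peak_normalize(apply_sensor_filter(simulate_bc_response(p, stim))$rf_filtered)
  })
  ti <- vapply(waves, function(w) transiency_index(pmax(w, 0)), numeric(1))
  ord <- order(ti, decreasing = TRUE)
  structure(list(rf = base[ord], prevalence = prevalence[ord] /
                   sum(prevalence), transiency = ti[ord], kind = kind,
                 meta = list(
                   reference_velocity = 0.5,
                   description = "clusters sorted by transiency of the 0.5 mm/s sensor-filtered waveform",
                   seed = seed)),
            class = "cluster_library")
}

#' @export
print.cluster_library <- function(x, ...) {
  cat(sprintf("<cluster_library %s: %d clusters, TI %s>\n", x$kind,
              length(x$rf), paste(sprintf("%.2f", x$transiency), collapse = " ")))
  invisible(x)
}

#' Synthetic ROI dataset with known cluster labels
#'
#' Draws each ROI's cluster from the library prevalences, places its RF at
#' a random arena position, simulates sensor-filtered responses to both
#' directions at every velocity, and adds Gaussian noise plus per-ROI
#' amplitude scatter. Ground-truth labels are retained.
#'
#' @param library a `cluster_library`.
#' @param n_rois number of ROIs.
#' @param velocities bar speeds (mm/s).
#' @param noise_sd additive Gaussian SD in units of the unit-peak waveform
#'   (0.1 = SNR 10).
#' @param amp_sd SD of the per-ROI multiplicative amplitude scatter.
#' @param rf_x_range range of RF positions (um).
#' @param seed RNG seed.
#' @return a `roi_dataset`: `traces` (list per ROI of per-velocity lists
#'   with elements `l` and `r`), `labels`, `rf_x`, `velocities`, `library`.
#' @export
gen_roi_dataset <- function(library, n_rois = 334,
                            velocities = c(0.25, 0.5, 1, 2, 4),
                            noise_sd = 0.1, amp_sd = 0.1,
                            rf_x_range = c(350, 650), seed = 1) {
  if (n_rois < length(library$rf)) {
    stop("`n_rois` must be at least the number of clusters", call. = FALSE)
  }
  with_seed(seed, {
    labels <- sample.int(length(library$rf), n_rois, replace = TRUE,
                         prob = library$prevalence)
    rf_x <- runif(n_rois, rf_x_range[1], rf_x_range[2])
    amp <- pmax(0.2, rnorm(n_rois, 1, amp_sd))
    stims <- lapply(velocities, function(v) {
      list(l = make_bar_stimulus(v, direction = 1),
           r = make_bar_stimulus(v, direction = -1))
    })
    # cache clean per-cluster waveforms on a position grid (5 um)
    traces <- vector("list", n_rois)
    for (i in seq_len(n_rois)) {
      p <- library$rf[[labels[i]]]
      per_v <- vector("list", length(velocities))
      for (vi in seq_along(velocities)) {
        wl <- apply_sensor_filter(
          simulate_bc_response(p, stims[[vi]]$l, rf_x = rf_x[i]))$rf_filtered
        wr <- apply_sensor_filter(
          simulate_bc_response(p, stims[[vi]]$r, rf_x = rf_x[i]))$rf_filtered
        scale <- amp[i] / max(max(wl), max(wr), 1e-12)
        per_v[[vi]] <- list(
          l = wl * scale + rnorm(length(wl), 0, noise_sd),
          r = wr * scale + rnorm(length(wr), 0, noise_sd))
      }
      traces[[i]] <- per_v
    }
    structure(list(traces = traces, labels = labels, rf_x = rf_x,
                   velocities = velocities, library = library,
                   meta = list(noise_sd = noise_sd, amp_sd = amp_sd,
                               rf_x_range = rf_x_range, seed = seed,
                               noise = "additive iid Gaussian; amplitude ~ N(1, amp_sd) truncated at 0.2")),
              class = "roi_dataset")
  })
}

#' Aligned waveform matrix for functional clustering
#'
#' Preprocesses each ROI's two directional responses at the reference
#' velocity and aligns them by half-maximum rise time into a single trace,
#' cropped to a window around the alignment point.
#'
#' @param dataset a `roi_dataset`.
#' @param velocity reference velocity (mm/s; must be in the dataset).
#' @param window half-width of the crop around the mean half-rise (ms).
#' @return matrix (ROIs x time) of aligned, normalized waveforms.
#' @export
roi_aligned_matrix <- function(dataset, velocity = 0.5, window = 1000) {
  vi <- match(velocity, dataset$velocities)
  if (is.na(vi)) stop("velocity not present in dataset", call. = FALSE)
  out <- NULL
  for (i in seq_along(dataset$traces)) {
    tl <- preprocess_trace(dataset$traces[[i]][[vi]]$l)
    tr <- preprocess_trace(dataset$traces[[i]][[vi]]$r)
    al <- align_bidirectional(tl, tr)
    ref <- round(half_max_rise_time(al))
    idx <- (ref - window):(ref + window)
    idx <- pmin(pmax(idx, 1), length(al))
    if (is.null(out)) out <- matrix(0, length(dataset$traces), length(idx))
    out[i, ] <- al[idx]
  }
  out
}

#' Synthetic dF/F movie with known pixel-to-ROI map
#'
#' Renders ROI footprints (discs) into a pixel grid, assigns each source's
#' trace to its pixels through an optional Gaussian point-spread blur, and
#' adds pixel noise.
#'
#' @param layout data.frame with `x`, `y` (um) and `radius` (um) per source.
#' @param traces matrix (time x source) of dF/F traces.
#' @param nx,ny movie dimensions in pixels.
#' @param pixel_size um per pixel (1.28 matches 2x2-binned scans).
#' @param frame_rate Hz.
#' @param psf_sigma Gaussian blur SD (um); 0 for a delta PSF.
#' @param noise_sd additive pixel noise SD (dF/F).
#' @param seed RNG seed.
#' @return a movie list: `frames` (nx x ny x t), `pixel_size`, `frame_rate`,
#'   `truth` (integer pixel-to-source matrix, 0 = background).
#' @export
gen_movie <- function(layout, traces, nx = 128, ny = 64, pixel_size = 1.28,
                      frame_rate = 50, psf_sigma = 0, noise_sd = 0.02,
                      seed = 1) {
  traces <- as.matrix(traces)
  if (nrow(layout) != ncol(traces)) {
    stop("one trace column per layout row required", call. = FALSE)
  }
  px <- (seq_len(nx) - 0.5) * pixel_size
  py <- (seq_len(ny) - 0.5) * pixel_size
  truth <- matrix(0L, nx, ny)
  weights <- array(0, c(nx, ny, nrow(layout)))
  for (s in seq_len(nrow(layout))) {
    d2 <- outer((px - layout$x[s])^2, (py - layout$y[s])^2, `+`)
    inside <- d2 <= layout$radius[s]^2
    if (any(truth[inside] != 0L)) warning("overlapping ROI footprints in layout")
    truth[inside] <- s
    if (psf_sigma > 0) {
      weights[, , s] <- exp(-pmax(sqrt(d2) - layout$radius[s], 0)^2 /
                            (2 * psf_sigma^2))
    } else {
      weights[, , s] <- inside * 1
    }
  }
  n_t <- nrow(traces)
  with_seed(seed, {
    frames <- array(rnorm(nx * ny * n_t, 0, noise_sd), c(nx, ny, n_t))
    for (s in seq_len(nrow(layout))) {
      w <- weights[, , s]
      sel <- which(w > 1e-6)
      for (ti in seq_len(n_t)) {
        fr <- frames[, , ti]
        fr[sel] <- fr[sel] + w[sel] * traces[ti, s]
        frames[, , ti] <- fr
      }
    }
    list(frames = frames, pixel_size = pixel_size, frame_rate = frame_rate,
         truth = truth,
         meta = list(psf_sigma = psf_sigma, noise_sd = noise_sd, seed = seed))
  })
}

#' Synthetic oriented-bar RF-mapping responses
#'
#' Emulates the RF-mapping protocol: 10-um-wide bars flashed at 32
#' positions along the normal axis of each of five orientations (36 deg
#' spacing). The per-bar response is the RF's Gaussian mass under the bar
#' strip (closed form in the bar-normal coordinate) scaled by the temporal
#' model's flash peak, plus noise.
#'
#' @param params an [rf_params()]; `center_width` sets the spatial Gaussian.
#' @param center RF center (x, y) in map coordinates (um).
#' @param orientations bar orientations (degrees).
#' @param n_positions positions per orientation.
#' @param spacing position spacing (um).
#' @param bar_width bar width (um).
#' @param noise_sd additive noise SD relative to the peak response.
#' @param seed RNG seed.
#' @return list with `responses` (orientations x positions), `orientations`,
#'   `positions`, `center`, `params`.
#' @export
gen_oriented_bar_responses <- function(params, center = c(0, 0),
                                       orientations = seq(0, 144, by = 36),
                                       n_positions = 32, spacing = 10,
                                       bar_width = 10, noise_sd = 0.02,
                                       seed = 1) {
  sigma <- fwhm_to_sigma(params$center_width)
  positions <- (seq_len(n_positions) - (n_positions + 1) / 2) * spacing
  flash_peak <- max(simulate_bc_response(params, make_flash_stimulus(0.5))$rf_full)
  with_seed(seed, {
    resp <- matrix(0, length(orientations), n_positions)
    for (i in seq_along(orientations)) {
      phi <- orientations[i] * pi / 180
      d <- center[1] * cos(phi) + center[2] * sin(phi)
      resp[i, ] <- pnorm(positions - d + bar_width / 2, 0, sigma) -
                   pnorm(positions - d - bar_width / 2, 0, sigma)
    }
    resp <- flash_peak * resp / max(resp) +
      rnorm(length(resp), 0, noise_sd * flash_peak)
    resp <- matrix(resp, length(orientations), n_positions)
    list(responses = resp, orientations = orientations, positions = positions,
         center = center, params = params,
         meta = list(noise_sd = noise_sd, seed = seed))
  })
}
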