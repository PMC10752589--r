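#' Select responsive pixels from a dF/F movie
#'
#' @param movie a movie list with `frames` (array x-by-y-by-t, dF/F units),
#'   `pixel_size` (um) and `frame_rate` (Hz); see [gen_movie()].
#' @param threshold dF/F threshold (default 0.20): pixels whose maximum
#'   response exceeds it are selected.
#' @return logical matrix (x-by-y) pixel mask.
#' @export
select_active_pixels <- function(movie, threshold = 0.20) {
  mx <- apply(movie$frames, c(1, 2), max)
  mask <- is.finite(mx) & mx > threshold
  if (!any(mask)) warning("no pixels exceed the dF/F threshold")
  mask
}

# 4-connected components of a logical matrix; returns an integer label matrix
connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask)) next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- cur
      stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                 list(p + c(0, 1)), list(p - c(0, 1)))
    }
  }
  lab
}

#' Segment responsive pixels into ROIs
#'
#' First-stage clustering: pixels under the mask are grouped by the
#' similarity (correlation distance) of their response waveforms with
#' agglomerative clustering; the number of waveform clusters is increased
#' until, after splitting each cluster into spatially connected components,
#' no ROI spans more than `max_extent` um. ROIs whose pixels vary more than
#' `cv_max` (coefficient of variation of pixel peak amplitudes) are
#' dropped.
#'
#' @param movie a movie list (see [select_active_pixels()]).
#' @param mask logical pixel mask.
#' @param max_extent maximum ROI span (um).
#' @param cv_max maximum pixel CV within an ROI.
#' @param min_pixels smallest ROI retained.
#' @return list of `roi_trace` objects: `pixels` (index matrix), `centroid`
#'   (um), `trace` (mean dF/F), `cv`.
#' @export
segment_rois <- function(movie, mask, max_extent = 10, cv_max = 1,
                         min_pixels = 2) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) < 2) stop("need at least 2 active pixels", call. = FALSE)
  traces <- t(apply(px, 1, function(p) movie$frames[p[1], p[2], ]))
  d <- as.dist(1 - cor(t(traces)))
  d[!is.finite(d)] <- 2
  hc <- hclust(d, method = "ward.D2")
  extent_of <- function(rows) {
    if (length(rows) == 1) return(0)
    xy <- px[rows, , drop = FALSE] * movie$pixel_size
    max(dist(xy))
  }
  for (k in seq_len(nrow(px))) {
    cl <- cutree(hc, k)
    rois <- list()
    ok <- TRUE
    for (g in unique(cl)) {
      rows <- which(cl == g)
      sub <- matrix(FALSE, nrow(mask), ncol(mask))
      sub[px[rows, , drop = FALSE]] <- TRUE
      lab <- connected_components(sub)
      for (cc in seq_len(max(lab))) {
        cc_px <- which(lab == cc, arr.ind = TRUE)
        rows_cc <- which(mask_rows(px, cc_px))
        if (extent_of(rows_cc) > max_extent) { ok <- FALSE; break }
        rois[[length(rois) + 1L]] <- rows_cc
      }
      if (!ok) break
    }
    if (ok) break
  }
  out <- list()
  for (rows in rois) {
    if (length(rows) < min_pixels) next
    tr <- colMeans(traces[rows, , drop = FALSE])
    pk <- apply(traces[rows, , drop = FALSE], 1, max)
    cv <- if (mean(pk) > 0) sd(pk) / mean(pk) else Inf
    if (!is.finite(cv) || cv > cv_max) next
    out[[length(out) + 1L]] <- structure(list(
      pixels = px[rows, , drop = FALSE],
      centroid = colMeans(px[rows, , drop = FALSE]) * movie$pixel_size,
      trace = tr, cv = cv), class = "roi_trace")
  }
  out
}

mask_rows <- function(px, cc_px) {
  key <- paste(px[, 1], px[, 2])
  key %in% paste(cc_px[, 1], cc_px[, 2])
}

#' Preprocess a dF/F trace
#'
#' First-order Butterworth low-pass (normalized critical frequency 0.1,
#' zero-phase), rolling-average smoothing, baseline subtraction
#' (pre-stimulus mean) and peak normalization to 1.
#'
#' @param trace numeric dF/F trace.
#' @param critical normalized Butterworth critical frequency.
#' @param roll_window rolling-average window (samples).
#' @param baseline_n number of leading samples treated as baseline.
#' @return preprocessed trace with peak exactly 1.
#' @export
preprocess_trace <- function(trace, critical = 0.1, roll_window = 5,
                             baseline_n = max(2L, round(length(trace) * 0.05))) {
  if (any(!is.finite(trace))) stop("trace must be finite", call. = FALSE)
  bf <- signal::butter(1, critical)
  # remove the leading level before zero-phase filtering so the filter's
  # zero initial conditions do not inject an edge transient
  y <- as.numeric(signal::filtfilt(bf, trace - trace[1]))
  k <- roll_window
  pad <- c(rep(y[1], k), y, rep(y[length(y)], k))
  sm <- as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2))
  y <- sm[seq_along(y) + k]
  y <- y - mean(y[seq_len(baseline_n)])
  pk <- max(y)
  if (!is.finite(pk) || pk <= 0) stop("zero peak: cannot normalize", call. = FALSE)
  y / pk
}

#' Cluster ROI waveforms into functional clusters
#'
#' Second-stage clustering: agglomerative (`ward.D2`) clustering of aligned,
#' normalized motion-response waveforms with Euclidean or maximum distance.
#' Time points whose across-ROI variance falls below `variance_floor` can
#' be discarded before clustering. The within-cluster variance curve is
#' computed for k = 1..`k_max`; if `k` is not given it is chosen by
#' [elbow_cluster_count()]. Cluster ids are relabelled in order of
#' decreasing transiency (C1 = most transient).
#'
#' @param waveforms matrix (ROIs x time) of aligned, normalized waveforms.
#' @param k number of clusters (default: elbow rule).
#' @param distance `"euclidean"` or `"maximum"`.
#' @param variance_floor variance threshold for time-point selection.
#' @param k_max largest k scanned for the variance curve.
#' @return a `cluster_set`: `assignment` (per ROI), `centers` (cluster mean
#'   waveforms), `center_sd`, `wcv` (within-cluster variance for k = 1..k_max),
#'   `k`, `transiency` (per cluster).
#' @export
cluster_rois <- function(waveforms, k = NULL, distance = c("euclidean", "maximum"),
                         variance_floor = 0, k_max = 12) {
  distance <- match.arg(distance)
  waveforms <- as.matrix(waveforms)
  if (nrow(waveforms) < 2) stop("need at least 2 ROIs", call. = FALSE)
  keep <- apply(waveforms, 2, var) >= variance_floor
  feat <- waveforms[, keep, drop = FALSE]
  hc <- hclust(dist(feat, method = distance), method = "ward.D2")
  k_max <- min(k_max, nrow(waveforms) - 1L)
  wcv <- vapply(seq_len(k_max), function(kk) {
    cl <- cutree(hc, kk)
    sum(vapply(unique(cl), function(g) {
      sub <- feat[cl == g, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }, numeric(1))
  if (is.null(k)) k <- elbow_cluster_count(wcv)
  if (k > k_max) stop("fewer ROIs than requested clusters", call. = FALSE)
  cl <- cutree(hc, k)
  centers <- t(vapply(seq_len(k), function(g)
    colMeans(waveforms[cl == g, , drop = FALSE]), numeric(ncol(waveforms))))
  ti <- vapply(seq_len(k), function(g) transiency_index(pmax(centers[g, ], 0)),
               numeric(1))
  relabel <- order(ti, decreasing = TRUE)
  new_id <- match(seq_len(k), relabel)
  structure(list(assignment = new_id[cl],
                 centers = centers[relabel, , drop = FALSE],
                 center_sd = t(vapply(relabel, function(g) {
                   sub <- waveforms[cl == g, , drop = FALSE]
                   apply(sub, 2, sd)
                 }, numeric(ncol(waveforms)))),
                 wcv = wcv, k = k, transiency = ti[relabel]),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d clusters over %d ROIs; TI %s>\n", x$k,
              length(x$assignment),
              paste(sprintf("%.2f", x$transiency), collapse = " ")))
  invisible(x)
}

#' Choose the cluster count from a within-cluster variance curve
#'
#' Elbow rule: the k whose point on the (k, log variance) curve lies
#' furthest from the chord connecting the curve's endpoints, with both axes
#' normalized to \[0, 1\]. The log scale is used because within-cluster
#' variance typically falls over orders of magnitude before flattening at
#' the noise floor, and the knee is the point where that flattening starts.
#' A flat curve returns 1.
#'
#' @param variance_curve within-cluster variance for k = 1..length(curve);
#'   must be non-increasing.
#' @export
elbow_cluster_count <- function(variance_curve) {
  v <- as.numeric(variance_curve)
  if (any(diff(v) > 1e-8 * max(abs(v), 1))) {
    stop("variance curve must be non-increasing in k", call. = FALSE)
  }
  n <- length(v)
  if (n < 3 || v[1] - v[n] <= 0 || v[1] <= 0) return(1L)
  lv <- log(pmax(v, v[1] * 1e-9))
  k <- seq_len(n)
  x <- (k - 1) / (n - 1)
  y <- (lv - lv[n]) / (lv[1] - lv[n])
  dist_chord <- abs(x + y - 1) / sqrt(2)
  which.max(dist_chord)
}

#' Reconstruct a spatial RF map by filtered back-projection
#'
#' Treats the per-orientation bar-response profiles as projections of the
#' spatial RF: each profile is ramp-filtered (Ram-Lak, via FFT) and smeared
#' back across the map perpendicular to its bar orientation; the sum over
#' orientations approximates the RF. Five orientations undersample the
#' angular spectrum, so faint streak artifacts are expected and quantified
#' in the tests.
#'
#' @param responses matrix (orientations x positions) of per-bar response
#'   amplitudes.
#' @param orientations bar orientations in degrees (default 5 x 36 deg).
#' @param positions bar offsets along each orientation's normal axis (um).
#' @param grid_n output grid size (pixels per side).
#' @return an `rf_map`: `map` (grid_n x grid_n), `x`, `y` (um axes).
#' @export
reconstruct_rf_map <- function(responses,
                               orientations = seq(0, 144, by = 36),
                               positions = (seq_len(ncol(responses)) -
                                            (ncol(responses) + 1) / 2) * 10,
                               grid_n = 64) {
  responses <- as.matrix(responses)
  if (nrow(responses) != length(orientations)) {
    stop("missing projections: need one row per orientation", call. = FALSE)
  }
  if (any(!is.finite(responses))) {
    bad <- which(!is.finite(responses), arr.ind = TRUE)
    stop(sprintf("missing projections at orientation row(s) %s",
                 paste(unique(bad[, 1]), collapse = ", ")), call. = FALSE)
  }
  n_pos <- ncol(responses)
  ds <- diff(positions[1:2])
  # Ram-Lak filter in frequency domain, zero-padded to 2x
  n_pad <- 2^ceiling(log2(2 * n_pos))
  freqs <- c(seq(0, n_pad / 2), seq(-n_pad / 2 + 1, -1)) / n_pad
  ramp <- abs(freqs)
  span <- range(positions)
  ax <- seq(span[1], span[2], length.out = grid_n)
  map <- matrix(0, grid_n, grid_n)
  xy <- expand.grid(x = ax, y = ax)
  for (i in seq_along(orientations)) {
    # pad with a crossfade from the last sample back to the first so the
    # circular FFT sees a continuous signal (a uniform projection then
    # filters to exactly zero instead of leaving wrap-around edge artifacts)
    pr <- responses[i, ]
    pad <- seq(pr[n_pos], pr[1], length.out = n_pad - n_pos + 2)
    p <- c(pr, pad[-c(1, length(pad))])
    filt <- Re(fft(fft(p) * ramp, inverse = TRUE)) / n_pad
    filt <- filt[seq_len(n_pos)]
    phi <- orientations[i] * pi / 180  # normal axis of the bar
    s <- xy$x * cos(phi) + xy$y * sin(phi)
    map <- map + matrix(approx(positions, filt, s, rule = 2)$y, grid_n, grid_n)
  }
  map <- map * pi / (2 * length(orientations)) * ds
  structure(list(map = map, x = ax, y = ax), class = "rf_map")
}

#' Fit a two-dimensional Gaussian to an RF map
#'
#' Least-squares fit of an axis-aligned 2-D Gaussian plus offset; the FWHM
#' along the axis of motion (x) is \eqn{2\sqrt{2\ln 2}\,\sigma_x}.
#'
#' @param map an `rf_map` from [reconstruct_rf_map()], or a plain matrix
#'   (then `x`/`y` default to pixel indices).
#' @return list with `sigma_x`, `sigma_y`, `fwhm` (um), `center` (x, y),
#'   `fit` (the nls object).
#' @export
fit_gaussian_rf <- function(map) {
  if (inherits(map, "rf_map")) {
    z <- map$map; xs <- map$x; ys <- map$y
  } else {
    z <- as.matrix(map); xs <- seq_len(nrow(z)); ys <- seq_len(ncol(z))
  }
  df <- expand.grid(x = xs, y = ys)
  df$z <- as.vector(z)
  pk <- which.max(df$z)
  start <- list(A = max(df$z) - min(df$z), x0 = df$x[pk], y0 = df$y[pk],
                sx = diff(range(xs)) / 6, sy = diff(range(ys)) / 6,
                C = min(df$z))
  fit <- try(minpack.lm::nlsLM(
    z ~ A * exp(-(x - x0)^2 / (2 * sx^2) - (y - y0)^2 / (2 * sy^2)) + C,
    data = df, start = start,
    lower = c(0, min(xs), min(ys), 1e-3, 1e-3, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("2-D Gaussian fit did not converge: ", attr(fit, "condition")$message,
         call. = FALSE)
  }
  cf <- coef(fit)
  list(sigma_x = abs(unname(cf["sx"])), sigma_y = abs(unname(cf["sy"])),
       fwhm = fwhm_from_sigma(abs(unname(cf["sx"]))),
       center = c(unname(cf["x0"]), unname(cf["y0"])), fit = fit)
}
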