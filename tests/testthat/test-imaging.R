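make_two_source_movie <- function(noise_sd = 0.02, seed = 11) {
  stim <- make_bar_stimulus(0.5)
  tr <- vapply(test_on7$rf[c(2, 6)], function(p) {
    w <- apply_sensor_filter(simulate_bc_response(p, stim))$rf_filtered
    w / max(w)
  }, numeric(length(seq(0, stim$duration, 1))))
  tr <- tr[seq(1, nrow(tr), by = 20), ]          # ~50 Hz sampling
  layout <- data.frame(x = c(20, 60), y = c(20, 35), radius = 4)
  list(movie = gen_movie(layout, tr, nx = 64, ny = 40, noise_sd = noise_sd,
                         seed = seed),
       layout = layout, traces = tr)
}

test_that("active-pixel selection follows the dF/F threshold", {
  zeros <- list(frames = array(0, c(8, 8, 10)), pixel_size = 1.28, frame_rate = 50)
  expect_warning(m0 <- select_active_pixels(zeros), "threshold")
  expect_false(any(m0))

  src <- make_two_source_movie()
  mask <- select_active_pixels(src$movie, 0.2)
  truth <- src$movie$truth > 0
  # precision: selected pixels are overwhelmingly true source pixels
  expect_gt(sum(mask & truth) / sum(mask), 0.95)
  expect_gt(sum(mask & truth) / sum(truth), 0.95)
  # threshold 0 keeps every finite pixel
  expect_true(all(select_active_pixels(src$movie, -Inf)))
})

test_that("ROI segmentation separates sources with distinct kinetics", {
  src <- make_two_source_movie()
  mask <- select_active_pixels(src$movie, 0.2)
  rois <- segment_rois(src$movie, mask, max_extent = 10)
  expect_gte(length(rois), 2)
  # each ROI is pure wrt ground truth and within the extent limit
  for (r in rois) {
    tru <- src$movie$truth[r$pixels]
    expect_gt(max(table(tru)) / length(tru), 0.95)
    if (nrow(r$pixels) > 1) {
      expect_lte(max(dist(r$pixels * src$movie$pixel_size)), 10)
    }
  }
  # a uniform single source yields ROIs carrying the same waveform
  one <- gen_movie(data.frame(x = 30, y = 25, radius = 6),
                   matrix(src$traces[, 1]), nx = 48, ny = 40,
                   noise_sd = 0.01, seed = 3)
  m1 <- select_active_pixels(one, 0.2)
  r1 <- segment_rois(one, m1, max_extent = 10)
  for (r in r1) expect_gt(cor(r$trace, src$traces[, 1]), 0.99)
})

test_that("high-variability pixel groups are dropped by the CV filter", {
  withr::with_seed(8, {
    n_t <- 80
    frames <- array(rnorm(10 * 10 * n_t, 0, 0.02), c(10, 10, n_t))
    sig <- c(numeric(20), seq(0, 1, length.out = 20), seq(1, 0, length.out = 40))
    # coherent source with uniform gain
    for (i in 2:4) for (j in 2:4) frames[i, j, ] <- sig + rnorm(n_t, 0, 0.02)
    # erratic group: same shape, wildly different gains -> pixel CV > 1
    # (all gains large enough to pass the dF/F selection threshold)
    gains <- c(0.5, 0.5, 0.5, 0.5, 8, 8, 0.5, 0.5, 0.5)
    g <- 1
    for (i in 7:9) for (j in 7:9) {
      frames[i, j, ] <- gains[g] * sig + rnorm(n_t, 0, 0.02); g <- g + 1
    }
    mov <- list(frames = frames, pixel_size = 1.28, frame_rate = 50)
    mask <- select_active_pixels(mov, 0.2)
    rois <- segment_rois(mov, mask, max_extent = 50, cv_max = 1)
    cents <- vapply(rois, function(r) r$centroid[1], numeric(1))
    expect_true(any(cents < 6 * 1.28))        # coherent source kept
    expect_false(any(cents > 6 * 1.28))       # erratic group removed
  })
})

test_that("trace preprocessing smooths, rebases and normalizes to unit peak", {
  # slow Gaussian bump (seconds-wide at 50 Hz): fully inside the passband
  tt <- seq(0, 8, by = 0.02)
  clean <- exp(-(tt - 4)^2 / (2 * 0.8^2))
  out <- preprocess_trace(clean + 0.3)          # constant offset
  expect_equal(max(out), 1)
  expect_gt(cor(out, clean), 0.999)
  # white noise: high-frequency power drops
  withr::with_seed(4, {
    wn <- rnorm(512)
    f <- preprocess_trace(wn + 2)
    spec_hi <- function(y) {
      s <- Mod(fft(y - mean(y)))^2
      sum(s[150:256]) / sum(s[2:256])
    }
    expect_lt(spec_hi(f), spec_hi(wn) / 2)
  })
  expect_error(preprocess_trace(rep(-1, 50)), "peak")
  expect_error(preprocess_trace(c(1, NA, 3)), "finite")
})

test_that("functional clustering is deterministic and sorted by transiency", {
  ds <- gen_roi_dataset(test_on7, n_rois = 60, velocities = 0.5,
                        noise_sd = 0.05, seed = 4)
  m <- roi_aligned_matrix(ds, 0.5)
  cs1 <- cluster_rois(m, k = 7)
  cs2 <- cluster_rois(m, k = 7)
  expect_identical(cs1$assignment, cs2$assignment)
  expect_true(all(diff(cs1$transiency) <= 1e-9))
  expect_true(all(cs1$assignment %in% 1:7))
  expect_true(all(diff(cs1$wcv) <= 1e-8 * max(cs1$wcv)))
  expect_error(cluster_rois(m[1:5, ], k = 10), "fewer ROIs")
})

test_that("elbow rule finds constructed knees and rejects bad curves", {
  knee <- c(100, 80, 60, 40, 20, 10, 5, 4.8, 4.6, 4.4, 4.2, 4)
  expect_equal(elbow_cluster_count(knee), 7L)
  expect_equal(elbow_cluster_count(rep(3, 8)), 1L)
  expect_error(elbow_cluster_count(c(5, 7, 3)), "non-increasing")
})

test_that("back-projection reconstructs Gaussian receptive fields", {
  p <- rf_params(center_width = 100, center_rise = 20, center_decay = 400)
  resp <- gen_oriented_bar_responses(p, center = c(20, -10), noise_sd = 0.02,
                                     seed = 3)
  map <- reconstruct_rf_map(resp$responses, resp$orientations, resp$positions)
  fit <- fit_gaussian_rf(map)
  expect_lt(sqrt(sum((fit$center - c(20, -10))^2)), 10)
  expect_equal(fit$fwhm, 100, tolerance = 0.1)
  expect_equal(fit$fwhm, fwhm_from_sigma(fit$sigma_x))

  # uniform responses produce a flat map: artifacts < 5% of a real peak
  flat <- reconstruct_rf_map(matrix(max(resp$responses), 5, 32))
  expect_lt(max(abs(flat$map - mean(flat$map))), 0.05 * max(map$map))

  # a two-source phantom at 100 um separation is resolved along x
  ph <- matrix(0, 5, 32)
  pos <- (1:32 - 16.5) * 10
  for (i in 1:5) {
    phi <- (i - 1) * 36 * pi / 180
    ph[i, ] <- exp(-(pos + 50 * cos(phi))^2 / 450) +
               exp(-(pos - 50 * cos(phi))^2 / 450)
  }
  mp <- reconstruct_rf_map(ph)
  mid <- which.min(abs(mp$y))
  prof <- mp$map[, mid]
  pk_l <- max(prof[mp$x < -20]); pk_r <- max(prof[mp$x > 20])
  trough <- min(prof[abs(mp$x) < 20])
  expect_lt(trough, 0.8 * min(pk_l, pk_r))

  expect_error(reconstruct_rf_map(matrix(1, 4, 32)), "one row per orientation")
  bad <- matrix(1, 5, 32); bad[2, 5] <- NA
  expect_error(reconstruct_rf_map(bad), "orientation row")
})

test_that("2-D Gaussian fits recover exact inputs to 1%", {
  xs <- seq(-150, 150, length.out = 40)
  z <- outer(xs, xs, function(x, y)
    2 * exp(-(x - 12)^2 / (2 * 30^2) - (y + 25)^2 / (2 * 45^2)) + 0.1)
  fit <- fit_gaussian_rf(structure(list(map = z, x = xs, y = xs),
                                   class = "rf_map"))
  expect_equal(fit$sigma_x, 30, tolerance = 0.01)
  expect_equal(fit$sigma_y, 45, tolerance = 0.01)
  expect_equal(fit$center, c(12, -25), tolerance = 0.01)
})
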