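test_that("bar stimulus geometry follows speed, dwell time and direction", {
  st <- make_bar_stimulus(speed = 0.5)
  expect_equal(st$bar_width, 1000)           # 0.5 um/ms x 2000 ms dwell
  # leading edge crosses the arena in arena/speed ms
  expect_equal(stwiring:::stim_intervals(st, 2000)[1, 2], 1000)

  st25 <- make_bar_stimulus(speed = 0.25)
  expect_equal(1000 / st25$speed, 4000)      # 4 s sweep of the leading edge

  # every point stimulated for exactly dwell_time
  x0 <- 300
  covered <- vapply(seq(0, st$duration, by = 1), function(t) {
    iv <- stwiring:::stim_intervals(st, t)
    nrow(iv) > 0 && x0 >= iv[1, 1] && x0 <= iv[1, 2]
  }, logical(1))
  expect_equal(sum(covered), 2001, tolerance = 2e-3)

  # direction -1 mirrors direction +1 about the arena midline
  stl <- make_bar_stimulus(0.5, direction = -1)
  x <- seq(0, 1000, by = 10)
  for (t in c(300, 1200, 2600)) {
    expect_equal(stwiring:::stim_indicator(stl, x, t),
                 rev(stwiring:::stim_indicator(st, x, t)))
  }
  expect_error(make_bar_stimulus(0), "positive")
  expect_error(make_bar_stimulus(1, direction = 2), "direction")
})

test_that("flash stimulus engages every RF fully and immediately", {
  fl <- make_flash_stimulus(duration = 4)
  expect_equal(fl$duration, 4000)
  # area fraction is 1 at onset for every width
  for (w in c(20, 100, 380)) {
    expect_equal(rf_area_fraction(w, 500, fl, 0), 1)
    expect_equal(rf_area_fraction(w, 500, fl, 3999), 1)
  }
  expect_equal(rf_area_fraction(50, 500, fl, 4500), 0)
  expect_error(make_flash_stimulus(0), "positive")
})

test_that("erf-based area fraction matches dense Riemann integration", {
  st <- make_bar_stimulus(0.5)
  withr::with_seed(42, {
    for (i in 1:25) {
      w <- runif(1, 20, 300)
      x0 <- runif(1, 100, 900)
      tt <- runif(1, 0, 3500)
      expect_lt(abs(rf_area_fraction(w, x0, st, tt) -
                    riemann_area_fraction(w, x0, st, tt)), 1e-6)
    }
  })
  # half coverage by symmetry: leading edge exactly at rf_x
  st1 <- make_bar_stimulus(1, arena_width = 4000, dwell_time = 2)
  expect_equal(rf_area_fraction(60, 2000, st1, 2000), 0.5, tolerance = 1e-9)
  expect_error(rf_area_fraction(-5, 500, st, 10), "positive")
})

test_that("area fraction is monotone while a bar covers the RF", {
  st <- make_bar_stimulus(0.5)
  a <- rf_area_fraction(80, 500, st, seq(0, 2000, by = 10))
  expect_true(all(diff(a) >= -1e-12))
})

test_that("masked stimuli hold masked regions at background", {
  st <- make_bar_stimulus(0.5, mask_intervals = list(c(400, 600)))
  x <- seq(0, 1000, by = 5)
  s <- stwiring:::stim_indicator(st, x, 1500)
  expect_true(all(s[x > 400 & x < 600] == 0))
  a_masked <- rf_area_fraction(50, 500, st, 3000)
  a_open <- rf_area_fraction(50, 500, make_bar_stimulus(0.5), 3000)
  expect_lt(a_masked, a_open)
})

test_that("bipolar recursion respects bounds and the flash fixed point", {
  p <- rf_params(center_width = 60, center_rise = 15, center_decay = 300,
                 surround_strength = 0.4, surround_reversal = 0.3)
  tr <- simulate_bc_response(p, make_bar_stimulus(0.5))
  expect_true(all(tr$rf_full >= 0 & tr$rf_full <= 1))
  expect_true(all(diff(tr$adaptation) <= 1e-12))
  expect_true(all(tr$adaptation >= 0 & tr$adaptation <= 1))

  # zero-contrast stimulus -> identically zero
  st0 <- make_bar_stimulus(0.5, intensity = 0)
  expect_true(all(simulate_bc_response(p, st0)$rf_full == 0))

  # closed-form fixed point: no surround, no adaptation =>
  # steady flash response = A * area_inf / (area_inf + R_in), area_inf = 1
  p2 <- rf_params(amplitude = 0.8, center_width = 60, center_rise = 10,
                  center_decay = 1e9, surround_strength = 0)
  fl <- simulate_bc_response(p2, make_flash_stimulus(4))
  expect_equal(tail(fl$rf_full[fl$t < 4000], 1), 0.8 * 1 / 1.1,
               tolerance = 1e-5)
})

test_that("motion responses mirror in time when direction is reversed", {
  p <- rf_params(center_width = 80, center_rise = 20, center_decay = 400,
                 surround_strength = 0.3)
  trl <- simulate_bc_response(p, make_bar_stimulus(0.5, direction = 1), rf_x = 500)
  trr <- simulate_bc_response(p, make_bar_stimulus(0.5, direction = -1), rf_x = 500)
  expect_equal(trl$rf_full, trr$rf_full, tolerance = 1e-10)
})

test_that("wider centers respond to motion earlier at fixed velocity", {
  st <- make_bar_stimulus(0.5)
  onset <- function(w) {
    p <- rf_params(center_width = w, center_rise = 15, center_decay = 400)
    y <- simulate_bc_response(p, st, rf_x = 500)$rf_full
    stwiring:::threshold_crossing(y, tr_t <- seq_along(y) - 1, 0.05)
  }
  onsets <- vapply(c(22, 60, 97, 200), onset, numeric(1))
  expect_true(all(diff(onsets) < 0))
  # the 97 vs 22 um pair shows a lag on the order of 100 ms at 0.5 mm/s
  expect_gt(onsets[1] - onsets[3], 50)
})

test_that("sensor filter matches its analytic kernel and a direct convolution", {
  # impulse -> the kernel itself, peak 1 at the analytic maximum
  imp <- c(1, numeric(799))
  k <- apply_sensor_filter(imp)
  expect_equal(max(k), 1, tolerance = 1e-9)
  tau_star <- log(50 / 10) * 10 * 50 / (50 - 10)
  expect_equal(which.max(k) - 1, round(tau_star))

  # step input: monotone rise, identical to direct discrete convolution
  stp <- c(numeric(50), rep(1, 450))
  got <- apply_sensor_filter(stp)
  expect_equal(got, direct_sensor_filter(stp, 10, 50), tolerance = 1e-9)
  expect_true(all(diff(got[51:500]) >= -1e-12))

  # constant input -> constant output (DC gain = kernel sum / peak);
  # settled after many filter decay constants
  cst <- rep(0.5, 2500)
  out <- apply_sensor_filter(cst)
  expect_lt(diff(range(out[2000:2500])) / mean(out[2000:2500]), 1e-6)

  expect_error(apply_sensor_filter(imp, f_rise = 50, f_decay = 10), "smaller")
})

test_that("invalid RF parameters are rejected", {
  expect_error(rf_params(amplitude = 1.2), "\\[0, 1\\]")
  expect_error(rf_params(center_width = -1), "positive")
  expect_error(rf_params(delay = -3), ">= 0")
})
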