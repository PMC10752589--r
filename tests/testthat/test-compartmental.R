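test_that("DC attenuation on a cylinder matches the finite-cable closed form", {
  cyl <- cylinder_morphology(length_um = 500, n = 501, diam = 1)
  mod <- build_sac_model(cyl, d_lambda = 0.01)
  lambda <- sqrt(1e-4 / (4 * 4e-4 * 150)) * 1e4   # um
  X <- mod$comp$path_dist / lambda
  L <- 500 / lambda
  src <- 2L; dst <- mod$n_seg
  got <- dc_transfer_ratio(mod, src, dst)
  want <- cosh(L - X[dst]) / cosh(L - X[src])
  expect_equal(got, want, tolerance = 1e-4)
  expect_equal(dc_transfer_ratio(mod, src, src), 1)
})

test_that("transfer impedance is reciprocal on a random passive tree", {
  tree <- random_tree_morphology(n_sections = 50, seed = 3)
  mod <- build_sac_model(tree)
  withr::with_seed(4, {
    for (i in 1:10) {
      ab <- sample(mod$n_seg, 2)
      z1 <- transfer_impedance(mod, ab[1], ab[2])
      z2 <- transfer_impedance(mod, ab[2], ab[1])
      expect_equal(z1, z2, tolerance = 1e-6)
    }
  })
})

test_that("current steps reproduce the single-compartment RC closed form", {
  soma <- stwiring:::as_sac_morphology(data.frame(
    id = 1L, type = 1L, x = 0, y = 0, z = 0, radius = 5, parent = -1L))
  mod <- build_sac_model(soma)
  res <- inject_current_step(mod, 1, amplitude = 10, duration = 300, t_stop = 400)
  dv <- max(res$v[, 1]) - (-60)
  want <- (10e-12) / (4e-4 * mod$area_cm2[1]) * 1e3   # I / (g A), in mV
  expect_equal(dv, want, tolerance = 1e-6)
  # zero amplitude -> flat at rest
  r0 <- inject_current_step(mod, 1, amplitude = 0)
  expect_true(all(abs(r0$v + 60) < 1e-12))
})

test_that("constant synaptic drive reaches the conductance-divider voltage", {
  soma <- stwiring:::as_sac_morphology(data.frame(
    id = 1L, type = 1L, x = 0, y = 0, z = 0, radius = 5, parent = -1L))
  mod <- build_sac_model(soma)
  syn <- data.frame(comp = 1L, x = 0, y = 0, path_dist = 0)
  r <- run_visual_trial(mod, syn, matrix(1, 500, 1), g_max = 0.5, record = 1L)
  g_pas <- 4e-4 * mod$area_cm2[1] * 1e6
  want <- (0.5e-3 * 0 + g_pas * (-60)) / (0.5e-3 + g_pas)
  expect_equal(r$v[nrow(r$v), 1], want, tolerance = 1e-6)
})

test_that("the quiescent circuit stays at rest", {
  mod <- build_sac_model(test_sac, membrane_spec(g_can = 0.003))
  syn <- place_bipolar_synapses(mod, n = 30, seed = 2)
  r <- run_visual_trial(mod, syn, matrix(0, 100, 30))
  expect_true(all(abs(r$v + 60) < 0.5))   # rest, allowing tiny channel leak
  expect_true(all(abs(r$ca - 100) < 1))
  expect_true(all(is.finite(r$v)) && all(r$ca >= 0))
})

test_that("calcium pool matches its closed-form steady state", {
  ca <- ca_pool_trace(rep(0.02, 20000), dt = 0.1, ca_tau = 50,
                      ca_rest = 100, ca_influx_scale = 500)
  expect_equal(tail(ca, 1), 100 + 500 * 0.02 * 50, tolerance = 1e-6)
  # no influx -> stays at rest
  expect_true(all(ca_pool_trace(numeric(100)) == 100))
})

test_that("synapse placement respects distance limits and samples by length", {
  mod <- build_sac_model(test_sac)
  syn <- place_bipolar_synapses(mod, n = 200, max_dist = 110, seed = 5)
  expect_true(all(syn$path_dist <= 110))
  expect_identical(syn, place_bipolar_synapses(mod, n = 200, max_dist = 110, seed = 5))

  # empirical density proportional to local dendritic length (chi-squared)
  big <- place_bipolar_synapses(mod, n = 1e4, max_dist = 110, seed = 6)
  elig <- which(mod$comp$path_dist > 0 & mod$comp$path_dist <= 110)
  sec <- mod$comp$section[elig]
  exp_w <- tapply(mod$comp$L[elig], sec, sum)
  obs <- table(factor(mod$comp$section[big$comp], levels = names(exp_w)))
  pval <- suppressWarnings(chisq.test(obs, p = exp_w / sum(exp_w))$p.value)
  expect_gt(pval, 0.001)
})

test_that("solution is stable under mesh and time-step refinement", {
  st <- make_bar_stimulus(1)
  peaks <- c()
  for (dl in c(0.1, 0.05)) {
    mod <- build_sac_model(test_sac, membrane_spec(g_can = 0.003), d_lambda = dl)
    syn <- place_bipolar_synapses(mod, n = 100, seed = 3)
    drv <- vapply(500 + syn$x,
                  function(x) stwiring:::bc_response_matrix(test_on7$rf[[2]], st, x)$rf_full[, 1],
                  numeric(length(seq(0, st$duration, st$dt))))
    for (dt in c(0.1, 0.05)) {
      r <- run_visual_trial(mod, syn, drv, g_max = 0.05, record = 1L, dt = dt)
      peaks <- c(peaks, max(r$v))
    }
  }
  expect_lt(diff(range(peaks)) / abs(mean(peaks) + 60), 0.01)
})

test_that("perisomatic modification only reduces cross-soma coupling", {
  mod <- build_sac_model(test_sac)
  sites <- recording_sites(mod)
  a <- sites$comp[sites$outward_sign < 0][1]
  b <- sites$comp[sites$outward_sign > 0][1]
  # identity factors leave the model bit-identical
  same <- perisomatic_modification(mod, 1, 1)
  expect_equal(dc_transfer_ratio(same, a, b), dc_transfer_ratio(mod, a, b))
  # monotone decrease with increasing axial factor
  tr <- vapply(c(1, 3, 10, 30), function(f)
    dc_transfer_ratio(perisomatic_modification(mod, f), a, b), numeric(1))
  expect_true(all(diff(tr) < 0))
})

test_that("recording sites sit on terminal dendrites near the horizontal axis", {
  mod <- build_sac_model(test_sac)
  sites <- recording_sites(mod, y_max = 30)
  expect_true(all(abs(sites$y) < 30))
  expect_true(all(mod$comp$terminal[sites$comp]))
  expect_true(any(sites$outward_sign > 0) && any(sites$outward_sign < 0))
})
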