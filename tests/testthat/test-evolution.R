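test_that("population initialization is bounded and deterministic", {
  b <- param_bounds("both")
  p1 <- init_population(b, n = 16, seed = 9)
  p2 <- init_population(b, n = 16, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(t(p1) >= b$lo & t(p1) <= b$hi))
  expect_equal(dim(p1), c(16L, nrow(b)))
  # the full scenario genome carries 23 free parameters
  expect_equal(nrow(stwiring:::scenario_bounds(scenario_spec("full"))), 23L)
})

test_that("mutation follows the scaled Gaussian-plus-uniform rule", {
  b <- data.frame(name = "p", lo = -1e6, hi = 1e6)
  # degenerate settings give the identity
  expect_equal(mutate_genome(5, b, sd = 0, u_range = 0), 5)
  # genomes always stay within bounds
  bt <- param_bounds("presynaptic")
  withr::with_seed(3, {
    g <- init_population(bt, 1, seed = 1)[1, ]
    for (i in 1:200) {
      g <- mutate_genome(g, bt)
      expect_true(all(g >= bt$lo & g <= bt$hi))
    }
  })
})

test_that("selection step keeps elites verbatim and repopulates from them", {
  b <- data.frame(name = c("a", "b"), lo = c(0, 0), hi = c(1, 1))
  pop <- list(params = matrix(runif(20), 10, 2,
                              dimnames = list(NULL, b$name)),
              annuli = NULL, fitness = seq(0.1, 1, length.out = 10))
  nxt <- step_generation(pop, b, seed = 4)
  ord <- order(pop$fitness, decreasing = TRUE)
  expect_equal(nxt$params[1:2, ], pop$params[ord[1:2], ])
  expect_equal(nxt$fitness[1:2], pop$fitness[ord[1:2]])
  expect_true(all(is.na(nxt$fitness[3:10])))
  # with mutation disabled, offspring are exact copies of the two elites
  frozen <- step_generation(pop, b, sd = 0, u_range = 0, seed = 5)
  for (i in 3:10) {
    expect_true(any(apply(pop$params[ord[1:2], ], 1,
                          function(e) all(e == frozen$params[i, ]))))
  }
})

test_that("elitist best fitness is monotone on a toy objective", {
  b <- data.frame(name = "x", lo = -10, hi = 10)
  obj <- function(v) -(v[["x"]] - 3)^2
  hist <- stwiring:::ea_optimize(obj, b, n_pop = 10, generations = 30, seed = 2)
  expect_true(all(diff(hist$history) >= 0))
  expect_equal(unname(hist$best[["x"]]), 3, tolerance = 0.05)
})

test_that("directional fitness matches an independent recomputation", {
  sc <- scenario_spec("full", velocities = 1)
  ctx <- make_eval_context(test_sac, sc, n_synapses = 60, seed = 1)
  b <- stwiring:::scenario_bounds(sc)
  g <- init_population(b, 1, seed = 11)[1, ]
  got <- evaluate_ds_fitness(g, ctx)

  # recompute from scratch with package primitives
  post <- stwiring:::genome_postsyn(g)
  model <- stwiring:::apply_postsyn(ctx$model, post, sc)
  rfs <- stwiring:::genome_rfs(g, sc)
  idx <- ifelse(ctx$groups == "prox", 1L, 2L)
  drv <- stwiring:::bc_drive(ctx, list(rfs$prox, rfs$dist), idx, 1)
  rp <- run_visual_trial(model, ctx$synapses, drv$outward_plus,
                         g_max = post$g_syn, record = ctx$sites$comp)
  rm_ <- run_visual_trial(model, ctx$synapses, drv$minus,
                          g_max = post$g_syn, record = ctx$sites$comp)
  pk_p <- apply(rp$ca, 2, max); pk_m <- apply(rm_$ca, 2, max)
  r_out <- ifelse(ctx$sites$outward_sign >= 0, pk_p, pk_m)
  r_in <- ifelse(ctx$sites$outward_sign >= 0, pk_m, pk_p)
  d <- (r_out - r_in) / (r_out + r_in)
  want <- mean(directional_metric(d, r_out))
  expect_equal(as.numeric(got), want, tolerance = 1e-10)
})

test_that("random initial circuits show weak direction selectivity", {
  sc <- scenario_spec("full", velocities = 1)
  ctx <- make_eval_context(test_sac, sc, n_synapses = 60, seed = 1)
  b <- stwiring:::scenario_bounds(sc)
  pop <- init_population(b, 4, seed = 21)
  dsis <- vapply(seq_len(nrow(pop)), function(i) {
    mean(attr(evaluate_ds_fitness(pop[i, ], ctx), "dsi"))
  }, numeric(1))
  expect_lt(mean(abs(dsis)), 0.2)
})

test_that("annuli genomes evolve per-bin cluster assignments", {
  sc <- scenario_spec("annuli", velocities = 1, library = test_on7$rf,
                      swap_prob = 0.5)
  ctx <- make_eval_context(test_sac, sc, n_synapses = 40, seed = 1)
  withr::with_seed(6, {
    pop <- list(params = init_population(stwiring:::scenario_bounds(sc), 6, seed = 2),
                annuli = matrix(1L, 6, ctx$n_bins),
                fitness = c(1, 2, 3, 4, 5, 6))
    nxt <- step_generation(pop, stwiring:::scenario_bounds(sc),
                           swap_prob = 0.5, n_clusters = 7)
    expect_equal(nxt$annuli[1:2, ], pop$annuli[c(6, 5), ])
    expect_gt(sum(nxt$annuli[3:6, ] != 1L), 0)   # swaps occurred
    expect_true(all(nxt$annuli %in% 1:7))
  })
})
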