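# Independent oracles and shared fixtures, built in code.

# Brute-force Riemann integration of the normalized Gaussian mass covered
# by the stimulus: arena gridded at `h` um, per-cell coverage fractions
# computed exactly from the stimulated intervals.
riemann_area_fraction <- function(width, rf_x, stim, t, h = 0.1) {
  edges <- seq(0, stim$arena_width, by = h)
  mid <- edges[-1] - h / 2
  sigma <- width / (2 * sqrt(2 * log(2)))
  m <- dnorm(mid, rf_x, sigma) * h
  iv <- stwiring:::stim_intervals(stim, t)
  cov <- numeric(length(mid))
  for (i in seq_len(nrow(iv))) {
    lo <- pmax(edges[-length(edges)], iv[i, 1])
    hi <- pmin(edges[-1], iv[i, 2])
    cov <- cov + pmax(hi - lo, 0) / h
  }
  sum(m * pmin(cov, 1)) / sum(m)
}

# Direct (untruncated) discrete convolution with the peak-normalized
# difference-of-exponentials kernel.
direct_sensor_filter <- function(y, f_rise, f_decay, dt = 1) {
  tau <- (seq_along(y) - 1) * dt
  k <- exp(-tau / f_decay) - exp(-tau / f_rise)
  tau_pk <- log(f_decay / f_rise) * f_rise * f_decay / (f_decay - f_rise)
  tg <- dt * (floor(tau_pk / dt) + c(0, 1))
  k <- k / max(exp(-tg / f_decay) - exp(-tg / f_rise))
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    j <- seq_len(i)
    out[i] <- sum(y[i - j + 1] * k[j])
  }
  out
}

# Unbranched cylinder morphology: `n` nodes over `length_um`, diameter 1 um.
cylinder_morphology <- function(length_um = 500, n = 501, diam = 1) {
  nodes <- data.frame(id = seq_len(n), type = c(1L, rep(3L, n - 1L)),
                      x = seq(0, length_um, length.out = n), y = 0, z = 0,
                      radius = diam / 2, parent = c(-1L, seq_len(n - 1L)))
  stwiring:::as_sac_morphology(nodes)
}

# Random binary-tree morphology with `n_sections` straight sections.
random_tree_morphology <- function(n_sections = 50, seed = 1) {
  withr::with_seed(seed, {
    nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = 3, parent = -1L)
    tips <- 1L
    next_id <- 2L
    for (s in seq_len(n_sections)) {
      par <- sample(tips, 1)
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 20, 60)
      n_pts <- 4L
      x0 <- nodes$x[par]; y0 <- nodes$y[par]
      for (i in seq_len(n_pts)) {
        nodes <- rbind(nodes, data.frame(
          id = next_id, type = 3L,
          x = x0 + len * i / n_pts * cos(ang),
          y = y0 + len * i / n_pts * sin(ang), z = 0,
          radius = runif(1, 0.1, 0.6),
          parent = if (i == 1) nodes$id[par] else next_id - 1L))
        next_id <- next_id + 1L
      }
      tips <- c(tips, nrow(nodes))
    }
    stwiring:::as_sac_morphology(nodes)
  })
}

# small shared fixtures (built once per test file load)
test_sac <- generate_synthetic_sac(seed = 1)
test_on7 <- gen_cluster_library("ON7")
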