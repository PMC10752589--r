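#' Parameter bounds for the evolutionary search
#'
#' Presynaptic RF parameters: amplitude, surround strength and reversal in
#' \[0, 1\]; widths, rise/decay constants and delay positive with documented
#' upper bounds. Postsynaptic parameters: leak conductance 1e-5 to 1e-3
#' S/cm2, axial resistance 50-300 Ohm cm, calcium channel voltage offset
#' +/-30 mV, channel density up to 0.01 S/cm2, synaptic conductance
#' 0.01-1 nS.
#'
#' @param set `"presynaptic"`, `"postsynaptic"` or `"both"`.
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
param_bounds <- function(set = c("both", "presynaptic", "postsynaptic")) {
  set <- match.arg(set)
  pre <- data.frame(
    name = c("amplitude", "center_width", "surround_width", "center_rise",
             "center_decay", "surround_rise", "surround_strength",
             "surround_reversal", "delay"),
    lo = c(0, 5, 10, 1, 10, 1, 0, 0, 0),
    hi = c(1, 400, 600, 100, 2000, 400, 1, 1, 200))
  post <- data.frame(
    name = c("g_pas", "ra", "g_can", "can_voffset", "g_syn"),
    lo = c(1e-5, 50, 1e-4, -30, 0.01),
    hi = c(1e-3, 300, 1e-2, 30, 1))
  switch(set, presynaptic = pre, postsynaptic = post, both = rbind(pre, post))
}

#' Initialize a random population
#'
#' Each genome's parameters are drawn uniformly within bounds;
#' deterministic per seed.
#'
#' @param bounds a bounds data.frame (`name`, `lo`, `hi`).
#' @param n population size.
#' @param seed RNG seed.
#' @return matrix (n x n_params) with named columns.
#' @export
init_population <- function(bounds, n = 16, seed = 1) {
  with_seed(seed, {
    m <- vapply(seq_len(nrow(bounds)),
                function(j) runif(n, bounds$lo[j], bounds$hi[j]),
                numeric(n))
    m <- matrix(m, nrow = n)
    colnames(m) <- bounds$name
    m
  })
}

#' Mutate a genome
#'
#' Each parameter is multiplied by a Gaussian scaling factor (mean 1,
#' SD `sd`), shifted by a uniform draw scaled to the parameter's bound
#' range (`+/- u_range` of the range), and clipped into bounds.
#'
#' @param g numeric genome vector.
#' @param bounds bounds data.frame matching `g`.
#' @param sd SD of the multiplicative Gaussian factor (default 0.05).
#' @param u_range half-width of the additive uniform term in normalized
#'   parameter space (default 0.015).
#' @param seed optional RNG seed (otherwise the current stream is used).
#' @export
mutate_genome <- function(g, bounds, sd = 0.05, u_range = 0.015, seed = NULL) {
  run <- function() {
    scale <- rnorm(length(g), 1, sd)
    add <- runif(length(g), -u_range, u_range) * (bounds$hi - bounds$lo)
    pmin(pmax(g * scale + add, bounds$lo), bounds$hi)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' One selection/mutation generation step
#'
#' Elitist step: the `n_elite` best genomes are retained verbatim; every
#' other slot is seeded from one of the elites (fair coin among them) and
#' mutated. When the population carries annulus cluster assignments, each
#' bin additionally swaps its cluster id with probability `swap_prob`.
#'
#' @param pop a population list with `params` (matrix), `fitness` (vector)
#'   and optionally `annuli` (integer matrix of cluster ids per bin).
#' @param bounds bounds data.frame.
#' @param n_elite number of elites (default 2).
#' @param sd,u_range mutation parameters (see [mutate_genome()]).
#' @param swap_prob per-bin probability of re-drawing an annulus cluster id.
#' @param n_clusters number of cluster ids available for annulus swaps.
#' @param seed optional RNG seed.
#' @return the next-generation population (fitness cleared except elites).
#' @export
step_generation <- function(pop, bounds, n_elite = 2, sd = 0.05,
                            u_range = 0.015, swap_prob = 0.05,
                            n_clusters = NULL, seed = NULL) {
  run <- function() {
    ord <- order(pop$fitness, decreasing = TRUE)
    elite <- ord[seq_len(n_elite)]
    n <- nrow(pop$params)
    new_params <- pop$params
    new_ann <- pop$annuli
    new_fit <- rep(NA_real_, n)
    new_params[seq_len(n_elite), ] <- pop$params[elite, , drop = FALSE]
    if (!is.null(new_ann)) new_ann[seq_len(n_elite), ] <- pop$annuli[elite, , drop = FALSE]
    new_fit[seq_len(n_elite)] <- pop$fitness[elite]
    for (i in seq(n_elite + 1, n)) {
      src <- elite[sample.int(n_elite, 1)]
      new_params[i, ] <- mutate_genome(pop$params[src, ], bounds, sd, u_range)
      if (!is.null(new_ann)) {
        ann <- pop$annuli[src, ]
        swap <- runif(length(ann)) < swap_prob
        if (any(swap)) ann[swap] <- sample.int(n_clusters, sum(swap), replace = TRUE)
        new_ann[i, ] <- ann
      }
    }
    list(params = new_params, annuli = new_ann, fitness = new_fit)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Scenario specification for directional training
#'
#' @param mode one of `"full"` (independent proximal and distal RFs),
#'   `"identical"` (one shared RF), `"single_free"` (shared RF except one
#'   parameter free to differ distally), `"compartmentalization"` (full
#'   model with perisomatic resistance factors), `"cluster_pair"` (fixed
#'   proximal/distal RFs from a cluster library; only postsynaptic
#'   parameters evolve) or `"annuli"` (10-um annuli, each assigned a
#'   library cluster, assignments evolving with a swap probability).
#' @param free_param RF parameter name for `single_free`.
#' @param velocities stimulus speeds (mm/s).
#' @param objective `"standard"` (directional metric) or `"dsi_only"`.
#' @param ra_factor,rm_factor perisomatic factors for `compartmentalization`.
#' @param library list of [rf_params()] (cluster library) for
#'   `cluster_pair` / `annuli`.
#' @param proximal_id,distal_id library indices for `cluster_pair`.
#' @param bin_width annulus width (um).
#' @param swap_prob per-annulus swap probability per generation.
#' @param ca_opt optimal outward calcium (nM) for the directional metric.
#' @export
scenario_spec <- function(mode = c("full", "identical", "single_free",
                                   "compartmentalization", "cluster_pair",
                                   "annuli"),
                          free_param = NULL,
                          velocities = c(0.25, 0.5, 1, 2, 4),
                          objective = c("standard", "dsi_only"),
                          ra_factor = 1, rm_factor = 1, library = NULL,
                          proximal_id = NULL, distal_id = NULL,
                          bin_width = 10, swap_prob = 0.05, ca_opt = 500) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  if (mode == "single_free" &&
      !free_param %in% param_bounds("presynaptic")$name) {
    stop("`free_param` must name a presynaptic RF parameter", call. = FALSE)
  }
  if (mode %in% c("cluster_pair", "annuli") && is.null(library)) {
    stop("`library` required for cluster_pair / annuli scenarios", call. = FALSE)
  }
  structure(list(mode = mode, free_param = free_param, velocities = velocities,
                 objective = objective, ra_factor = ra_factor,
                 rm_factor = rm_factor, library = library,
                 proximal_id = proximal_id, distal_id = distal_id,
                 bin_width = bin_width, swap_prob = swap_prob, ca_opt = ca_opt),
            class = "scenario_spec")
}

scenario_bounds <- function(scenario) {
  pre <- param_bounds("presynaptic")
  post <- param_bounds("postsynaptic")
  switch(scenario$mode,
    full = ,
    compartmentalization = {
      b <- rbind(pre, pre, post)
      b$name <- c(paste0("prox_", pre$name), paste0("dist_", pre$name), post$name)
      b
    },
    identical = {
      b <- rbind(pre, post)
      b$name <- c(paste0("shared_", pre$name), post$name)
      b
    },
    single_free = {
      extra <- pre[pre$name == scenario$free_param, ]
      b <- rbind(pre, extra, post)
      b$name <- c(paste0("shared_", pre$name),
                  paste0("dist_", scenario$free_param), post$name)
      b
    },
    cluster_pair = ,
    annuli = post)
}

genome_rfs <- function(genome, scenario) {
  pre_names <- param_bounds("presynaptic")$name
  as_rf <- function(v) do.call(rf_params, as.list(setNames(v, pre_names)))
  switch(scenario$mode,
    full = ,
    compartmentalization = list(
      prox = as_rf(genome[paste0("prox_", pre_names)]),
      dist = as_rf(genome[paste0("dist_", pre_names)])),
    identical = {
      rf <- as_rf(genome[paste0("shared_", pre_names)])
      list(prox = rf, dist = rf)
    },
    single_free = {
      shared <- genome[paste0("shared_", pre_names)]
      dist <- shared
      dist[paste0("shared_", scenario$free_param)] <-
        genome[paste0("dist_", scenario$free_param)]
      list(prox = as_rf(shared), dist = as_rf(dist))
    },
    cluster_pair = list(prox = scenario$library[[scenario$proximal_id]],
                        dist = scenario$library[[scenario$distal_id]]))
}

genome_postsyn <- function(genome) {
  as.list(genome[param_bounds("postsynaptic")$name])
}

#' Evaluation context for directional training
#'
#' Builds the discretized compartmental model, places the bipolar synapses,
#' selects the recording sites and splits synapses into proximal/distal
#' halves (by median path distance) or annulus bins. Built once per
#' training run; genomes are evaluated against it.
#'
#' @param morph a `sac_morphology`.
#' @param scenario a [scenario_spec()].
#' @param n_synapses number of bipolar inputs.
#' @param seed seed for synapse placement.
#' @param dt cable solver step (ms).
#' @param position_grid spatial rounding (um) used to share bipolar traces
#'   between synapses at nearly identical x positions.
#' @export
make_eval_context <- function(morph, scenario, n_synapses = 200, seed = 1,
                              dt = 0.1, position_grid = 5) {
  model <- build_sac_model(morph)
  syn <- place_bipolar_synapses(model, n = n_synapses, seed = seed)
  sites <- recording_sites(model)
  split_dist <- median(syn$path_dist)
  groups <- ifelse(syn$path_dist <= split_dist, "prox", "dist")
  bins <- floor(syn$path_dist / scenario$bin_width) + 1L
  list(model = model, synapses = syn, sites = sites, groups = groups,
       bins = bins, n_bins = max(bins), scenario = scenario, dt = dt,
       position_grid = position_grid, arena = 1000)
}

apply_postsyn <- function(model, post, scenario) {
  m <- model$membrane
  m$g_pas <- post$g_pas
  m$g_can <- post$g_can
  m$can_voffset <- post$can_voffset
  m$can_vhalf <- -10 + post$can_voffset
  model$g_axial <- model$g_axial * (model$membrane$ra / post$ra)
  m$ra <- post$ra
  model$membrane <- m
  if (scenario$mode == "compartmentalization") {
    model <- perisomatic_modification(model, scenario$ra_factor, scenario$rm_factor)
  }
  model
}

# Bipolar drive matrices for one velocity and both directions.
# rf_by_syn: list mapping each synapse to an rf_params object (via group or
# annulus assignment). Traces for direction -1 at position x are the
# direction +1 traces at (arena - x): the bar geometry is mirror-symmetric.
bc_drive <- function(ctx, rf_list, syn_rf_idx, velocity) {
  stim <- make_bar_stimulus(velocity, direction = 1, arena_width = ctx$arena)
  # morphology coordinates are soma-centered; the cell sits mid-arena
  x <- ctx$arena / 2 + ctx$synapses$x
  x <- round(x / ctx$position_grid) * ctx$position_grid
  x <- pmin(pmax(x, 0), ctx$arena)
  xm <- ctx$arena - x
  n_t <- length(seq(0, stim$duration, by = stim$dt))
  out <- matrix(0, n_t, length(x)); inw <- matrix(0, n_t, length(x))
  for (k in seq_along(rf_list)) {
    sel <- which(syn_rf_idx == k)
    if (!length(sel)) next
    pos <- unique(c(x[sel], xm[sel]))
    tr <- bc_response_matrix(rf_list[[k]], stim, pos)$rf_full
    out[, sel] <- tr[, match(x[sel], pos)]
    inw[, sel] <- tr[, match(xm[sel], pos)]
  }
  list(outward_plus = out, minus = inw, n_t = n_t)
}

#' Directional fitness of a genome
#'
#' Simulates the bipolar-SAC circuit for each velocity and both directions,
#' measures peak dendritic calcium at the recording sites, and returns the
#' mean (over velocities, then sites) directional metric — or mean DSI for
#' the `dsi_only` objective. Per-site outward/inward assignment follows the
#' sign of the site's x position relative to the soma.
#'
#' @param genome named numeric genome vector (layout per the scenario's bounds).
#' @param ctx an evaluation context from [make_eval_context()].
#' @param annuli optional integer vector of per-bin cluster assignments
#'   (annuli scenarios).
#' @return scalar fitness; also carries per-velocity DSI as attribute
#'   `"dsi"` and mean outward calcium as `"r_out"`.
#' @export
evaluate_ds_fitness <- function(genome, ctx, annuli = NULL) {
  scenario <- ctx$scenario
  post <- genome_postsyn(genome)
  model <- apply_postsyn(ctx$model, post, scenario)
  if (scenario$mode == "annuli") {
    rf_list <- scenario$library
    syn_rf_idx <- annuli[ctx$bins]
  } else {
    rfs <- genome_rfs(genome, scenario)
    rf_list <- list(rfs$prox, rfs$dist)
    syn_rf_idx <- ifelse(ctx$groups == "prox", 1L, 2L)
  }
  site_sign <- ctx$sites$outward_sign
  rec <- ctx$sites$comp
  dsis <- numeric(length(scenario$velocities))
  mets <- numeric(length(scenario$velocities))
  r_outs <- numeric(length(scenario$velocities))
  for (vi in seq_along(scenario$velocities)) {
    drv <- bc_drive(ctx, rf_list, syn_rf_idx, scenario$velocities[vi])
    res_p <- run_visual_trial(model, ctx$synapses, drv$outward_plus,
                              g_max = post$g_syn, record = rec, dt = ctx$dt)
    res_m <- run_visual_trial(model, ctx$synapses, drv$minus,
                              g_max = post$g_syn, record = rec, dt = ctx$dt)
    pk_p <- apply(res_p$ca, 2, max)
    pk_m <- apply(res_m$ca, 2, max)
    r_out <- ifelse(site_sign >= 0, pk_p, pk_m)
    r_in <- ifelse(site_sign >= 0, pk_m, pk_p)
    ok <- (r_out + r_in) > 0
    if (!any(ok)) { dsis[vi] <- 0; mets[vi] <- 0; next }
    d <- (r_out[ok] - r_in[ok]) / (r_out[ok] + r_in[ok])
    dsis[vi] <- mean(d)
    mets[vi] <- mean(directional_metric(d, r_out[ok], scenario$ca_opt))
    r_outs[vi] <- mean(r_out[ok])
  }
  fit <- if (scenario$objective == "dsi_only") mean(dsis) else mean(mets)
  structure(fit, dsi = dsis, r_out = r_outs)
}

#' Train a directional bipolar-SAC model
#'
#' Runs the elitist evolutionary algorithm: random initialization within
#' bounds, fitness = mean directional metric over velocities, retention of
#' the two best genomes, offspring drawn from the elites and mutated.
#'
#' @param scenario a [scenario_spec()].
#' @param morph a `sac_morphology` (default: synthetic SAC).
#' @param generations number of generations.
#' @param n_pop population size.
#' @param seed root RNG seed (controls initialization, placement, mutation).
#' @param n_synapses number of bipolar inputs.
#' @param dt solver step (ms).
#' @param verbose print per-generation best fitness.
#' @return a `train_result`: `best` (named genome), `best_rfs`, `best_post`,
#'   `fitness_history` (best per generation, non-decreasing), `dsi`
#'   (per-velocity DSI of the best genome), `population`, `ctx`.
#' @export
train_ds_model <- function(scenario, morph = generate_synthetic_sac(seed = 1),
                           generations = 100, n_pop = 16, seed = 1,
                           n_synapses = 200, dt = 0.1, verbose = FALSE) {
  ctx <- make_eval_context(morph, scenario, n_synapses = n_synapses,
                           seed = seed, dt = dt)
  bounds <- scenario_bounds(scenario)
  with_seed(seed + 1, {
    params <- init_population(bounds, n = n_pop, seed = seed + 2)
    annuli <- NULL
    if (scenario$mode == "annuli") {
      annuli <- matrix(sample.int(length(scenario$library),
                                  n_pop * ctx$n_bins, replace = TRUE),
                       n_pop, ctx$n_bins)
    }
    pop <- list(params = params, annuli = annuli,
                fitness = rep(NA_real_, n_pop))
    history <- numeric(generations)
    dsi_attr <- NULL
    for (gen in seq_len(generations)) {
      for (i in which(is.na(pop$fitness))) {
        ann_i <- if (is.null(pop$annuli)) NULL else pop$annuli[i, ]
        f <- evaluate_ds_fitness(setNames(pop$params[i, ], colnames(pop$params)),
                                 ctx, annuli = ann_i)
        pop$fitness[i] <- as.numeric(f)
      }
      history[gen] <- max(pop$fitness)
      if (verbose) message(sprintf("gen %3d: best fitness %.4f", gen, history[gen]))
      if (gen < generations) {
        pop <- step_generation(pop, bounds, swap_prob = scenario$swap_prob,
                               n_clusters = length(scenario$library))
      }
    }
    best_i <- which.max(pop$fitness)
    best <- setNames(pop$params[best_i, ], colnames(pop$params))
    best_ann <- if (is.null(pop$annuli)) NULL else pop$annuli[best_i, ]
    best_eval <- evaluate_ds_fitness(best, ctx, annuli = best_ann)
    structure(list(
      best = best,
      best_annuli = best_ann,
      best_rfs = if (scenario$mode != "annuli") genome_rfs(best, scenario),
      best_post = genome_postsyn(best),
      fitness_history = history,
      fitness = as.numeric(best_eval),
      dsi = attr(best_eval, "dsi"),
      population = pop, scenario = scenario, ctx = ctx
    ), class = "train_result")
  })
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result: %s scenario, best fitness %.4f, mean DSI %.1f%%>\n",
              x$scenario$mode, x$fitness, 100 * mean(x$dsi)))
  invisible(x)
}
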