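#' Membrane and calcium specification for the SAC model
#'
#' Passive properties follow the standard SAC parameterization: leak
#' conductance 4e-4 S/cm2, capacitance 1 uF/cm2, reversal -60 mV, axial
#' resistance 150 Ohm cm. The N-type calcium channel is an m^2 activation
#' stand-in (half-activation -10 mV plus a tunable offset, 6 mV slope,
#' tau_m = 1 ms, ohmic driving force toward +60 mV); the calcium pool has a
#' 50 ms time constant and 100 nM resting level, driven by the inward
#' calcium current density with gain `ca_influx_scale`.
#'
#' @param g_pas leak conductance (S/cm2).
#' @param cm specific capacitance (uF/cm2).
#' @param e_rev leak reversal potential (mV).
#' @param ra axial resistivity (Ohm cm).
#' @param g_can N-type calcium channel density (S/cm2).
#' @param can_voffset shift of the channel's half-activation voltage (mV).
#' @param ca_tau calcium pool time constant (ms).
#' @param ca_rest resting calcium (nM).
#' @param ca_influx_scale calcium influx gain, nM per (mA/cm2 x ms).
#' @param e_syn excitatory synaptic reversal potential (mV).
#' @export
membrane_spec <- function(g_pas = 4e-4, cm = 1, e_rev = -60, ra = 150,
                          g_can = 0, can_voffset = 0, ca_tau = 50,
                          ca_rest = 100, ca_influx_scale = 500, e_syn = 0) {
  if (g_pas < 0 || g_can < 0) stop("conductances must be >= 0", call. = FALSE)
  stopifnot_positive(ca_tau, "ca_tau")
  list(g_pas = g_pas, cm = cm, e_rev = e_rev, ra = ra, g_can = g_can,
       can_voffset = can_voffset, can_vhalf = -10 + can_voffset,
       can_slope = 6, can_taum = 1, e_ca = 60, ca_tau = ca_tau,
       ca_rest = ca_rest, ca_influx_scale = ca_influx_scale, e_syn = e_syn)
}

# Split a morphology into unbranched sections (chains between branch
# points), each a vector of node ids ordered soma-outward.
morph_sections <- function(morph) {
  soma <- attr(morph, "soma_id")
  kids <- split(morph$id[morph$parent != -1], morph$parent[morph$parent != -1])
  branch_nodes <- c(soma, as.integer(names(kids)[lengths(kids) >= 2]))
  starts <- unique(unlist(kids[as.character(branch_nodes)], use.names = FALSE))
  sections <- list()
  for (s in starts) {
    chain <- s
    cur <- s
    repeat {
      ch <- kids[[as.character(cur)]]
      if (is.null(ch) || length(ch) != 1L) break
      cur <- ch
      chain <- c(chain, cur)
    }
    sections[[length(sections) + 1L]] <- chain
  }
  sections
}

#' Build a compartmental SAC model from a morphology
#'
#' Splits the tree into unbranched sections, picks the number of segments
#' per section by the d-lambda rule (fraction `d_lambda` of the AC length
#' constant at `f_lambda` Hz, rounded up to an odd count), and assembles
#' topologically ordered compartments with axial conductances from the
#' half-segment resistances.
#'
#' @param morph a `sac_morphology`.
#' @param membrane a [membrane_spec()].
#' @param d_lambda segment length as a fraction of lambda (default 0.1).
#' @param f_lambda frequency for the length constant (Hz).
#' @return a `sac_model` list: `comp` (data.frame of compartments with
#'   position, length, diameter, path distance, terminal flag), `parent`
#'   (0-based), `g_axial` (uS), `membrane`, `n_seg`.
#' @export
build_sac_model <- function(morph, membrane = membrane_spec(),
                            d_lambda = 0.1, f_lambda = 100) {
  soma_id <- attr(morph, "soma_id")
  soma <- morph[morph$id == soma_id, ]
  idx <- match(morph$parent, morph$id)
  seglen <- sqrt((morph$x - morph$x[idx])^2 + (morph$y - morph$y[idx])^2 +
                 (morph$z - morph$z[idx])^2)
  sections <- morph_sections(morph)
  # order sections so parents come first (by path distance of first node)
  ord <- order(vapply(sections, function(s) morph$path_dist[match(s[1], morph$id)],
                      numeric(1)))
  sections <- sections[ord]

  soma_L <- soma$radius * 2
  comp <- list(data.frame(x = soma$x, y = soma$y, L = soma_L,
                          diam = soma$radius * 2, path_dist = 0,
                          terminal = FALSE, section = 0L))
  parent <- c(-1L)
  half_res <- function(L, diam) {  # MOhm for half a compartment
    membrane$ra * (L / 2) / (pi * (diam / 2)^2) * 1e-2
  }
  hr <- c(half_res(soma_L, soma$radius * 2))
  sec_last_comp <- c(`0` = 0L)  # node id -> 0-based index of its compartment
  node_comp <- setNames(0L, as.character(soma_id))

  for (si in seq_along(sections)) {
    ids <- sections[[si]]
    rows <- match(ids, morph$id)
    par_node <- morph$parent[rows[1]]
    L_sec <- sum(seglen[rows])
    d_mean <- mean(morph$radius[rows]) * 2
    lambda_f <- 1e5 * sqrt(d_mean / (4 * pi * f_lambda * membrane$ra * membrane$cm))
    nseg <- max(1L, as.integer((L_sec / (d_lambda * lambda_f) + 0.9) / 2) * 2L + 1L)
    # arc-length positions of section nodes, starting at the parent node
    s_nodes <- cumsum(seglen[rows])
    s0 <- c(0, s_nodes)
    xs <- c(morph$x[match(par_node, morph$id)], morph$x[rows])
    ys <- c(morph$y[match(par_node, morph$id)], morph$y[rows])
    ds <- c(morph$radius[match(par_node, morph$id)], morph$radius[rows]) * 2
    pd0 <- morph$path_dist[match(par_node, morph$id)]
    mid <- (seq_len(nseg) - 0.5) / nseg * L_sec
    cx <- approx(s0, xs, mid)$y
    cy <- approx(s0, ys, mid)$y
    cd <- approx(s0, ds, mid)$y
    term <- !(ids[length(ids)] %in% morph$parent)
    comp[[length(comp) + 1L]] <- data.frame(
      x = cx, y = cy, L = L_sec / nseg, diam = cd, path_dist = pd0 + mid,
      terminal = c(rep(FALSE, nseg - 1L), term), section = si)
    base <- length(parent)
    par_comp <- node_comp[[as.character(par_node)]]
    parent <- c(parent, par_comp, base + seq_len(nseg - 1L) - 1L)
    hr <- c(hr, half_res(L_sec / nseg, cd))
    node_comp[[as.character(ids[length(ids)])]] <- base + nseg - 1L
  }
  comp <- do.call(rbind, comp)
  n <- nrow(comp)
  g_axial <- numeric(n)
  for (i in seq_len(n)[-1]) g_axial[i] <- 1 / (hr[i] + hr[parent[i] + 1L])
  area_cm2 <- pi * comp$diam * comp$L * 1e-8
  structure(list(comp = comp, parent = as.integer(parent), g_axial = g_axial,
                 area_cm2 = area_cm2, membrane = membrane, n_seg = n,
                 soma_xy = c(soma$x, soma$y)),
            class = "sac_model")
}

#' @export
print.sac_model <- function(x, ...) {
  cat(sprintf("<sac_model: %d compartments, %d sections, %.0f um total dendrite>\n",
              x$n_seg, max(x$comp$section), sum(x$comp$L[-1])))
  invisible(x)
}

model_conductances <- function(model) {
  m <- model$membrane
  list(cap = m$cm * model$area_cm2 * 1e3,          # nF
       g_pas = m$g_pas * model$area_cm2 * 1e6)     # uS
}

# Sparse symmetric conductance matrix (uS) of the passive tree.
passive_matrix <- function(model) {
  n <- model$n_seg
  i <- seq_len(n); j <- seq_len(n); xv <- effective_g_pas(model)
  for (k in seq_len(n)[-1]) {
    p <- model$parent[k] + 1L
    ga <- model$g_axial[k]
    i <- c(i, k, p, k, p); j <- c(j, k, p, p, k)
    xv <- c(xv, ga, ga, -ga, -ga)
  }
  Matrix::sparseMatrix(i = i, j = j, x = xv, dims = c(n, n))
}

#' Steady-state voltage transfer between two sites
#'
#' Injects a small DC current at `src` in the passive model (channels
#' frozen) and returns the attenuation ratio `V(dst)/V(src)` of the
#' steady-state deflections from rest.
#'
#' @param model a `sac_model`.
#' @param src,dst compartment indices (1-based).
#' @return attenuation ratio in (0, 1\].
#' @export
dc_transfer_ratio <- function(model, src, dst) {
  v <- dc_response(model, src)
  v[dst] / v[src]
}

#' Transfer impedance between two sites
#'
#' @inheritParams dc_transfer_ratio
#' @return steady-state voltage at `dst` per unit current at `src` (MOhm).
#' @export
transfer_impedance <- function(model, src, dst) {
  v <- dc_response(model, src)
  v[dst]
}

dc_response <- function(model, src) {
  n <- model$n_seg
  b <- numeric(n); b[src] <- 1  # 1 nA -> deflection in mV = impedance in MOhm
  as.numeric(Matrix::solve(passive_matrix(model), b))
}

#' Recording sites on distal dendrites
#'
#' Terminal compartments within `y_max` um of the horizontal axis through
#' the soma — the output sites whose calcium signals enter the directional
#' analysis. Outward direction at a site is the sign of its x-position
#' relative to the soma.
#'
#' @param model a `sac_model`.
#' @param y_max maximum |y - y_soma| (um).
#' @return data.frame with `comp` (index), `x`, `y`, `outward_sign`.
#' @export
recording_sites <- function(model, y_max = 30) {
  sel <- which(model$comp$terminal & abs(model$comp$y - model$soma_xy[2]) < y_max)
  if (!length(sel)) stop("no terminal compartments near the horizontal axis", call. = FALSE)
  data.frame(comp = sel, x = model$comp$x[sel], y = model$comp$y[sel],
             outward_sign = sign(model$comp$x[sel] - model$soma_xy[1]))
}

#' Distribute bipolar synapses over proximal dendrites
#'
#' Samples `n` synaptic sites uniformly over the dendritic length within
#' `max_dist` um (path distance) of the soma. Each site carries the (x, y)
#' position to which its presynaptic RF center is aligned.
#'
#' @param model a `sac_model`.
#' @param n number of synapses.
#' @param max_dist maximum path distance from the soma (um).
#' @param seed RNG seed.
#' @return data.frame with `comp`, `x`, `y`, `path_dist`.
#' @export
place_bipolar_synapses <- function(model, n = 200, max_dist = 110, seed = 1) {
  elig <- which(model$comp$path_dist > 0 & model$comp$path_dist <= max_dist)
  if (length(elig) < 2) stop("no eligible dendritic length within `max_dist`", call. = FALSE)
  w <- model$comp$L[elig]
  with_seed(seed, {
    comp <- sample(elig, n, replace = TRUE, prob = w)
    data.frame(comp = comp, x = model$comp$x[comp], y = model$comp$y[comp],
               path_dist = model$comp$path_dist[comp])
  })
}

#' Scale electrical properties in a perisomatic annulus
#'
#' Multiplies the axial resistance (`ra_factor`) and membrane resistance
#' (`rm_factor`) of compartments within `annulus` um of the soma, leaving
#' the rest of the tree unchanged. Used to manipulate inter-dendritic
#' signal propagation (compartmentalization experiments).
#'
#' @param model a `sac_model`.
#' @param ra_factor,rm_factor multiplicative factors (> 0).
#' @param annulus path-distance radius of the modified region (um).
#' @export
perisomatic_modification <- function(model, ra_factor = 1, rm_factor = 1,
                                     annulus = 20) {
  if (ra_factor <= 0 || rm_factor <= 0) stop("factors must be > 0", call. = FALSE)
  sel <- which(model$comp$path_dist <= annulus)
  # axial conductance of a compartment's parent link scales with 1/Ra of
  # both endpoints; approximate by scaling links whose child lies inside.
  model$g_axial[intersect(sel, 2:model$n_seg)] <-
    model$g_axial[intersect(sel, 2:model$n_seg)] / ra_factor
  model$rm_scaled <- sel
  model$rm_factor <- rm_factor
  model
}

effective_g_pas <- function(model) {
  g <- model$membrane$g_pas * model$area_cm2 * 1e6
  if (!is.null(model$rm_scaled)) g[model$rm_scaled] <- g[model$rm_scaled] / model$rm_factor
  g
}

#' Inject a current step and record the response
#'
#' @param model a `sac_model`.
#' @param site compartment index of the injection.
#' @param amplitude current amplitude (pA).
#' @param duration step duration (ms).
#' @param record compartment indices to record (defaults to the injection
#'   site and the soma).
#' @param t_stop total simulated time (ms).
#' @param dt solver step (ms).
#' @return a `sim_result`: list with `t`, `v` (mV, one column per recorded
#'   site), `ca` (nM), `sites`.
#' @export
inject_current_step <- function(model, site, amplitude = 10, duration = 100,
                                record = unique(c(site, 1L)), t_stop = duration + 100,
                                dt = 0.1) {
  res <- run_cable(model, inj_idx = site, inj_amp = amplitude * 1e-3,
                   inj_t0 = 10, inj_t1 = 10 + duration,
                   t_stop = t_stop, dt = dt, record = record)
  res$stimulus <- list(kind = "current_step", site = site,
                       amplitude_pA = amplitude, duration = duration)
  res
}

#' Run a visual trial on the compartmental model
#'
#' Drives each synapse with conductance `g_max x RF_full(t)` from its
#' bipolar cell's activation trace and integrates the branched cable with
#' N-type calcium current and per-compartment calcium pools.
#'
#' @param model a `sac_model`.
#' @param synapses a synapse table from [place_bipolar_synapses()].
#' @param bc_traces matrix of RF_full traces (time x synapse) sampled at `dt_rf`.
#' @param g_max peak synaptic conductance (nS).
#' @param record compartment indices to record (default: [recording_sites()]).
#' @param dt_rf sample interval of `bc_traces` (ms).
#' @param dt solver step (ms).
#' @param out_dt recording interval (ms).
#' @return a `sim_result` (voltage mV, calcium nM at the recorded sites).
#' @export
run_visual_trial <- function(model, synapses, bc_traces, g_max = 0.1,
                             record = recording_sites(model)$comp,
                             dt_rf = 1, dt = 0.1, out_dt = 1) {
  bc_traces <- as.matrix(bc_traces)
  if (ncol(bc_traces) != nrow(synapses)) {
    stop("`bc_traces` must have one column per synapse", call. = FALSE)
  }
  t_stop <- (nrow(bc_traces) - 1) * dt_rf
  res <- run_cable(model, syn_idx = synapses$comp,
                   syn_g = bc_traces * (g_max * 1e-3),  # nS -> uS
                   dt_rf = dt_rf, t_stop = t_stop, dt = dt,
                   record = record, out_dt = out_dt)
  res
}

run_cable <- function(model, syn_idx = integer(0), syn_g = NULL, dt_rf = 1,
                      inj_idx = integer(0), inj_amp = numeric(0),
                      inj_t0 = 0, inj_t1 = 0, t_stop = 100, dt = 0.1,
                      record = 1L, out_dt = 1) {
  m <- model$membrane
  g <- model_conductances(model)
  if (is.null(syn_g)) syn_g <- matrix(0, 2, max(1, length(syn_idx)))
  g_can <- rep(m$g_can, model$n_seg)
  out <- sim_cable_cpp(model$parent, model$g_axial, g$cap, effective_g_pas(model),
                       model$area_cm2, m$e_rev,
                       g_can, m$can_vhalf, m$can_slope, m$can_taum, m$e_ca,
                       m$ca_tau, m$ca_rest, m$ca_influx_scale,
                       as.integer(syn_idx - 1L), syn_g, dt_rf, m$e_syn,
                       as.integer(inj_idx - 1L), inj_amp, inj_t0, inj_t1,
                       t_stop, dt, as.integer(record - 1L), out_dt)
  structure(list(t = out$t, v = out$v, ca = out$ca, sites = record, dt = out_dt),
            class = "sim_result")
}

#' Calcium pool response to a calcium-current trace
#'
#' First-order relaxation of the dendritic calcium pool,
#' \eqn{dCa/dt = -(Ca - Ca_{rest})/\tau + k \cdot I_{Ca}}, integrated with
#' the same explicit update as the cable solver. With constant influx the
#' fixed point is \eqn{Ca_{rest} + k I \tau}.
#'
#' @param i_ca inward calcium current density trace (mA/cm2, positive = influx).
#' @param dt time step (ms).
#' @param ca_tau,ca_rest,ca_influx_scale pool parameters (see [membrane_spec()]).
#' @return calcium trace (nM).
#' @export
ca_pool_trace <- function(i_ca, dt = 0.1, ca_tau = 50, ca_rest = 100,
                          ca_influx_scale = 500) {
  ca <- numeric(length(i_ca))
  prev <- ca_rest
  for (i in seq_along(i_ca)) {
    prev <- prev + dt * (-(prev - ca_rest) / ca_tau +
                         ca_influx_scale * max(0, i_ca[i]))
    ca[i] <- prev
  }
  ca
}
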