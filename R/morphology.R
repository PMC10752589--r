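#' Read a morphology from an SWC file
#'
#' Parses the standard 7-column SWC dialect (`id type x y z radius parent`,
#' `#` comments). Node order in the file is irrelevant; the tree is
#' validated (single root, no cycles, no orphans) and path distances to the
#' soma are computed along the edges.
#'
#' @param path path to an SWC file.
#' @return A `sac_morphology`: a data.frame with columns `id`, `type`, `x`,
#'   `y`, `z`, `radius`, `parent`, `path_dist` (um from the soma) plus a
#'   `soma_id` attribute.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop(sprintf("SWC parse error: line %d does not have 7 fields", bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]))
  as_sac_morphology(nodes)
}

as_sac_morphology <- function(nodes) {
  if (anyDuplicated(nodes$id)) stop("SWC parse error: duplicate node ids", call. = FALSE)
  if (any(nodes$radius <= 0)) stop("SWC parse error: non-positive radius", call. = FALSE)
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L) {
    stop(sprintf("morphology must have exactly one root, found %d", length(roots)),
         call. = FALSE)
  }
  idx <- match(nodes$parent, nodes$id)
  orphan <- which(nodes$parent != -1 & is.na(idx))
  if (length(orphan)) {
    stop(sprintf("SWC parse error: node %d references missing parent %d",
                 nodes$id[orphan[1]], nodes$parent[orphan[1]]), call. = FALSE)
  }
  # topological order (also detects cycles)
  n <- nrow(nodes)
  order_ <- integer(0)
  placed <- logical(n); placed[roots] <- TRUE; order_ <- roots
  repeat {
    nxt <- which(!placed & placed[idx])
    if (!length(nxt)) break
    placed[nxt] <- TRUE
    order_ <- c(order_, nxt)
  }
  if (!all(placed)) stop("SWC parse error: cycle detected in morphology", call. = FALSE)
  # path distance along edges, in topological order
  seglen <- numeric(n)
  has_par <- nodes$parent != -1
  seglen[has_par] <- sqrt((nodes$x - nodes$x[idx])^2 +
                          (nodes$y - nodes$y[idx])^2 +
                          (nodes$z - nodes$z[idx])^2)[has_par]
  pd <- numeric(n)
  for (i in order_[-1]) pd[i] <- pd[idx[i]] + seglen[i]
  nodes$path_dist <- pd
  structure(nodes, soma_id = nodes$id[roots],
            class = c("sac_morphology", "data.frame"))
}

#' Write a morphology to an SWC file
#'
#' @param morph a `sac_morphology`.
#' @param path output path.
#' @export
write_swc <- function(morph, path) {
  lines <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                   morph$id, morph$type, morph$x, morph$y, morph$z,
                   morph$radius, morph$parent)
  writeLines(c("# SWC generated by stwiring", lines), path)
  invisible(path)
}

#' Apply the thin-dendrite diameter rule
#'
#' Dendritic segments further than `cutoff` um (path distance) from the soma
#' are set to `thin_diam` um diameter, matching the normalization applied to
#' reconstructed SACs.
#'
#' @param morph a `sac_morphology`.
#' @param cutoff path distance threshold (um).
#' @param thin_diam diameter beyond the cutoff (um).
#' @export
normalize_diameters <- function(morph, cutoff = 30, thin_diam = 0.2) {
  sel <- morph$path_dist > cutoff & morph$id != attr(morph, "soma_id")
  morph$radius[sel] <- thin_diam / 2
  morph
}

#' Generate a synthetic starburst amacrine cell morphology
#'
#' Builds a radially symmetric dendritic tree: `n_primary` primary dendrites
#' leave the soma at evenly spaced angles (with small seeded jitter) and
#' bifurcate at each subsequent branch order, so the tree carries
#' `n_primary * 2^(branch_orders - 1)` terminal dendrites with tips near
#' `radius`. Dendrites taper to 0.2 um beyond 30 um from the soma. Output is
#' deterministic per seed.
#'
#' @param seed integer RNG seed.
#' @param n_primary number of primary dendrites (>= 4).
#' @param radius target dendritic field radius (um; ~110-150 for a SAC).
#' @param branch_orders number of branch orders (>= 1).
#' @param soma_diam soma diameter (um).
#' @param step spacing of morphology points along dendrites (um).
#' @return a `sac_morphology`.
#' @examples
#' m <- generate_synthetic_sac(seed = 1)
#' sum(morph_terminal_ids(m) > 0)  # 24 terminals with the defaults
#' @export
generate_synthetic_sac <- function(seed = 1, n_primary = 6, radius = 120,
                                   branch_orders = 3, soma_diam = 8,
                                   step = 10) {
  if (n_primary < 4) stop("`n_primary` must be >= 4", call. = FALSE)
  stopifnot_positive(radius, "radius")
  with_seed(seed, {
    rows <- list(c(1, 1, 0, 0, 0, soma_diam / 2, -1))
    next_id <- 2L
    seg_r <- radius / branch_orders
    # queue entries: (parent id, start x, y, angle, order)
    queue <- lapply(seq_len(n_primary), function(k) {
      ang <- 2 * pi * (k - 1) / n_primary + runif(1, -0.06, 0.06)
      list(parent = 1L, x = 0, y = 0, ang = ang, order = 1L)
    })
    while (length(queue)) {
      br <- queue[[1]]; queue <- queue[-1]
      n_pts <- max(2L, ceiling(seg_r / step))
      d <- seg_r / n_pts
      par <- br$parent; x <- br$x; y <- br$y
      for (i in seq_len(n_pts)) {
        jitter <- runif(1, -0.03, 0.03)
        x <- x + d * cos(br$ang + jitter)
        y <- y + d * sin(br$ang + jitter)
        rows[[length(rows) + 1L]] <- c(next_id, 3, x, y, 0, 0.5, par)
        par <- next_id
        next_id <- next_id + 1L
      }
      if (br$order < branch_orders) {
        spread <- pi / (n_primary * 2^br$order)
        for (s in c(-1, 1)) {
          queue[[length(queue) + 1L]] <- list(
            parent = par, x = x, y = y,
            ang = br$ang + s * spread, order = br$order + 1L)
        }
      }
    }
    m <- do.call(rbind, rows)
    nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                        x = m[, 3], y = m[, 4], z = m[, 5],
                        radius = m[, 6], parent = as.integer(m[, 7]))
    normalize_diameters(as_sac_morphology(nodes))
  })
}

# ids of terminal nodes (no children, excluding the soma)
morph_terminal_ids <- function(morph) {
  setdiff(morph$id, c(morph$parent, attr(morph, "soma_id")))
}

# total dendritic length (um)
morph_total_length <- function(morph) {
  idx <- match(morph$parent, morph$id)
  has_par <- morph$parent != -1
  sum(sqrt((morph$x - morph$x[idx])^2 + (morph$y - morph$y[idx])^2 +
           (morph$z - morph$z[idx])^2)[has_par])
}

# node ids of the subtree rooted at `root_id` (inclusive)
morph_subtree_ids <- function(morph, root_id) {
  ids <- root_id
  repeat {
    kids <- morph$id[morph$parent %in% ids & !(morph$id %in% ids)]
    if (!length(kids)) break
    ids <- c(ids, kids)
  }
  ids
}

# ids of nodes at the given branch order counted from the soma
# (order 1 = primary). A node's order = number of branch points (including
# the soma) on its path.
morph_branch_roots <- function(morph, order = 2) {
  soma <- attr(morph, "soma_id")
  child_count <- table(factor(morph$parent, levels = morph$id))
  is_branch <- as.integer(child_count) >= 2
  names(is_branch) <- morph$id
  idx <- match(morph$parent, morph$id)
  ord <- integer(nrow(morph))
  # topological walk
  o <- order(morph$path_dist)
  for (i in o) {
    if (morph$parent[i] == -1) { ord[i] <- 0L; next }
    p <- idx[i]
    ord[i] <- ord[p] + as.integer(is_branch[[as.character(morph$id[p])]] ||
                                  morph$id[p] == soma)
  }
  morph$id[ord == order & morph$parent != -1 &
           ord[idx] == order - 1]
}
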