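# Independent brute-force oracles used to cross-check the package
# implementations.  These are deliberately naive (frame-by-frame loops,
# dense grids) and share no code with the implementations they check.

# Naive per-frame permeation scanner: walks every frame of one ion,
# tracking the last bulk compartment seen; records a completed passage on
# arrival in the opposite bulk compartment, skipping transits that
# contain a wrap/teleport jump.
oracle_permeation <- function(z_mat, times, z_top, z_bottom, Lz) {
  events <- data.frame(ion_id = integer(0), t_enter = numeric(0),
                       t_exit = numeric(0), direction = character(0))
  for (ion in seq_len(ncol(z_mat))) {
    zz <- z_mat[, ion]
    last_bulk <- NA_integer_   # +1 above, -1 below
    i_last <- NA_integer_
    teleport_since <- FALSE
    for (f in seq_along(zz)) {
      if (f > 1 && abs(zz[f] - zz[f - 1]) > Lz / 2) teleport_since <- TRUE
      comp <- if (zz[f] > z_top) 1L else if (zz[f] < z_bottom) -1L else 0L
      if (comp == 0L) next
      if (!is.na(last_bulk) && comp != last_bulk && !teleport_since) {
        t_enter <- if (f > i_last + 1) times[i_last + 1] else times[i_last]
        events <- rbind(events, data.frame(
          ion_id = ion, t_enter = t_enter, t_exit = times[f],
          direction = if (last_bulk == 1L) "inward" else "outward"))
      }
      last_bulk <- comp
      i_last <- f
      teleport_since <- FALSE
    }
  }
  events[order(events$t_exit), , drop = FALSE]
}

# Dense-grid exhaustive inscribed-sphere search (default 0.01 A grid).
# `span` bounds the in-plane search domain (the pore lumen); `cap` caps
# the clearance like the implementation does.
oracle_slice_radius <- function(atoms, z, cap = 8, grid_step = 0.01,
                                span = cap, center = c(0, 0)) {
  g0 <- seq(-span, span, by = grid_step)
  gx <- g0 + center[1]; gy_all <- g0 + center[2]
  dz2 <- (z - atoms$xyz[, 3])^2
  best <- -Inf
  for (gy in gy_all) {                  # row-by-row to bound memory
    dy2 <- (gy - atoms$xyz[, 2])^2
    dx <- outer(gx, atoms$xyz[, 1], "-")
    dist <- sqrt(dx^2 + rep(dy2 + dz2, each = length(gx)))
    dim(dist) <- dim(dx)
    clr <- do.call(pmin, c(as.data.frame(sweep(dist, 2, atoms$radii)),
                           list(cap)))
    best <- max(best, clr)
  }
  best
}

# All-pairs coordination count.
oracle_coordination <- function(p, atoms, cutoff, species = NULL) {
  n <- 0L
  for (i in seq_along(atoms$species)) {
    if (!is.null(species) && toupper(atoms$species[i]) != toupper(species)) next
    if (sqrt(sum((atoms$xyz[i, ] - p)^2)) <= cutoff) n <- n + 1L
  }
  n
}

# Build a trajectory from a z matrix (x = y = 0), 1 ns per frame.
traj_from_z <- function(z_mat, box = c(30, 30, 60), species = NULL) {
  z_mat <- as.matrix(z_mat)
  nf <- nrow(z_mat); np <- ncol(z_mat)
  coords <- array(0, c(nf, np, 3))
  coords[, , 3] <- z_mat
  if (is.null(species)) species <- rep("NA", np)
  trajectory(coords, seq_len(nf), species, box)
}

kT310 <- 0.0019872041 * 310
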