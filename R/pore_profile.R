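# HOLE-style pore profiling: at each z the radius of the largest sphere
# centered in the slice plane that touches no atom.  Atoms off the plane
# still intersect it: an atom at axial offset dz contributes an effective
# in-plane radius sqrt(vdw^2 - dz^2) when |dz| < vdw, and constrains the
# sphere through 3D distance otherwise.  We maximize over the in-plane
# center the clearance  min_i ( |p - atom_i| - vdw_i )  using 3D
# distances, which reduces to the in-plane picture automatically.

#' Inscribed-sphere radius in one axial slice
#'
#' Maximizes over the in-plane center the clearance to the nearest atom
#' surface, via a deterministic multi-start grid (1 A spacing within
#' `seed_span` of the axis guess, so the search stays in the pore lumen
#' rather than jumping outside the wall) refined by Nelder-Mead.  Radii
#' are capped at `cap` A; a slice whose best sphere reaches the cap (no
#' enclosing wall) returns the cap with a bulk flag.
#'
#' @param atoms An [atom_set()].
#' @param z Slice height, A.
#' @param axis_guess Starting in-plane center (x, y), default origin.
#' @param cap Search cap, A (bulk marker; HOLE convention), default 15.
#' @param seed_span Half-width of the start grid around the guess, A.
#' @return List with `radius` (A), `center` (x, y) and `bulk` flag,
#'   class `slice_radius`.
#' @export
slice_radius <- function(atoms, z, axis_guess = c(0, 0), cap = 15,
                         seed_span = 3) {
  xyz <- atoms$xyz; rad <- atoms$radii
  # atoms able to influence the slice: within (vdw + cap) of the plane
  keep <- abs(xyz[, 3] - z) < rad + cap
  if (!any(keep)) {
    out <- list(radius = cap, center = axis_guess, bulk = TRUE)
    class(out) <- "slice_radius"
    return(out)
  }
  a <- xyz[keep, , drop = FALSE]; r <- rad[keep]
  clearance <- function(p) {
    d <- sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2 + (a[, 3] - z)^2) - r
    min(d, cap)
  }
  # deterministic start grid, 1 A spacing, centered on the guess
  g <- seq(-seed_span, seed_span, by = 1)
  sx <- axis_guess[1] + rep(g, times = length(g))
  sy <- axis_guess[2] + rep(g, each = length(g))
  dz2 <- (a[, 3] - z)^2
  vals <- vapply(seq_along(sx), function(k) {
    min(sqrt((a[, 1] - sx[k])^2 + (a[, 2] - sy[k])^2 + dz2) - r, cap)
  }, numeric(1))
  best <- which.max(vals)
  p0 <- c(sx[best], sy[best])
  opt <- stats::optim(p0, function(p) -clearance(p), method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  radius <- max(-opt$value, 0)
  bulk <- radius >= cap
  out <- list(radius = min(radius, cap), center = opt$par, bulk = bulk)
  class(out) <- "slice_radius"
  out
}

#' Pore-radius profile over frames
#'
#' Runs [slice_radius()] along a z grid for each frame (or static
#' structure) and reports the mean and sample SD across frames.
#'
#' @param frames A single [atom_set()] or a list of them (e.g. trajectory
#'   frames converted to atom sets).
#' @param z_grid Numeric vector of slice heights, A; default 0.5 A
#'   spacing over the occupied z range.
#' @param stride Keep every `stride`-th frame (default 1).
#' @param cap Search cap passed to [slice_radius()].
#' @return An object of class `pore_profile`: list with `z_grid`,
#'   `radius_mean`, `radius_sd`, `n_frames`, `min_radius`
#'   (`value`, `z`), `stride`.
#' @export
profile_over_frames <- function(frames, z_grid = NULL, stride = 1, cap = 15) {
  if (inherits(frames, "atom_set")) frames <- list(frames)
  if (!length(frames)) stop("empty frame selection")
  frames <- frames[seq(1, length(frames), by = stride)]
  if (is.null(z_grid)) {
    zr <- range(frames[[1]]$xyz[, 3])
    z_grid <- seq(zr[1], zr[2], by = 0.5)
  }
  rmat <- vapply(frames, function(fr) {
    # track the center up the pore for stability: start each slice at the
    # previous slice's optimal center
    guess <- c(0, 0)
    out <- numeric(length(z_grid))
    for (i in seq_along(z_grid)) {
      s <- slice_radius(fr, z_grid[i], axis_guess = guess, cap = cap)
      out[i] <- s$radius
      if (!s$bulk) guess <- s$center
    }
    out
  }, numeric(length(z_grid)))
  rmat <- matrix(rmat, nrow = length(z_grid))
  rmean <- rowMeans(rmat)
  rsd <- if (ncol(rmat) > 1) apply(rmat, 1, stats::sd) else rep(0, nrow(rmat))
  imin <- which.min(rmean)
  out <- list(z_grid = z_grid, radius_mean = rmean, radius_sd = rsd,
              n_frames = ncol(rmat), stride = stride,
              min_radius = list(value = rmean[imin], z = z_grid[imin]))
  class(out) <- "pore_profile"
  out
}

#' Classify the pore state from its minimum radius
#'
#' Thresholds: below 1.4 A nothing passes (closed); between 1.4 and 2.0 A
#' water but not hydrated cations (water-only); at or above 2.0 A a
#' partially hydrated cation fits (cation-permeable).
#'
#' @param profile A [profile_over_frames()] result (or a number, taken as
#'   the minimum radius in A).
#' @return One of `"closed"`, `"water-only"`, `"cation-permeable"`.
#' @export
classify_pore_state <- function(profile) {
  rmin <- if (inherits(profile, "pore_profile")) profile$min_radius$value
          else as.numeric(profile)
  if (rmin < 1.4) "closed"
  else if (rmin < 2.0) "water-only"
  else "cation-permeable"
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("Pore profile: %d slices over [%g, %g] A, %d frame(s)\n",
              length(x$z_grid), min(x$z_grid), max(x$z_grid), x$n_frames))
  cat(sprintf("min radius %.2f A at z = %.2f A -> %s\n",
              x$min_radius$value, x$min_radius$z, classify_pore_state(x)))
  invisible(x)
}

#' Write a pore profile as TSV
#'
#' Columns `z`, `radius_mean`, `radius_sd`, `n`.
#' @param profile A `pore_profile`.
#' @param path Output file.
#' @export
write_pore_profile <- function(profile, path) {
  df <- data.frame(z = profile$z_grid, radius_mean = profile$radius_mean,
                   radius_sd = profile$radius_sd, n = profile$n_frames)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
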