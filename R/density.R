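# Time-averaged 3D number-density grids, threshold segmentation of
# binding sites, coordination counting and RMSD utilities.

#' Time-averaged 3D ion-density grid
#'
#' Histograms selected particle positions over frames and divides by
#' (n_frames x voxel volume), giving a number density in A^-3.  The
#' density integrates (sum x voxel volume) to the mean per-frame count of
#' selected particles inside the grid bounds.
#'
#' @param traj A [trajectory()].
#' @param selection Particle indices or a species symbol (default: all
#'   particles).
#' @param voxel_edge Cubic voxel edge, A (default 0.5).
#' @param bounds 3 x 2 matrix (rows x/y/z, columns lo/hi), A; default the
#'   particle bounding box padded by one voxel.
#' @param stride Use every `stride`-th frame.
#' @return Object of class `density_grid`: list with `origin`,
#'   `voxel_edge`, `density` (3D array, A^-3), `n_frames`, `selection`.
#' @export
density_grid <- function(traj, selection = NULL, voxel_edge = 0.5,
                         bounds = NULL, stride = 1) {
  stopifnot(voxel_edge > 0)
  if (is.null(selection)) selection <- seq_len(n_particles(traj))
  if (is.character(selection))
    selection <- which(toupper(traj$species) == toupper(selection))
  if (!length(selection)) stop("empty selection")
  fsel <- seq(1, n_frames(traj), by = stride)
  co <- traj$coords[fsel, selection, , drop = FALSE]
  nf <- length(fsel)
  pts <- matrix(co, ncol = 3)   # (frame x particle) rows
  if (is.null(bounds)) {
    bounds <- t(apply(pts, 2, range))
    bounds[, 1] <- bounds[, 1] - voxel_edge
    bounds[, 2] <- bounds[, 2] + voxel_edge
  }
  nvox <- pmax(ceiling((bounds[, 2] - bounds[, 1]) / voxel_edge), 1)
  if (prod(nvox) < 1) stop("bounds enclose no voxel")
  idx <- floor(sweep(sweep(pts, 2, bounds[, 1]), 2, rep(voxel_edge, 3), "/")) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= nvox[1] &
            idx[, 2] >= 1 & idx[, 2] <= nvox[2] &
            idx[, 3] >= 1 & idx[, 3] <= nvox[3]
  idx <- idx[inside, , drop = FALSE]
  counts <- array(0, dim = nvox)
  if (nrow(idx)) {
    lin <- (idx[, 3] - 1) * nvox[1] * nvox[2] + (idx[, 2] - 1) * nvox[1] + idx[, 1]
    tab <- tabulate(lin, nbins = prod(nvox))
    counts[] <- tab
  }
  out <- list(origin = bounds[, 1], voxel_edge = voxel_edge,
              density = counts / (nf * voxel_edge^3),
              n_frames = nf, selection = selection)
  class(out) <- "density_grid"
  out
}

#' Integral of a density grid
#'
#' @param grid A [density_grid()].
#' @return sum(density) * voxel volume = mean selected-particle count
#'   inside the grid per frame.
#' @export
density_integral <- function(grid) sum(grid$density) * grid$voxel_edge^3

#' Segment binding sites from a density grid
#'
#' Voxels at or above the threshold are grouped into 26-neighbor
#' connected components; components are ranked by peak density and
#' centroids are density-weighted.
#'
#' @param grid A [density_grid()].
#' @param threshold Density threshold, A^-3 (> 0; default 0.005).
#' @return data.frame (class `binding_sites`) with columns `label`,
#'   `peak_density`, `cx`, `cy`, `cz`, `n_voxels`, `z_lo`, `z_hi`, ranked
#'   by peak density; attribute `members` lists voxel indices per site.
#' @export
find_binding_sites <- function(grid, threshold = 0.005) {
  stopifnot(threshold > 0)
  dn <- dim(grid$density)
  hot <- which(grid$density >= threshold)
  empty <- data.frame(label = character(0), peak_density = numeric(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      n_voxels = integer(0), z_lo = numeric(0), z_hi = numeric(0))
  if (!length(hot)) { class(empty) <- c("binding_sites", "data.frame"); return(empty) }
  ai <- arrayInd(hot, dn)
  key <- (ai[, 3] - 1) * dn[1] * dn[2] + (ai[, 2] - 1) * dn[1] + ai[, 1]
  lut <- new.env(hash = TRUE, size = length(hot))
  for (k in seq_along(key)) assign(as.character(key[k]), k, envir = lut)
  comp <- integer(length(hot))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  cid <- 0L
  for (s in seq_along(hot)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      p <- ai[cur, ]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > dn)) next
        k2 <- (q[3] - 1) * dn[1] * dn[2] + (q[2] - 1) * dn[1] + q[1]
        hit <- get0(as.character(k2), envir = lut)
        if (!is.null(hit) && comp[hit] == 0L) {
          comp[hit] <- cid
          queue <- c(queue, hit)
        }
      }
    }
  }
  cent <- sweep((ai - 0.5) * grid$voxel_edge, 2, grid$origin, "+")  # voxel centers
  dens <- grid$density[hot]
  sites <- lapply(seq_len(cid), function(cc) {
    m <- comp == cc
    w <- dens[m] / sum(dens[m])
    data.frame(peak_density = max(dens[m]),
               cx = sum(cent[m, 1] * w), cy = sum(cent[m, 2] * w),
               cz = sum(cent[m, 3] * w), n_voxels = sum(m),
               z_lo = min(cent[m, 3]) - grid$voxel_edge / 2,
               z_hi = max(cent[m, 3]) + grid$voxel_edge / 2)
  })
  df <- do.call(rbind, sites)
  o <- order(-df$peak_density)
  df <- df[o, , drop = FALSE]
  df <- cbind(label = paste0("S", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  attr(df, "members") <- lapply(seq_len(cid), function(cc) hot[comp == cc])[o]
  class(df) <- c("binding_sites", "data.frame")
  df
}

#' Count coordinating atoms within a cutoff
#'
#' @param ion_position Length-3 numeric (A) or an `n x 3` matrix of
#'   per-frame ion positions.
#' @param atoms An [atom_set()] (static) or a list of atom sets (one per
#'   frame, matched to the rows of `ion_position`).
#' @param cutoff Center-to-center cutoff, A (> 0; default 3).
#' @param species Optional species filter (e.g. "O").
#' @return Integer count, or for the batch form a list with `per_frame`
#'   counts and their `mean`.
#' @export
coordination_count <- function(ion_position, atoms, cutoff = 3, species = NULL) {
  stopifnot(cutoff > 0)
  one <- function(p, at) {
    keep <- if (is.null(species)) rep(TRUE, length(at$species))
            else toupper(at$species) == toupper(species)
    if (!any(keep)) return(0L)
    xyz <- at$xyz[keep, , drop = FALSE]
    d2 <- (xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2
    sum(d2 <= cutoff^2)
  }
  if (is.null(dim(ion_position))) return(one(ion_position, atoms))
  at_list <- if (inherits(atoms, "atom_set"))
    rep(list(atoms), nrow(ion_position)) else atoms
  per <- vapply(seq_len(nrow(ion_position)),
                function(f) one(ion_position[f, ], at_list[[f]]), integer(1))
  list(per_frame = per, mean = mean(per))
}

#' Per-frame RMSD against a reference frame
#'
#' @param traj A [trajectory()].
#' @param reference Frame index used as reference (default 1) or an
#'   `n x 3` coordinate matrix.
#' @param selection Particle indices (default all).
#' @param superpose Apply optimal rigid-body superposition (Kabsch
#'   least-squares rotation after centroid matching) before the deviation
#'   is computed.  Default FALSE, appropriate for membrane-embedded
#'   systems analyzed in a fixed frame.
#' @return Numeric vector of per-frame RMSD, A.
#' @export
rmsd_series <- function(traj, reference = 1, selection = NULL,
                        superpose = FALSE) {
  if (is.null(selection)) selection <- seq_len(n_particles(traj))
  ref <- if (is.matrix(reference)) reference
         else traj$coords[reference, selection, , drop = TRUE]
  ref <- matrix(ref, ncol = 3)
  if (nrow(ref) != length(selection))
    stop("reference/selection particle counts differ")
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- matrix(traj$coords[f, selection, , drop = TRUE], ncol = 3)
    if (superpose) {
      mc <- scale(m, scale = FALSE)
      rc <- scale(ref, scale = FALSE)
      s <- svd(t(mc) %*% rc)
      d <- sign(det(s$v %*% t(s$u)))
      R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
      m <- mc %*% t(R)
      r2 <- rc
    } else r2 <- ref
    sqrt(mean(rowSums((m - r2)^2)))
  }, numeric(1))
}

#' Write a density grid as a TSV voxel list and OpenDX-style text
#'
#' @param grid A [density_grid()].
#' @param path Output TSV path (`x, y, z, density`); if `dx_path` is
#'   given, an OpenDX-style regular-grid scalar file is written too.
#' @param dx_path Optional OpenDX output path.
#' @param min_density Only voxels above this value go into the TSV list.
#' @export
write_density_grid <- function(grid, path, dx_path = NULL, min_density = 0) {
  dn <- dim(grid$density)
  hot <- which(grid$density > min_density)
  ai <- arrayInd(hot, dn)
  cent <- sweep((ai - 0.5) * grid$voxel_edge, 2, grid$origin, "+")
  df <- data.frame(x = cent[, 1], y = cent[, 2], z = cent[, 3],
                   density = grid$density[hot])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dx_path)) {
    con <- file(dx_path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("object 1 class gridpositions counts %d %d %d", dn[1], dn[2], dn[3]),
      sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
      sprintf("delta %g 0 0", grid$voxel_edge),
      sprintf("delta 0 %g 0", grid$voxel_edge),
      sprintf("delta 0 0 %g", grid$voxel_edge),
      sprintf("object 2 class gridconnections counts %d %d %d", dn[1], dn[2], dn[3]),
      sprintf("object 3 class array type double rank 0 items %d data follows",
              prod(dn))), con)
    # OpenDX wants the last axis (z) varying fastest
    vals <- as.vector(aperm(grid$density, c(3, 2, 1)))
    writeLines(apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
                            ncol = 3, byrow = TRUE), 1,
                     function(r) paste(r[!is.na(r)], collapse = " ")), con)
    writeLines('attribute "dep" string "positions"', con)
  }
  invisible(path)
}
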