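# Trajectory container: time-ordered 3D coordinates for a fixed particle
# set, with species/charge, per-frame box and the axis convention (z = 0
# at the intracellular reference plane, +z extracellular).

#' Construct a trajectory object
#'
#' @param coords Numeric array `[n_frames, n_particles, 3]`, Angstrom.
#' @param times_ns Strictly increasing frame times, ns.
#' @param species Character vector, one symbol per particle (e.g. "NA").
#' @param box Length-3 numeric (Lx, Ly, Lz) in Angstrom, or an
#'   `n_frames x 3` matrix.
#' @param charge Optional charges in e (defaults from the species table).
#' @param exit_log Optional data.frame (`time_ns`, `ion`, `direction`) of
#'   raw boundary exits from the simulator (flux bookkeeping).
#' @param z_unwrapped Optional `n_frames x n_particles` matrix of
#'   teleport-free axial coordinates (simulator record).
#' @param seed,config Optional provenance carried in the object.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, times_ns, species, box, charge = NULL,
                       exit_log = NULL, z_unwrapped = NULL,
                       seed = NULL, config = NULL) {
  d <- dim(coords)
  if (length(d) != 3 || d[3] != 3)
    stop("coords must be an [n_frames, n_particles, 3] array")
  if (length(times_ns) != d[1]) stop("times length must match frame count")
  if (any(diff(times_ns) <= 0)) stop("frame times must be strictly increasing")
  if (length(species) != d[2]) stop("one species per particle required")
  if (is.null(dim(box))) box <- matrix(box, d[1], 3, byrow = TRUE)
  if (any(box <= 0)) stop("box lengths must be > 0")
  if (is.null(charge)) charge <- species_charge(species)
  obj <- list(coords = coords, times_ns = times_ns, species = species,
              charge = charge, box = box, exit_log = exit_log,
              z_unwrapped = z_unwrapped, seed = seed, config = config,
              axis_convention = "z0-intracellular,+z-extracellular")
  class(obj) <- "trajectory"
  obj
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames, %d particles, %.4g-%.4g ns, box %g x %g x %g A\n",
              d[1], d[2], min(x$times_ns), max(x$times_ns),
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  cat("species:", paste(unique(x$species), collapse = " "), "\n")
  if (!is.null(x$exit_log))
    cat("raw boundary exits logged:", nrow(x$exit_log), "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_particles <- function(traj) dim(traj$coords)[2]

#' Axial (z) coordinates of a trajectory
#'
#' @param traj A `trajectory`.
#' @param unwrapped If TRUE and the simulator's teleport-free record is
#'   present, return it instead of the raw z.
#' @return `n_frames x n_particles` matrix, Angstrom.
#' @export
axial_coords <- function(traj, unwrapped = FALSE) {
  if (unwrapped && !is.null(traj$z_unwrapped)) return(traj$z_unwrapped)
  z <- traj$coords[, , 3, drop = FALSE]
  dim(z) <- dim(traj$coords)[1:2]
  z
}

#' Unwrap axial coordinates across the periodic/re-injection boundary
#'
#' Makes each particle's z series continuous by minimum-image correction:
#' any inter-frame jump with |dz| > Lz/2 is folded back by the box height.
#' The raw trajectory is not modified; the unwrapped record is stored in
#' the `z_unwrapped` field of the returned copy.
#'
#' @param traj A `trajectory` with box metadata.
#' @return A `trajectory` with `z_unwrapped` set.
#' @export
unwrap_axis <- function(traj) {
  if (is.null(traj$box)) stop("unwrap_axis requires box metadata")
  z <- traj$coords[, , 3, drop = FALSE]
  dim(z) <- dim(traj$coords)[1:2]
  Lz <- traj$box[, 3]
  if (nrow(z) > 1) {
    dz <- z[-1, , drop = FALSE] - z[-nrow(z), , drop = FALSE]
    L <- matrix(Lz[-1], nrow(dz), ncol(dz))
    dz <- dz - L * round(dz / L)
    out <- z
    for (j in seq_len(ncol(z))) out[-1, j] <- z[1, j] + cumsum(dz[, j])
    z <- out
  }
  traj$z_unwrapped <- z
  traj
}
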