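# Geometric fixtures with analytically known properties: ring-built pore
# walls for profiling tests and hydration shells for coordination tests.

#' Construct an atom set
#'
#' A static structure: species, 3D coordinates and vdW radii.
#'
#' @param species Character vector of element symbols.
#' @param xyz `n x 3` numeric matrix, Angstrom.
#' @param radii Optional vdW radii (A); looked up from the default table
#'   when missing.
#' @param label Free-text label.
#' @return An object of class `atom_set`.
#' @export
atom_set <- function(species, xyz, radii = NULL, label = "") {
  xyz <- as.matrix(xyz)
  if (length(species) == 0 || nrow(xyz) == 0) stop("empty atom set")
  if (ncol(xyz) != 3 || nrow(xyz) != length(species))
    stop("xyz must be n x 3 with one row per species entry")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(radii)) radii <- vdw_radius(species)
  if (any(radii <= 0)) stop("vdW radii must be > 0")
  out <- list(species = species, xyz = xyz, radii = radii, label = label)
  class(out) <- "atom_set"
  out
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("AtomSet '%s': %d atoms, elements %s\n", x$label,
              nrow(x$xyz), paste(unique(x$species), collapse = " ")))
  invisible(x)
}

#' Build a ring-walled pore fixture with known inscribed radius
#'
#' Stacks rings of atoms around the z-axis.  The analytic inscribed-sphere
#' radius at a ring plane is `ring_radius(z) - vdw_radius`.
#'
#' @param shape `"cylinder"`, `"hourglass"` or `"radius-function"`.
#' @param z_range z extent of the wall, A.
#' @param ring_radius Radius of the atom rings (A): a constant for
#'   cylinder, the mouth radius for hourglass.
#' @param waist_radius Hourglass waist ring radius, A (at mid-height).
#' @param radius_fun For `"radius-function"`: function of z returning the
#'   ring radius.
#' @param vdw Atom vdW radius, A.
#' @param ring_spacing Axial spacing of rings, A.
#' @param atoms_per_ring Atoms per ring.
#' @param species Element symbol of the wall atoms.
#' @return An `atom_set` with attribute `analytic_radius`, a function of z.
#' @export
make_pore_fixture <- function(shape = c("cylinder", "hourglass", "radius-function"),
                              z_range = c(0, 20), ring_radius = 5,
                              waist_radius = 3, radius_fun = NULL,
                              vdw = 1.7, ring_spacing = 0.25,
                              atoms_per_ring = 12, species = "C") {
  shape <- match.arg(shape)
  if (vdw <= 0 || ring_radius <= vdw)
    stop("require ring_radius > vdw > 0 (positive pore lumen)")
  zmid <- mean(z_range)
  rfun <- switch(shape,
    cylinder = function(z) rep(ring_radius, length(z)),
    hourglass = function(z) {
      # parabolic flare: waist at zmid, ring_radius at both ends
      t <- (z - zmid) / (diff(z_range) / 2)
      waist_radius + (ring_radius - waist_radius) * t^2
    },
    `radius-function` = {
      if (is.null(radius_fun)) stop("radius_fun required for shape 'radius-function'")
      radius_fun
    })
  zs <- seq(z_range[1], z_range[2], by = ring_spacing)
  ang <- seq(0, 2 * pi, length.out = atoms_per_ring + 1)[-(atoms_per_ring + 1)]
  xyz <- do.call(rbind, lapply(zs, function(z) {
    r <- rfun(z)
    if (r <= vdw) stop("ring radius must exceed the atom vdW radius everywhere")
    cbind(r * cos(ang), r * sin(ang), z)
  }))
  out <- atom_set(rep(species, nrow(xyz)), xyz, radii = rep(vdw, nrow(xyz)),
                  label = paste0(shape, " pore fixture"))
  attr(out, "analytic_radius") <- function(z) rfun(z) - vdw
  attr(out, "waist_z") <- zmid
  out
}

#' Build a hydration-shell fixture around the origin
#'
#' Places `n` oxygen atoms at exactly `distance` from the origin,
#' maximally spread (octahedral directions first, then golden-spiral
#' points on the sphere).
#'
#' @param n_oxygens Number of oxygens (>= 0).
#' @param distance Ion-oxygen distance, A (> 0).
#' @return An `atom_set` (possibly with zero rows represented as NULL for
#'   `n_oxygens = 0`).
#' @export
make_hydration_fixture <- function(n_oxygens, distance) {
  stopifnot(n_oxygens >= 0, distance > 0)
  if (n_oxygens == 0) {
    out <- list(species = character(0), xyz = matrix(numeric(0), 0, 3),
                radii = numeric(0), label = "empty hydration fixture")
    class(out) <- "atom_set"
    return(out)
  }
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  if (n_oxygens <= 6) {
    dirs <- oct[seq_len(n_oxygens), , drop = FALSE]
  } else {
    i <- seq_len(n_oxygens)
    phi <- acos(1 - 2 * (i - 0.5) / n_oxygens)
    theta <- pi * (1 + sqrt(5)) * i
    dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  atom_set(rep("O", n_oxygens), dirs * distance,
           label = "hydration fixture")
}
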