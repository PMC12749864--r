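# Physical constants and unit conversions.  Everything downstream uses
# these helpers; no other file hard-codes a unit conversion.

#' Physical constants used by poreflux
#'
#' `kB` is the Boltzmann constant in kcal/mol/K, `faraday_kcal` converts
#' volt x elementary-charge to kcal/mol, `e_coulomb` is the elementary
#' charge in coulomb, and `coulomb_kcal` is the Coulomb-law prefactor
#' q1*q2/r in kcal*A/mol/e^2.
#'
#' @format A named list.
#' @export
pf_constants <- list(
  kB           = 0.0019872041,   # kcal/mol/K
  faraday_kcal = 23.0609,        # kcal/mol per (V * e)
  e_coulomb    = 1.602176634e-19,
  coulomb_kcal = 332.06          # kcal*A/mol/e^2
)

#' Thermal energy kT
#'
#' @param temperature Temperature in kelvin (scalar or vector, >= 0).
#' @return Thermal energy k_B * T in kcal/mol.
#' @examples
#' thermal_energy(310)   # 0.616 kcal/mol
#' @export
thermal_energy <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature < 0))
    stop("temperature must be finite and >= 0 K")
  pf_constants$kB * temperature
}

#' Convert a membrane potential to a uniform axial field
#'
#' Represents a transmembrane voltage as a constant force per unit charge
#' along the channel axis, the reduced-model analogue of applying an
#' external electric field along z in an all-atom simulation.
#'
#' @param potential_mV Membrane potential in millivolt.  Negative values
#'   drive cations toward -z (the intracellular side).
#' @param box_height Length in Angstrom over which the potential drops.
#' @return Axial field in kcal/mol/A/e, sign preserved.
#' @examples
#' field_from_potential(-100, 170.8)  # ~ -0.0135 kcal/mol/A/e
#' @export
field_from_potential <- function(potential_mV, box_height) {
  if (!is.finite(box_height) || box_height <= 0)
    stop("box_height must be a positive length in Angstrom")
  (potential_mV / 1000) * pf_constants$faraday_kcal / box_height
}

#' Single-channel conductance from permeation counts
#'
#' Implements G = N_permeation * Q_ion / (t_trajectory * V_membrane) per
#' run, with the mean and the sample (n-1) standard deviation across runs.
#'
#' @param event_counts Integer vector, permeation events per run (>= 0).
#' @param durations_ns Numeric vector, trajectory length per run in ns (> 0).
#' @param potential_mV Membrane potential in mV (nonzero); its magnitude is
#'   used so that conductance is reported as a positive quantity.
#' @param ion_charge Ion charge in elementary-charge units (default +1).
#' @return An object of class `conductance_estimate`: list with
#'   `per_run_pS`, `mean_pS`, `sd_pS` (NA for a single run), `n_events`,
#'   `durations_ns`, `potential_mV`, `ion_charge_e`.
#' @examples
#' conductance_estimate(c(35, 31, 34), c(1500, 1500, 1500), -100)
#' @export
conductance_estimate <- function(event_counts, durations_ns,
                                 potential_mV = -100, ion_charge = 1) {
  if (length(event_counts) != length(durations_ns))
    stop("event_counts and durations_ns must have equal length")
  if (length(event_counts) == 0) stop("at least one run is required")
  if (any(event_counts < 0)) stop("event counts must be >= 0")
  if (any(durations_ns <= 0)) stop("durations must be > 0 ns")
  if (potential_mV == 0) stop("membrane potential must be nonzero")
  q_C <- ion_charge * pf_constants$e_coulomb
  t_s <- durations_ns * 1e-9
  v_V <- abs(potential_mV) / 1000
  g_S <- event_counts * q_C / (t_s * v_V)
  per_run <- g_S * 1e12   # pS
  out <- list(
    per_run_pS   = per_run,
    mean_pS      = mean(per_run),
    sd_pS        = if (length(per_run) > 1) stats::sd(per_run) else NA_real_,
    n_events     = as.integer(event_counts),
    durations_ns = durations_ns,
    potential_mV = potential_mV,
    ion_charge_e = ion_charge
  )
  class(out) <- "conductance_estimate"
  out
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("Single-channel conductance: %.1f", x$mean_pS))
  if (!is.na(x$sd_pS)) cat(sprintf(" +/- %.1f", x$sd_pS))
  cat(sprintf(" pS  (%d runs, %d events, %g mV)\n",
              length(x$per_run_pS), sum(x$n_events), x$potential_mV))
  invisible(x)
}

# Default van der Waals radii (A) for pore profiling and structure input.
# A deliberately small table in the spirit of HOLE's simple radius files;
# override via the `radii` arguments of read_structure()/slice_radius().
.default_vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                  P = 1.80, NA. = 2.27, CL = 1.75, K = 2.75, F = 1.47)

#' Default van der Waals radius lookup
#'
#' @param species Character vector of element symbols (case-insensitive).
#' @param radii Optional named numeric vector overriding/extending the
#'   built-in table.
#' @param default Radius in Angstrom assigned to unknown elements
#'   (a warning is emitted once per call).
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(species, radii = NULL, default = 1.70) {
  tab <- .default_vdw
  names(tab) <- sub("\\.$", "", names(tab))
  if (!is.null(radii)) tab[toupper(names(radii))] <- radii
  key <- toupper(species)
  out <- unname(tab[key])
  if (anyNA(out)) {
    warning("unknown element(s) ", paste(unique(key[is.na(out)]), collapse = ", "),
            ": using default radius ", default, " A")
    out[is.na(out)] <- default
  }
  out
}

# Default charge per species, elementary-charge units.
.species_charge <- c(NA. = 1, K = 1, CL = -1, CA = 2, MG = 2)

species_charge <- function(species) {
  tab <- .species_charge
  names(tab) <- sub("\\.$", "", names(tab))
  out <- unname(tab[toupper(species)])
  out[is.na(out)] <- 0
  out
}
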