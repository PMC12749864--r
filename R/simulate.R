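# Brownian-dynamics front end: configuration objects and R wrappers
# around the compiled Euler-Maruyama integrator.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the all-atom reference system
#' in reduced form: 310 K, a ~150 mM ion count for the reduced box
#' (6 ions in 30 x 30 x 60 A), sodium-like diffusion coefficient
#' 0.1 A^2/ps, 0.01 ps timestep, pore region 0-40 A along z.
#'
#' @param n_ions Number of mobile ions.
#' @param temperature Kelvin.  0 disables noise (gradient descent; the
#'   310 K mobility is then used).
#' @param diffusion Diffusion coefficient, A^2/ps.
#' @param timestep Integration step, ps.
#' @param n_steps Number of steps.
#' @param save_stride Save a frame every this many steps.
#' @param box Lengths (Lx, Ly, Lz), A.  The z domain is
#'   `z_bottom + c(0, Lz)`.
#' @param z_bottom Bottom (intracellular) wall position, A.  Ions crossing
#'   it are logged as raw exits and re-injected one box height up.
#' @param pore_region z interval (A) of the pore (radial confinement and
#'   field interval default to it).
#' @param pore_radius Flat-bottom confinement radius inside the pore, A.
#' @param reservoir_radius Confinement radius outside the pore, A.
#' @param radial_k Confinement stiffness, kcal/mol/A^2.
#' @param ion_species Species label for the mobile ions.
#' @param bottom_wall `"reinject"` (default; crossing ions are logged as
#'   raw exits and teleported one box height up, sustaining a steady
#'   conduction flux) or `"reflect"` (closed box, true equilibrium).
#' @param seed Integer master seed, recorded in all outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_ions = 6, temperature = 310, diffusion = 0.1,
                       timestep = 0.01, n_steps = 100000, save_stride = 100,
                       box = c(30, 30, 60), z_bottom = -10,
                       pore_region = c(0, 40), pore_radius = 2.5,
                       reservoir_radius = 12, radial_k = 1,
                       ion_species = "NA",
                       bottom_wall = c("reinject", "reflect"), seed = 1) {
  bottom_wall <- match.arg(bottom_wall)
  stopifnot(timestep > 0, save_stride >= 1, n_steps >= 1, n_ions >= 1,
            diffusion > 0, temperature >= 0, all(box > 0))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Flatten a channel_potential + per-ion bias into the C++ call.
.run_core <- function(cfg, pot, init, charges, bias_k, bias_c,
                      max_step = 2.0) {
  kT <- thermal_energy(cfg$temperature)
  mobility <- cfg$diffusion / thermal_energy(max(cfg$temperature, 310))
  if (cfg$temperature > 0) mobility <- cfg$diffusion / kT
  zlo <- cfg$z_bottom
  zhi <- cfg$z_bottom + cfg$box[3]
  res <- cpp_simulate(init, charges,
                      as.integer(cfg$n_steps), cfg$timestep, cfg$diffusion,
                      kT, as.integer(cfg$save_stride),
                      zlo, zhi,
                      cfg$pore_region[1], cfg$pore_region[2],
                      cfg$pore_radius, cfg$reservoir_radius, cfg$radial_k,
                      pot$wells$center, pot$wells$depth, pot$wells$width,
                      pot$barriers$center, pot$barriers$height, pot$barriers$width,
                      pot$field, pot$field_range[1], pot$field_range[2],
                      pot$repulsion$prefactor / pot$repulsion$eps_r,
                      pot$repulsion$screening, 1.0,
                      bias_k, bias_c, mobility, max_step,
                      as.integer(identical(cfg$bottom_wall, "reflect")))
  res
}

#' Simulate free (unbiased) Langevin dynamics of ions in the channel
#'
#' Overdamped Euler-Maruyama dynamics in the given channel potential with
#' screened ion-ion repulsion, radial flat-bottom confinement, a
#' reflecting wall at the top of the box and re-injection (with raw-exit
#' logging) at the bottom.  Identical seeds give identical trajectories.
#'
#' @param cfg A [sim_config()].
#' @param pot A [channel_potential()].
#' @param init Optional `n_ions x 3` matrix of starting coordinates;
#'   by default ions start spread through the extracellular reservoir.
#' @return A [trajectory()] carrying the raw-exit log and the
#'   teleport-free `z_unwrapped` record.
#' @export
simulate_langevin <- function(cfg, pot, init = NULL) {
  set.seed(cfg$seed)
  zhi <- cfg$z_bottom + cfg$box[3]
  if (is.null(init)) {
    r <- sqrt(stats::runif(cfg$n_ions)) * cfg$reservoir_radius * 0.8
    th <- stats::runif(cfg$n_ions, 0, 2 * pi)
    init <- cbind(r * cos(th), r * sin(th),
                  stats::runif(cfg$n_ions, cfg$pore_region[2] + 1, zhi - 1))
  }
  res <- .run_core(cfg, pot, init, rep(1, cfg$n_ions),
                   numeric(cfg$n_ions), numeric(cfg$n_ions))
  times <- seq(0, cfg$n_steps, by = cfg$save_stride) * cfg$timestep / 1000
  exit_log <- data.frame(time_ns = res$exit_time_ps / 1000,
                         ion = res$exit_ion,
                         direction = ifelse(res$exit_dir < 0, "inward", "outward"))
  trajectory(res$coords, times,
             species = rep(cfg$ion_species, cfg$n_ions),
             box = cfg$box, charge = rep(1, cfg$n_ions),
             exit_log = exit_log, z_unwrapped = res$z_unwrapped,
             seed = cfg$seed, config = cfg)
}

#' Umbrella-window specification
#'
#' @param center Window center along z, A.
#' @param force_constant Harmonic bias on the tagged ion, kcal/mol/A^2.
#' @param extra_ion_positions z positions (A) of additional restrained
#'   upstream ions (e.g. at binding sites A/B), possibly empty.
#' @param restraint_constant_extra Restraint stiffness for the extra ions,
#'   kcal/mol/A^2 (default 2.5).
#' @return An object of class `umbrella_spec`.
#' @export
umbrella_spec <- function(center, force_constant = 5,
                          extra_ion_positions = numeric(0),
                          restraint_constant_extra = 2.5) {
  stopifnot(force_constant > 0,
            length(extra_ion_positions) == 0 || restraint_constant_extra > 0)
  out <- list(center = center, force_constant = force_constant,
              extra_ion_positions = extra_ion_positions,
              restraint_constant_extra = restraint_constant_extra)
  class(out) <- "umbrella_spec"
  out
}

#' Simulate one umbrella-sampling window
#'
#' Dynamics as in [simulate_langevin()] plus a harmonic bias
#' 0.5*k*(z - center)^2 on the tagged ion and positional restraints on any
#' extra ions.  The tagged ion starts at the window center (windows are
#' initialized directly rather than by a pulling run; only the stationary
#' window distribution enters WHAM).
#'
#' @param cfg A [sim_config()]; `n_ions` is overridden to
#'   1 + number of extra ions.
#' @param pot A [channel_potential()].
#' @param spec An [umbrella_spec()].
#' @return An object of class `window_series`: list with `time_ns`, `z`
#'   (tagged-ion axial series at `save_stride`), `spec`, `seed`.
#' @export
simulate_umbrella_window <- function(cfg, pot, spec) {
  n_extra <- length(spec$extra_ion_positions)
  cfg$n_ions <- 1L + n_extra
  set.seed(cfg$seed)
  init <- cbind(rep(0, cfg$n_ions), rep(0, cfg$n_ions),
                c(spec$center, spec$extra_ion_positions))
  bias_k <- c(spec$force_constant,
              rep(spec$restraint_constant_extra, n_extra))
  bias_c <- c(spec$center, spec$extra_ion_positions)
  res <- .run_core(cfg, pot, init, rep(1, cfg$n_ions), bias_k, bias_c)
  times <- seq(0, cfg$n_steps, by = cfg$save_stride) * cfg$timestep / 1000
  out <- list(time_ns = times, z = res$coords[, 1, 3],
              spec = spec, seed = cfg$seed)
  class(out) <- "window_series"
  out
}
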