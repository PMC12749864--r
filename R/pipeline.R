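# End-to-end pipeline: one configuration drives simulation, permeation
# counting, conductance, pore profiling, density/binding sites, umbrella
# sampling + WHAM and the structured run report.

#' Pipeline configuration
#'
#' Bundles simulator, analysis and umbrella settings with one master
#' seed.  Round-trips losslessly through JSON
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed Master seed (integer).
#' @param sim Named list overriding [sim_config()] defaults for the
#'   conduction run (e.g. `list(n_steps = 2e5)`).
#' @param potential Named list overriding [default_channel_potential()]
#'   arguments (e.g. `list(field = -0.0577)`).
#' @param membrane_potential_mV Membrane potential for the conduction run
#'   and the conductance estimate, mV; the axial field is derived from it
#'   across the pore region.
#' @param z_top,z_bottom Permeation boundary planes, A.
#' @param sites Named list of site z ranges.
#' @param voxel_edge,density_threshold Density-grid controls.
#' @param window_span,window_spacing,window_k Umbrella plan (A, A,
#'   kcal/mol/A^2).
#' @param window_steps Steps per umbrella window.
#' @param window_stride Save stride within windows.
#' @param burn_in Window burn-in fraction.
#' @param wham_bin,wham_tol WHAM bin width (A) and tolerance (kcal/mol).
#' @param cooperativity_window Hand-off window, ns.
#' @param out_dir Output directory for reports and TSV sidecars.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = list(), potential = list(),
                            membrane_potential_mV = -100,
                            z_top = 40, z_bottom = -5,
                            sites = lapply(default_sites(), `[[`, "z_range"),
                            voxel_edge = 0.5, density_threshold = 0.005,
                            window_span = 15, window_spacing = 0.5,
                            window_k = 5, window_steps = 1e6,
                            window_stride = 70, burn_in = 0.3,
                            wham_bin = 0.1, wham_tol = 1e-6,
                            cooperativity_window = 1,
                            out_dir = tempfile("poreflux_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / parse a pipeline configuration (JSON)
#'
#' @param cfg A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$sites <- lapply(cfg$sites, as.numeric)
  cfg$sim <- as.list(cfg$sim)
  cfg$potential <- as.list(cfg$potential)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' simulate -> permeation + conductance -> pore profile -> density +
#' binding sites -> umbrella sampling + WHAM + barriers -> report.
#' Bitwise-reproducible given the master seed (the report contains no
#' wall-clock fields).
#'
#' @param cfg A [pipeline_config()].
#' @param pore_atoms Optional [atom_set()] for pore profiling; by default
#'   an hourglass fixture whose waist mirrors an open gate is used.
#' @param quiet Suppress progress messages.
#' @return Object of class `run_report` (also written to
#'   `cfg$out_dir/report.json` with TSV sidecars).
#' @export
run_pipeline <- function(cfg, pore_atoms = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "), ...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  tryCatch({
    # --- potential and simulator config
    pot_args <- cfg$potential
    sim_args <- cfg$sim
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    if (is.null(pot_args$field))
      pot_args$field <- field_from_potential(
        cfg$membrane_potential_mV, diff(scfg$pore_region))
    pot <- do.call(default_channel_potential, pot_args)
    say("seed ", cfg$seed, "; field ", signif(pot$field, 4), " kcal/mol/A/e")

    stage <- "simulate"
    traj <- simulate_langevin(scfg, pot)

    stage <- "permeation"
    ev <- detect_permeations(traj, z_top = cfg$z_top, z_bottom = cfg$z_bottom)
    write_events(ev, file.path(cfg$out_dir, "events.tsv"))
    n_in <- sum(ev$direction == "inward")
    dur <- max(traj$times_ns) - min(traj$times_ns)
    cond <- conductance_estimate(n_in, dur, cfg$membrane_potential_mV)
    sites_def <- lapply(names(cfg$sites), function(l)
      site_definition(l, cfg$sites[[l]]))
    occ <- site_occupancy(traj, sites_def)
    coop <- cooperativity_fraction(occ, ev, window = cfg$cooperativity_window)

    stage <- "pore_profile"
    if (is.null(pore_atoms))
      pore_atoms <- make_pore_fixture("hourglass", z_range = c(0, 40),
                                      ring_radius = 6, waist_radius = 4.2)
    prof <- profile_over_frames(pore_atoms)
    write_pore_profile(prof, file.path(cfg$out_dir, "pore_profile.tsv"))

    stage <- "density"
    grid <- density_grid(traj, selection = scfg$ion_species,
                         voxel_edge = cfg$voxel_edge,
                         bounds = rbind(c(-6, 6), c(-6, 6), c(0, 40)))
    sites <- find_binding_sites(grid, threshold = cfg$density_threshold)
    utils::write.table(as.data.frame(sites),
                       file.path(cfg$out_dir, "binding_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "umbrella_wham"
    centers <- build_windows(cfg$window_span, cfg$window_spacing)
    wcfg <- scfg
    wcfg$n_steps <- as.integer(cfg$window_steps)
    wcfg$save_stride <- as.integer(cfg$window_stride)
    pot0 <- do.call(default_channel_potential,
                    utils::modifyList(pot_args, list(field = 0)))
    wins <- run_umbrella_ladder(pot0, centers, wcfg,
                                force_constant = cfg$window_k,
                                burn_in = cfg$burn_in)
    wh <- wham_pmf(wins, bin_width = cfg$wham_bin, tolerance = cfg$wham_tol,
                   temperature = scfg$temperature,
                   range = c(0, cfg$window_span))
    write_pmf(wh$pmf, file.path(cfg$out_dir, "pmf.tsv"))
    bars <- barrier_heights(wh$pmf, cfg$sites)

    stage <- "report"
    cfg_path <- file.path(cfg$out_dir, "config.json")
    write_pipeline_config(cfg, cfg_path)
    # hash the scientific settings only (not the output location)
    hcfg <- cfg
    hcfg$out_dir <- NULL
    hpath <- tempfile(fileext = ".json")
    write_pipeline_config(hcfg, hpath)
    cfg_md5 <- unname(tools::md5sum(hpath))
    unlink(hpath)
    report <- list(
      provenance = list(
        package = "poreflux",
        version = as.character(utils::packageVersion("poreflux")),
        seed = cfg$seed,
        config_md5 = cfg_md5),
      permeation = list(
        n_inward = n_in,
        n_outward = sum(ev$direction == "outward"),
        raw_exits = raw_exit_count(traj),
        duration_ns = dur,
        cooperativity_fraction = as.numeric(coop),
        occupancy_fraction = as.list(occupancy_fraction(occ))),
      conductance = list(
        per_run_pS = cond$per_run_pS, mean_pS = cond$mean_pS,
        sd_pS = cond$sd_pS, potential_mV = cond$potential_mV),
      pore = list(min_radius_A = prof$min_radius$value,
                  min_radius_z = prof$min_radius$z,
                  state = classify_pore_state(prof)),
      binding_sites = as.data.frame(sites),
      pmf = list(n_windows = length(wins),
                 converged = wh$converged,
                 min_adjacent_overlap = wh$min_adjacent_overlap,
                 barriers = bars))
    class(report) <- "run_report"
    jsonlite::write_json(unclass(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    say("report written to ", cfg$out_dir)
    report
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         " (partial outputs in ", cfg$out_dir, ")", call. = FALSE)
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("poreflux run report (seed ", x$provenance$seed, ")\n", sep = "")
  cat(sprintf("  permeation: %d inward / %d outward in %.3g ns\n",
              x$permeation$n_inward, x$permeation$n_outward,
              x$permeation$duration_ns))
  cat(sprintf("  conductance: %.2f pS at %g mV\n",
              x$conductance$mean_pS, x$conductance$potential_mV))
  cat(sprintf("  pore: min radius %.2f A (%s)\n",
              x$pore$min_radius_A, x$pore$state))
  cat(sprintf("  binding sites: %d above threshold\n",
              nrow(x$binding_sites)))
  bc <- x$pmf$barriers
  for (i in seq_len(nrow(bc)))
    cat(sprintf("  barrier %s: %.2f kcal/mol\n", bc$site[i], bc$barrier[i]))
  invisible(x)
}
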