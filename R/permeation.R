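# Permeation-event detection, binding-site occupancy and the cooperative
# (knock-off) hand-off statistic.

#' Detect completed permeation events
#'
#' Three-compartment state machine per ion: extracellular (z > z_top),
#' pore, intracellular (z < z_bottom).  An inward event is the ordered
#' passage extracellular -> pore -> intracellular; after an event the ion
#' must re-enter from a bulk compartment before it can count again.
#' Outward events are tracked symmetrically.  `t_enter` is the time of the
#' first in-pore frame of the transit (the last bulk frame when the
#' crossing falls between saved frames); `t_exit` is the first frame in
#' the destination compartment.  Events are sorted by `t_exit`.
#'
#' @param traj A [trajectory()].  Transits containing an inter-frame jump
#'   larger than half the box height (a re-injection teleport or a
#'   periodic wrap) are boundary bookkeeping, not passages through the
#'   pore, and are never counted as events; the raw simulator output can
#'   therefore be used directly.
#' @param z_top Extracellular boundary plane, A (default 40).
#' @param z_bottom Intracellular boundary plane, A (default -5).
#' @param unwrapped Use the unwrapped axial record if available.
#' @return data.frame with columns `ion_id`, `t_enter`, `t_exit`,
#'   `direction` ("inward"/"outward"), class `permeation_events`.
#' @export
detect_permeations <- function(traj, z_top = 40, z_bottom = -5,
                               unwrapped = FALSE) {
  if (z_top <= z_bottom) stop("z_top must exceed z_bottom")
  z <- axial_coords(traj, unwrapped = unwrapped)
  if (is.null(dim(z))) z <- matrix(z, ncol = n_particles(traj))
  times <- traj$times_ns
  out <- list()
  Lz <- traj$box[, 3]
  for (i in seq_len(ncol(z))) {
    comp <- ifelse(z[, i] > z_top, 1L, ifelse(z[, i] < z_bottom, -1L, 0L))
    jump <- if (nrow(z) > 1) abs(diff(z[, i])) > Lz[-1] / 2 else logical(0)
    idx <- which(comp != 0L)
    if (length(idx) < 2) next
    cc <- comp[idx]
    trans <- which(cc[-1] != cc[-length(cc)])
    for (k in trans) {
      i_src <- idx[k]; i_dst <- idx[k + 1]
      if (any(jump[i_src:(i_dst - 1)])) next   # teleport/wrap, not a passage
      t_enter <- if (i_dst > i_src + 1) times[i_src + 1] else times[i_src]
      out[[length(out) + 1]] <- data.frame(
        ion_id = i, t_enter = t_enter, t_exit = times[i_dst],
        direction = if (cc[k] == 1L) "inward" else "outward")
    }
  }
  ev <- if (length(out)) do.call(rbind, out)
        else data.frame(ion_id = integer(0), t_enter = numeric(0),
                        t_exit = numeric(0), direction = character(0))
  ev <- ev[order(ev$t_exit), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("permeation_events", "data.frame")
  ev
}

#' Define a binding site along the pore axis
#'
#' @param label Site label ("A", "B", "C", ...).
#' @param z_range Length-2 numeric, z interval (A), low < high.
#' @param radial_cutoff Optional in-plane radial cutoff, A.
#' @return An object of class `site_definition`.
#' @export
site_definition <- function(label, z_range, radial_cutoff = NULL) {
  stopifnot(length(z_range) == 2, z_range[1] < z_range[2])
  out <- list(label = label, z_range = z_range, radial_cutoff = radial_cutoff)
  class(out) <- "site_definition"
  out
}

#' Default binding-site definitions for the calibrated channel
#'
#' z intervals bracketing the default well centers (C at 9, B at 19,
#' A at 24 A); half-open on the shared boundaries so sites never overlap.
#' @return List of [site_definition()]s named A, B, C.
#' @export
default_sites <- function() {
  list(A = site_definition("A", c(21.5, 28)),
       B = site_definition("B", c(14, 21.5)),
       C = site_definition("C", c(5.5, 14)))
}

.check_sites <- function(sites) {
  if (!length(sites)) stop("at least one site required")
  rng <- t(vapply(sites, function(s) s$z_range, numeric(2)))
  o <- order(rng[, 1])
  rng <- rng[o, , drop = FALSE]
  if (nrow(rng) > 1 && any(rng[-1, 1] < rng[-nrow(rng), 2] - 1e-12))
    stop("site z ranges overlap")
  invisible(TRUE)
}

#' Per-frame binding-site occupancy
#'
#' Assigns each ion whose z lies in `[low, high)` of a site (and within
#' the radial cutoff, when set) to that site.  Sites may hold several
#' ions (multi-occupancy, as at the outermost site).
#'
#' @param traj A [trajectory()].
#' @param sites List of [site_definition()]s (non-overlapping).
#' @return An object of class `occupancy_table`: list with `times_ns` and
#'   `occupants`, a per-site list of per-frame integer vectors of ion ids.
#' @export
site_occupancy <- function(traj, sites = default_sites()) {
  .check_sites(sites)
  z <- axial_coords(traj)
  if (is.null(dim(z))) z <- matrix(z, ncol = n_particles(traj))
  x <- traj$coords[, , 1, drop = FALSE]; dim(x) <- dim(z)
  y <- traj$coords[, , 2, drop = FALSE]; dim(y) <- dim(z)
  occ <- lapply(sites, function(s) {
    inside <- z >= s$z_range[1] & z < s$z_range[2]
    if (!is.null(s$radial_cutoff))
      inside <- inside & (x^2 + y^2 <= s$radial_cutoff^2)
    lapply(seq_len(nrow(z)), function(f) which(inside[f, ]))
  })
  names(occ) <- vapply(sites, function(s) s$label, character(1))
  out <- list(times_ns = traj$times_ns, occupants = occ)
  class(out) <- "occupancy_table"
  out
}

#' Occupancy fractions per site
#'
#' @param occ An [site_occupancy()] table.
#' @return Named numeric: fraction of frames with at least one occupant.
#' @export
occupancy_fraction <- function(occ) {
  vapply(occ$occupants, function(site) mean(lengths(site) > 0), numeric(1))
}

#' Cooperative (knock-off) fraction of inward permeation events
#'
#' For each inward event, locates the release of the event ion from site C
#' (its last frame as a C occupant before `t_exit`) and asks whether,
#' within `+/- window` ns of that release, the previous site-B occupant
#' becomes the site-C occupant (a B -> C hand-off).  The fraction of
#' inward events with a hand-off is returned; events whose ion never
#' visited site C do not qualify.
#'
#' @param occ An [site_occupancy()] table containing sites "B" and "C".
#' @param events A [detect_permeations()] result.
#' @param window Hand-off window, ns (> 0; default 1).
#' @return Numeric fraction in `[0, 1]` with attributes `n_events`
#'   (inward events considered) and `n_cooperative`; `NA` (flagged via
#'   attribute `undefined = TRUE`) when there are no inward events.
#' @export
cooperativity_fraction <- function(occ, events, window = 1) {
  stopifnot(window > 0, all(c("B", "C") %in% names(occ$occupants)))
  inw <- events[events$direction == "inward", , drop = FALSE]
  if (nrow(inw) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  times <- occ$times_ns
  occB <- occ$occupants$B; occC <- occ$occupants$C
  coop <- logical(nrow(inw))
  for (e in seq_len(nrow(inw))) {
    ion <- inw$ion_id[e]
    inC <- vapply(occC, function(v) ion %in% v, logical(1)) &
           times <= inw$t_exit[e]
    rel <- if (any(inC)) max(which(inC)) else NA_integer_
    if (is.na(rel)) next
    # previous B occupant: the most recent frame at/before release where B
    # is occupied
    bframes <- which(lengths(occB) > 0 & seq_along(occB) <= rel)
    if (!length(bframes)) next
    b_prev <- occB[[max(bframes)]][1]
    if (b_prev == ion) next
    in_win <- which(abs(times - times[rel]) <= window)
    coop[e] <- any(vapply(occC[in_win], function(v) b_prev %in% v, logical(1)))
  }
  out <- sum(coop) / nrow(inw)
  attr(out, "n_events") <- nrow(inw)
  attr(out, "n_cooperative") <- sum(coop)
  out
}

#' Net inward flux from the simulator's raw-exit log
#'
#' @param traj A simulated [trajectory()] with an exit log.
#' @return Integer count of raw bottom-boundary exits (each a completed
#'   inward passage at the absorbing/re-injection boundary).
#' @export
raw_exit_count <- function(traj) {
  if (is.null(traj$exit_log)) stop("trajectory carries no exit log")
  sum(traj$exit_log$direction == "inward")
}
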