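# Umbrella-sampling window construction and the weighted histogram
# analysis method (WHAM).  The estimator iterates the standard coupled
# equations
#   P(z)        = sum_i n_i(z) / sum_j N_j exp(beta f_j - beta w_j(z))
#   exp(-b f_j) = sum_z P(z) exp(-beta w_j(z)),   w_j(z) = k_j/2 (z-c_j)^2
# to self-consistency in the per-window shifts f_j, then reports
# F(z) = -kT ln P(z) anchored to min 0.

#' Build umbrella window centers
#'
#' Centers at 0, spacing, ..., span (both endpoints included).
#'
#' @param span Reaction-coordinate length, A (>= 0).
#' @param spacing Window spacing, A (> 0; default 0.5).
#' @param from Origin of the ladder (default 0).
#' @return Numeric vector of centers; length span/spacing + 1.
#' @export
build_windows <- function(span, spacing = 0.5, from = 0) {
  stopifnot(span >= 0, spacing > 0)
  n <- span / spacing
  if (abs(n - round(n)) > 1e-9)
    stop("span must be an integer multiple of spacing ",
         "(e.g. span = ", round(n) * spacing, ")")
  from + seq(0, span, by = spacing)
}

#' Package window samples for WHAM
#'
#' @param center Window center, A.
#' @param force_constant Bias force constant, kcal/mol/A^2 (> 0).
#' @param samples Numeric vector of reaction-coordinate samples, A.
#' @param burn_in Fraction of initial samples discarded (default 0.3,
#'   mirroring the use of the last 7 ns of 10-ns windows).
#' @param offset Optional constant added to the window bias (affects only
#'   the recovered shifts, never the PMF).
#' @return Object of class `umbrella_window` with `n_raw`, `n_used`.
#' @export
umbrella_window <- function(center, force_constant, samples, burn_in = 0.3,
                            offset = 0) {
  stopifnot(force_constant >= 0, burn_in >= 0, burn_in < 1)  # 0 = unbiased
  n_raw <- length(samples)
  keep <- samples[seq.int(floor(n_raw * burn_in) + 1, n_raw)]
  out <- list(center = center, force_constant = force_constant,
              samples = keep, n_raw = n_raw, n_used = length(keep),
              offset = offset)
  class(out) <- "umbrella_window"
  out
}

#' @rdname umbrella_window
#' @param ws A [simulate_umbrella_window()] result (`window_series`).
#' @export
as_umbrella_window <- function(ws, burn_in = 0.3) {
  umbrella_window(ws$spec$center, ws$spec$force_constant, ws$z,
                  burn_in = burn_in)
}

#' WHAM estimate of the potential of mean force
#'
#' @param windows List of [umbrella_window()]s.
#' @param bin_width Histogram bin width, A (default 0.1).
#' @param temperature Kelvin (default 310).
#' @param tolerance Convergence tolerance on the max change of any window
#'   shift f_j, kcal/mol (default 1e-6).
#' @param max_iter Iteration cap (default 1e5).
#' @param range Optional length-2 z range for the PMF grid; default the
#'   sample range.
#' @return Object of class `wham_result`: list with `pmf` (list `z`
#'   bin centers, `free_energy` kcal/mol anchored to min 0, `n_samples`
#'   per bin, `bin_width`, `gaps` flag vector for empty interior bins),
#'   `shifts`, `iterations`, `final_change`, `converged`,
#'   `overlap` (adjacent-window overlap matrix), `disconnected` flag.
#' @export
wham_pmf <- function(windows, bin_width = 0.1, temperature = 310,
                     tolerance = 1e-6, max_iter = 1e5, range = NULL) {
  stopifnot(length(windows) >= 1)
  ns <- vapply(windows, function(w) w$n_used, numeric(1))
  if (any(ns < 1)) stop("every window needs at least one sample")
  kT <- thermal_energy(temperature)
  beta <- 1 / kT
  allz <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(range)) range <- range(allz)
  edges <- seq(range[1], range[2] + bin_width, by = bin_width)
  mid <- edges[-length(edges)] + bin_width / 2
  nb <- length(mid)
  nw <- length(windows)
  counts <- vapply(windows, function(w) {
    h <- findInterval(w$samples, edges, rightmost.closed = FALSE)
    tabulate(h[h >= 1 & h <= nb], nbins = nb)
  }, numeric(nb))
  counts <- matrix(counts, nrow = nb)
  n_tot <- rowSums(counts)                    # n_i(z) summed over windows
  N_j <- colSums(counts)                      # samples per window in range
  # bias energies w_j(z) on the grid
  W <- vapply(seq_len(nw), function(j) {
    w <- windows[[j]]
    0.5 * w$force_constant * (mid - w$center)^2 + w$offset
  }, numeric(nb))
  W <- matrix(W, nrow = nb)
  expW <- exp(-beta * W)
  f <- numeric(nw)
  it <- 0L; change <- Inf
  covered <- n_tot > 0
  while (it < max_iter) {
    it <- it + 1L
    denom <- as.vector(expW %*% (N_j * exp(beta * f)))
    P <- ifelse(covered, n_tot / denom, 0)
    expnf <- as.vector(t(expW) %*% P)
    f_new <- -kT * log(expnf)
    f_new <- f_new - f_new[1]
    change <- max(abs(f_new - f))
    f <- f_new
    if (change < tolerance) break
  }
  denom <- as.vector(expW %*% (N_j * exp(beta * f)))
  P <- ifelse(covered, n_tot / denom, NA_real_)
  F_z <- -kT * log(P)
  F_z <- F_z - min(F_z, na.rm = TRUE)
  # gaps: empty bins strictly inside the covered range
  gaps <- !covered & seq_len(nb) > min(which(covered)) &
          seq_len(nb) < max(which(covered))
  ov <- window_overlap(windows, bin_width = bin_width, range = range)
  adj <- if (nw > 1) ov[cbind(1:(nw - 1), 2:nw)] else 1
  out <- list(
    pmf = structure(list(z = mid, free_energy = F_z, n_samples = n_tot,
                         bin_width = bin_width, gaps = gaps),
                    class = "pmf_profile"),
    shifts = f, iterations = it, final_change = change,
    converged = change < tolerance,
    overlap = ov, min_adjacent_overlap = min(adj),
    disconnected = any(gaps))
  class(out) <- "wham_result"
  out
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("WHAM: %d windows, %d bins, %d iterations (%sconverged)\n",
              length(x$shifts), length(x$pmf$z), x$iterations,
              if (x$converged) "" else "NOT "))
  cat(sprintf("min adjacent overlap %.3f%s\n", x$min_adjacent_overlap,
              if (x$disconnected) "; WARNING: coverage gaps" else ""))
  invisible(x)
}

#' Pairwise histogram overlap between windows
#'
#' Overlap(i, j) = sum_z min(p_i(z), p_j(z)) of the normalized window
#' histograms.
#'
#' @param windows List of [umbrella_window()]s.
#' @param bin_width Bin width, A.
#' @param range Optional shared histogram range.
#' @return Symmetric matrix in `[0, 1]`.
#' @export
window_overlap <- function(windows, bin_width = 0.1, range = NULL) {
  allz <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(range)) range <- range(allz)
  edges <- seq(range[1] - bin_width, range[2] + 2 * bin_width, by = bin_width)
  H <- vapply(windows, function(w) {
    h <- findInterval(w$samples, edges)
    h <- tabulate(h[h >= 1 & h <= length(edges) - 1], nbins = length(edges) - 1)
    if (sum(h) > 0) h / sum(h) else h
  }, numeric(length(edges) - 1))
  H <- matrix(H, ncol = length(windows))
  nw <- ncol(H)
  ov <- matrix(1, nw, nw)
  for (i in seq_len(nw)) for (j in seq_len(nw)) if (j > i) {
    ov[i, j] <- ov[j, i] <- sum(pmin(H[, i], H[, j]))
  }
  ov
}

#' Barrier heights out of binding sites
#'
#' For each site, the barrier is the maximum free energy between the
#' site's minimum and the next minimum (or grid boundary) on the inward
#' (-z) side, minus the site minimum.  A site whose free energy is
#' monotone (no well) gets `NA`, never 0.
#'
#' @param pmf A `pmf_profile` (from [wham_pmf()]`$pmf`) or a list with
#'   `z` and `free_energy`.
#' @param site_ranges Named list of z intervals, e.g.
#'   `list(A = c(21.5, 28), B = c(14, 21.5), C = c(5.5, 14))`.
#' @return data.frame with `site`, `barrier` (kcal/mol), `z_min`
#'   (site-minimum location), `z_top` (barrier-top location).
#' @export
barrier_heights <- function(pmf,
                            site_ranges = lapply(default_sites(), `[[`, "z_range")) {
  z <- pmf$z; Fv <- pmf$free_energy
  ok <- is.finite(Fv)
  z <- z[ok]; Fv <- Fv[ok]
  # outermost site first; each site's inward segment ends at the next
  # (inner) site's minimum, the innermost at the grid boundary --
  # the neighbouring basin IS the next inward minimum, and anchoring the
  # segment on the supplied ranges keeps the search robust to bin noise
  labs <- names(site_ranges)
  lo <- vapply(site_ranges, function(r) r[1], numeric(1))
  labs <- labs[order(-lo)]
  mins <- lapply(labs, function(lab) {
    rg <- site_ranges[[lab]]
    in_site <- which(z >= rg[1] & z <= rg[2])
    if (!length(in_site)) return(NA_integer_)
    in_site[which.min(Fv[in_site])]
  })
  names(mins) <- labs
  out <- lapply(seq_along(labs), function(si) {
    lab <- labs[si]
    i_min <- mins[[lab]]
    if (is.na(i_min))
      return(data.frame(site = lab, barrier = NA_real_,
                        z_min = NA_real_, z_top = NA_real_))
    i_stop <- 1L
    if (si < length(labs)) {
      nxt <- mins[[labs[si + 1]]]
      if (!is.na(nxt) && nxt < i_min) i_stop <- nxt
    }
    seg <- i_stop:i_min
    i_top <- seg[which.max(Fv[seg])]
    barrier <- Fv[i_top] - Fv[i_min]
    if (barrier < 1e-9 || i_top == i_min)
      return(data.frame(site = lab, barrier = NA_real_,
                        z_min = z[i_min], z_top = NA_real_))
    data.frame(site = lab, barrier = barrier, z_min = z[i_min],
               z_top = z[i_top])
  })
  df <- do.call(rbind, out)
  df <- df[match(names(site_ranges), df$site), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' PMF of the analytic single-ion potential on a grid (ground truth)
#'
#' @param pot A [channel_potential()].
#' @param z Grid, A.
#' @return Energies anchored to min 0, kcal/mol.
#' @export
analytic_pmf <- function(pot, z) {
  u <- single_ion_energy(pot, z)
  u - min(u)
}

#' Run a ladder of umbrella windows and assemble WHAM input
#'
#' @param pot A [channel_potential()].
#' @param centers Window centers, A (see [build_windows()]).
#' @param cfg A [sim_config()]; the seed is re-derived per window from
#'   `cfg$seed` so windows are independent but reproducible.
#' @param force_constant Tagged-ion bias, kcal/mol/A^2 (default 5).
#' @param extra_ion_positions,restraint_constant_extra Passed to
#'   [umbrella_spec()].
#' @param burn_in Burn-in fraction (default 0.3).
#' @return List of [umbrella_window()]s.
#' @export
run_umbrella_ladder <- function(pot, centers, cfg, force_constant = 5,
                                extra_ion_positions = numeric(0),
                                restraint_constant_extra = 2.5,
                                burn_in = 0.3) {
  lapply(seq_along(centers), function(i) {
    wcfg <- cfg
    wcfg$seed <- (cfg$seed * 1000L + i) %% .Machine$integer.max
    spec <- umbrella_spec(centers[i], force_constant,
                          extra_ion_positions, restraint_constant_extra)
    as_umbrella_window(simulate_umbrella_window(wcfg, pot, spec),
                       burn_in = burn_in)
  })
}
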