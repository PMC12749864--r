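# File I/O: extended-XYZ and TSV trajectory dialects, PDB structures
# (via bio3d), umbrella-window series and WHAM metadata files.
#
# Extended-XYZ dialect: per frame, a particle-count line, then a comment
# line `time_ns=<t> box=<Lx> <Ly> <Lz>` (optionally `seed=<s>`), then one
# line per particle: `species x y z`.
# TSV dialect: comment headers `# key=value`, then the columns
# `frame time_ns particle_id species x y z`.

#' Write a trajectory
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @param format `"xyz"` (extended XYZ) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "tsv")) {
  format <- match.arg(format)
  nf <- n_frames(traj); np <- n_particles(traj)
  con <- file(path, "w")
  on.exit(close(con))
  seed_tag <- if (!is.null(traj$seed)) paste0(" seed=", traj$seed) else ""
  if (format == "xyz") {
    for (f in seq_len(nf)) {
      writeLines(as.character(np), con)
      writeLines(sprintf("time_ns=%.9g box=%.9g %.9g %.9g%s",
                         traj$times_ns[f], traj$box[f, 1], traj$box[f, 2],
                         traj$box[f, 3], seed_tag), con)
      writeLines(sprintf("%s %.6f %.6f %.6f", traj$species,
                         traj$coords[f, , 1], traj$coords[f, , 2],
                         traj$coords[f, , 3]), con)
    }
  } else {
    writeLines(sprintf("# box=%.9g %.9g %.9g%s", traj$box[1, 1],
                       traj$box[1, 2], traj$box[1, 3], seed_tag), con)
    writeLines("frame\ttime_ns\tparticle_id\tspecies\tx\ty\tz", con)
    for (f in seq_len(nf)) {
      writeLines(sprintf("%d\t%.9g\t%d\t%s\t%.6f\t%.6f\t%.6f",
                         f, traj$times_ns[f], seq_len(np), traj$species,
                         traj$coords[f, , 1], traj$coords[f, , 2],
                         traj$coords[f, , 3]), con)
    }
  }
  invisible(path)
}

#' Read a trajectory
#'
#' Inverse of [write_trajectory()] for both dialects.  Malformed frames
#' (wrong particle count, non-monotone times, unparseable headers) are
#' rejected with the offending line/frame identified.
#'
#' @param path Input file.
#' @param format `"xyz"`, `"tsv"` or `"auto"` (by extension).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "xyz"
  lines <- readLines(path)
  if (format == "xyz") {
    i <- 1; frames <- list(); times <- numeric(); boxes <- list()
    species <- NULL; seed <- NULL
    while (i <= length(lines)) {
      if (!grepl("^\\s*\\d+\\s*$", lines[i]))
        stop("malformed particle-count header at line ", i)
      np <- as.integer(lines[i])
      hdr <- lines[i + 1]
      t <- suppressWarnings(
        as.numeric(sub(".*time_ns=([-0-9.eE+]+).*", "\\1", hdr)))
      bx <- strsplit(sub(".*box=([-0-9.eE+ ]+?)( [a-z_]+=.*)?$", "\\1", hdr),
                     "\\s+")[[1]]
      bx <- suppressWarnings(as.numeric(bx[nzchar(bx)]))
      if (is.na(t) || length(bx) != 3 || anyNA(bx))
        stop("malformed comment header at line ", i + 1)
      if (grepl("seed=", hdr))
        seed <- as.integer(sub(".*seed=(\\d+).*", "\\1", hdr))
      if (i + 1 + np > length(lines))
        stop("frame starting at line ", i, " is missing particle lines")
      body <- lines[(i + 2):(i + 1 + np)]
      parts <- strsplit(trimws(body), "\\s+")
      if (any(lengths(parts) < 4))
        stop("malformed atom line in frame starting at line ", i)
      sp <- vapply(parts, `[[`, character(1), 1)
      co <- suppressWarnings(
        t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))))
      if (anyNA(co)) stop("non-numeric coordinates in frame at line ", i)
      if (is.null(species)) species <- sp
      else if (!identical(sp, species))
        stop("inconsistent particle set in frame starting at line ", i)
      frames[[length(frames) + 1]] <- co
      times <- c(times, t); boxes[[length(boxes) + 1]] <- bx
      i <- i + 2 + np
    }
    if (!length(frames)) stop("no frames parsed from ", path)
    nf <- length(frames); np <- nrow(frames[[1]])
    coords <- array(NA_real_, c(nf, np, 3))
    for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
    if (any(diff(times) <= 0)) stop("frame times not strictly increasing")
    trajectory(coords, times, species, do.call(rbind, boxes), seed = seed)
  } else {
    hdr <- grep("^#", lines, value = TRUE)
    box <- c(30, 30, 60); seed <- NULL
    bh <- grep("box=", hdr, value = TRUE)
    if (length(bh))
      box <- as.numeric(strsplit(sub(".*box=", "", bh[1]), "\\s+")[[1]][1:3])
    sh <- grep("seed=", hdr, value = TRUE)
    if (length(sh)) seed <- as.integer(sub(".*seed=(\\d+).*", "\\1", sh[1]))
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", na.strings = "",
                            colClasses = c("integer", "numeric", "integer",
                                           "character", "numeric", "numeric",
                                           "numeric"))
    fr <- sort(unique(df$frame))
    np <- length(unique(df$particle_id))
    if (nrow(df) != length(fr) * np)
      stop("inconsistent particle count across frames (", nrow(df),
           " rows, ", length(fr), " frames x ", np, " particles)")
    df <- df[order(df$frame, df$particle_id), ]
    coords <- array(NA_real_, c(length(fr), np, 3))
    coords[, , 1] <- matrix(df$x, length(fr), np, byrow = TRUE)
    coords[, , 2] <- matrix(df$y, length(fr), np, byrow = TRUE)
    coords[, , 3] <- matrix(df$z, length(fr), np, byrow = TRUE)
    times <- df$time_ns[match(fr, df$frame)]
    if (any(diff(times) <= 0)) stop("frame times not strictly increasing")
    species <- df$species[df$frame == fr[1]]
    trajectory(coords, times, species, box, seed = seed)
  }
}

#' Read a static structure from PDB
#'
#' Parses ATOM/HETATM records via bio3d and assigns vdW radii from the
#' active radius table; unknown elements get the default radius with a
#' warning.  Occupancy and altLoc fields are ignored.
#'
#' @param path PDB file.
#' @param radii Optional named radius overrides (A), see [vdw_radius()].
#' @return An [atom_set()].
#' @export
read_structure <- function(path, radii = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!nrow(at)) stop("no atoms parsed from ", path)
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- substr(trimws(at$elety[bad]), 1, 1)
  elem <- toupper(trimws(elem))
  atom_set(elem, cbind(at$x, at$y, at$z),
           radii = vdw_radius(elem, radii = radii),
           label = basename(path))
}

#' Write umbrella-window samples and a WHAM metadata file
#'
#' Each window's samples go to a two-column TSV (`time_ns`, `z`) and the
#' metadata file lists one window per line:
#' `samples_path center force_constant` (the widespread WHAM metadata
#' layout).
#'
#' @param series List of `window_series` (from
#'   [simulate_umbrella_window()]).
#' @param dir Output directory.
#' @param meta_name Metadata filename (default "windows.meta").
#' @return Path of the metadata file.
#' @export
write_windows <- function(series, dir, meta_name = "windows.meta") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- file.path(dir, meta_name)
  rows <- character(length(series))
  for (i in seq_along(series)) {
    ws <- series[[i]]
    p <- file.path(dir, sprintf("window_%03d.tsv", i))
    con <- file(p, "w")
    writeLines(sprintf("# center=%g k=%g seed=%s", ws$spec$center,
                       ws$spec$force_constant, ws$seed), con)
    writeLines("time_ns\tz", con)
    writeLines(sprintf("%.9g\t%.6f", ws$time_ns, ws$z), con)
    close(con)
    rows[i] <- sprintf("%s %g %g", p, ws$spec$center, ws$spec$force_constant)
  }
  writeLines(rows, meta)
  meta
}

#' Read umbrella windows from a WHAM metadata file
#'
#' @param meta Metadata path (`samples_path center force_constant` per
#'   line; paths relative to the metadata file's directory are resolved).
#' @param burn_in Burn-in fraction applied to each series.
#' @return List of [umbrella_window()]s.
#' @export
read_windows <- function(meta, burn_in = 0.3) {
  rows <- strsplit(trimws(readLines(meta)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  lapply(rows, function(r) {
    p <- r[1]
    if (!file.exists(p)) p <- file.path(dirname(meta), basename(r[1]))
    df <- utils::read.table(p, header = TRUE, sep = "\t", comment.char = "#")
    umbrella_window(as.numeric(r[2]), as.numeric(r[3]), df$z,
                    burn_in = burn_in)
  })
}

#' Write a PMF profile as TSV
#'
#' Columns `z`, `free_energy_kcal_mol`, `n_samples`.
#' @param pmf A `pmf_profile`.
#' @param path Output file.
#' @export
write_pmf <- function(pmf, path) {
  df <- data.frame(z = pmf$z, free_energy_kcal_mol = pmf$free_energy,
                   n_samples = pmf$n_samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write permeation events as TSV
#'
#' @param events A [detect_permeations()] result.
#' @param path Output file.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
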