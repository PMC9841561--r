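#' Read a multi-frame (extended-)XYZ trajectory
#'
#' Extended-XYZ is the canonical on-disk dialect: each frame is an atom-count
#' line, a comment line of `key=value` pairs (including a `Properties=`
#' column map, optionally `Time=` in fs and `Lattice="..."`), and one line
#' per atom.  Velocity columns (`vel:R:3`) are parsed when present; for plain
#' XYZ files (positions only) velocities are reconstructed by central finite
#' differences on the positions (forward/backward one-sided differences at
#' the ends), which requires `timestep` when the file carries no `Time=`
#' keys.  Per-atom `mass:R:1` and `tags:S:1` columns are honoured; otherwise
#' masses come from `masses` or a small built-in element table and all atoms
#' are tagged adsorbate.
#'
#' Units are angstrom and angstrom/fs after applying the declared unit map:
#' the header keys `pos_unit` (`"A"`) and `vel_unit` (`"A/fs"` or `"A/ps"`)
#' or the `pos_scale`/`vel_scale` arguments.
#'
#' @param path file to read.
#' @param timestep frame spacing in fs, required for plain XYZ without
#'   `Time=` keys.
#' @param masses optional per-atom masses (amu) overriding file/element table.
#' @param tags optional per-atom role tags overriding the file.
#' @param pos_scale,vel_scale multiplicative unit conversions applied on read
#'   (defaults 1; overridden by recognised `pos_unit`/`vel_unit` header keys).
#' @param meta metadata list stored on the trajectory.
#' @return a [trajectory()].
#' @seealso [write_xyz_trajectory()]
#' @export
read_xyz_trajectory <- function(path, timestep = NULL, masses = NULL,
                                tags = NULL, pos_scale = 1, vel_scale = 1,
                                meta = list()) {
  frames <- parse_xyz_frames(path)
  n <- frames[[1]]$n
  for (f in frames) {
    if (f$n != n) stop("inconsistent atom counts across frames in ", path, call. = FALSE)
  }
  nt <- length(frames)

  # unit map from the first header
  h1 <- frames[[1]]$keys
  if (!is.null(h1$pos_unit) && h1$pos_unit != "A") {
    stop("unsupported pos_unit '", h1$pos_unit, "'", call. = FALSE)
  }
  if (!is.null(h1$vel_unit)) {
    vel_scale <- switch(h1$vel_unit, "A/fs" = 1, "A/ps" = 1e-3,
                        stop("unsupported vel_unit '", h1$vel_unit, "'", call. = FALSE))
  }

  times <- vapply(frames, function(f) {
    if (is.null(f$keys$Time)) NA_real_ else as.numeric(f$keys$Time)
  }, numeric(1))
  if (anyNA(times)) {
    if (is.null(timestep)) {
      stop("file has no Time= keys; a timestep must be supplied", call. = FALSE)
    }
    times <- (seq_len(nt) - 1) * timestep
  }

  pos <- array(NA_real_, c(n, 3, nt))
  vel <- array(NA_real_, c(n, 3, nt))
  has_vel <- !is.null(frames[[1]]$vel)
  for (k in seq_len(nt)) {
    pos[, , k] <- frames[[k]]$pos * pos_scale
    if (has_vel) vel[, , k] <- frames[[k]]$vel * vel_scale
  }
  if (!has_vel) {
    if (nt < 2) stop("need >= 2 frames to reconstruct velocities", call. = FALSE)
    vel <- central_difference_velocities(pos, times)
  }

  sym <- frames[[1]]$symbols
  if (is.null(masses)) {
    masses <- if (!is.null(frames[[1]]$mass)) frames[[1]]$mass else element_masses(sym)
  }
  if (is.null(tags)) {
    tags <- if (!is.null(frames[[1]]$tags)) frames[[1]]$tags else rep("adsorbate", n)
  }
  cell <- if (!is.null(h1$Lattice)) {
    matrix(as.numeric(strsplit(trimws(h1$Lattice), "\\s+")[[1]]), 3, 3, byrow = TRUE)
  }
  sys <- atomic_system(sym, masses, matrix(pos[, , 1], ncol = 3),
                       cell = cell, tags = tags)
  for (key in c("seed", "h_m", "h_s", "kick_energy")) {
    if (!is.null(h1[[key]]) && is.null(meta[[key]])) meta[[key]] <- as.numeric(h1[[key]])
  }
  trajectory(sys, times, pos, vel, meta = meta)
}

# 2nd-order finite-difference velocities on a constant time grid
central_difference_velocities <- function(pos, times) {
  nt <- length(times)
  dt <- times[2] - times[1]
  vel <- array(NA_real_, dim(pos))
  vel[, , 1] <- (pos[, , 2] - pos[, , 1]) / dt
  vel[, , nt] <- (pos[, , nt] - pos[, , nt - 1]) / dt
  if (nt > 2) {
    for (k in 2:(nt - 1)) vel[, , k] <- (pos[, , k + 1] - pos[, , k - 1]) / (2 * dt)
  }
  vel
}

# split a (extended-)XYZ file into frames with parsed headers
parse_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("malformed XYZ: expected atom count at line ", i, call. = FALSE)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i, call. = FALSE)
    keys <- parse_xyz_comment(lines[i + 1L])
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol <- length(toks[[1]])
    if (any(vapply(toks, length, integer(1)) != ncol)) {
      stop("ragged atom lines in XYZ frame at line ", i, call. = FALSE)
    }
    cols <- xyz_column_map(keys$Properties, ncol)
    tab <- do.call(rbind, toks)
    num <- function(ix) {
      m <- matrix(as.numeric(tab[, ix, drop = FALSE]), nrow = n)
      if (anyNA(m)) stop("non-numeric field in XYZ frame at line ", i, call. = FALSE)
      m
    }
    frames[[length(frames) + 1L]] <- list(
      n = n, keys = keys,
      symbols = tab[, cols$species],
      pos = num(cols$pos),
      vel = if (!is.null(cols$vel)) num(cols$vel),
      mass = if (!is.null(cols$mass)) as.numeric(num(cols$mass)),
      tags = if (!is.null(cols$tags)) tab[, cols$tags]
    )
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  frames
}

# key=value comment line; values may be double-quoted
parse_xyz_comment <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|[^\\s]+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (j in seq_along(m)) {
    piece <- substr(line, m[j], m[j] + attr(m, "match.length")[j] - 1)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- substr(piece, 1, eq - 1)
    val <- substr(piece, eq + 1, nchar(piece))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

# resolve the Properties= column layout; fall back to classic XYZ layouts
xyz_column_map <- function(properties, ncol) {
  if (!is.null(properties)) {
    specs <- strsplit(properties, ":")[[1]]
    if (length(specs) %% 3 != 0) stop("malformed Properties string", call. = FALSE)
    names_ <- specs[seq(1, length(specs), 3)]
    widths <- as.integer(specs[seq(3, length(specs), 3)])
    start <- cumsum(c(1L, widths))[seq_along(widths)]
    cols <- stats::setNames(
      lapply(seq_along(names_), function(j) start[j]:(start[j] + widths[j] - 1L)),
      names_
    )
    return(list(species = cols[["species"]][1], pos = cols[["pos"]],
                vel = cols[["vel"]], mass = cols[["mass"]][1], tags = cols[["tags"]][1]))
  }
  if (ncol >= 7) return(list(species = 1L, pos = 2:4, vel = 5:7))
  if (ncol >= 4) return(list(species = 1L, pos = 2:4, vel = NULL))
  stop("cannot interpret XYZ columns (", ncol, " fields)", call. = FALSE)
}

#' Write a trajectory as extended-XYZ with velocities
#'
#' Full double precision (`%.17g`) so that a write/read round trip is
#' bit-exact on positions and velocities.  Per-atom mass and tag columns and
#' per-frame `Time=` keys are always written; handedness metadata is recorded
#' in the header of every frame.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  sys <- traj$system
  n <- n_atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  lattice <- if (!is.null(sys$cell)) {
    sprintf(' Lattice="%s"', paste(sprintf("%.17g", t(sys$cell)), collapse = " "))
  } else ""
  meta_keys <- ""
  for (key in c("seed", "h_m", "h_s", "kick_energy")) {
    if (!is.null(traj$meta[[key]]) && is.finite(traj$meta[[key]])) {
      meta_keys <- paste0(meta_keys, sprintf(" %s=%.17g", key, as.numeric(traj$meta[[key]])))
    }
  }
  for (k in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Properties=species:S:1:pos:R:3:vel:R:3:mass:R:1:tags:S:1 Time=%.17g pos_unit=A vel_unit=A/fs%s%s',
      traj$times[k], lattice, meta_keys), con)
    p <- traj$positions[, , k, drop = FALSE]
    v <- traj$velocities[, , k, drop = FALSE]
    writeLines(sprintf("%-3s %.17g %.17g %.17g %.17g %.17g %.17g %.17g %s",
                       sys$symbols, p[, 1, 1], p[, 2, 1], p[, 3, 1],
                       v[, 1, 1], v[, 2, 1], v[, 3, 1], sys$masses, sys$tags), con)
  }
  invisible(path)
}

#' Read or write a trajectory ensemble (extended-XYZ + JSON sidecar)
#'
#' An ensemble is stored as `<stem>.xyz` (all trajectories concatenated) plus
#' `<stem>.json` recording the label, frames per trajectory and per-trajectory
#' metadata, so the concatenated file can be split back losslessly.
#'
#' @param ens an [ensemble()].
#' @param stem path without extension.
#' @return `write_ensemble()` returns `stem` invisibly; `read_ensemble()`
#'   returns the [ensemble()].
#' @export
write_ensemble <- function(ens, stem) {
  stopifnot(inherits(ens, "ensemble"))
  xyz <- paste0(stem, ".xyz")
  unlink(xyz)
  tmp <- tempfile(fileext = ".xyz")
  out <- file(xyz, "w")
  on.exit(close(out))
  for (tr in ens$trajectories) {
    write_xyz_trajectory(tr, tmp)
    writeLines(readLines(tmp), out)
  }
  unlink(tmp)
  sidecar <- list(
    label = ens$label,
    n_trajectories = length(ens),
    n_frames = if (length(ens)) n_frames(ens$trajectories[[1]]) else 0L,
    meta = lapply(ens$trajectories, function(tr) tr$meta)
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  frames <- parse_xyz_frames(paste0(stem, ".xyz"))
  nf <- side$n_frames
  ntraj <- side$n_trajectories
  if (length(frames) != nf * ntraj) {
    stop("ensemble file does not match its sidecar frame count", call. = FALSE)
  }
  # round-trip through a temporary per-trajectory file keeps one code path
  trajs <- vector("list", ntraj)
  tmp <- tempfile(fileext = ".xyz")
  lines <- readLines(paste0(stem, ".xyz"))
  n <- frames[[1]]$n
  block <- (n + 2L) * nf
  for (i in seq_len(ntraj)) {
    writeLines(lines[((i - 1L) * block + 1L):(i * block)], tmp)
    meta <- if (is.data.frame(side$meta)) as.list(side$meta[i, ]) else side$meta[[i]]
    trajs[[i]] <- read_xyz_trajectory(tmp, meta = meta)
  }
  unlink(tmp)
  ensemble(trajs, label = if (is.null(side$label)) "" else side$label)
}

#' Read a Cartesian Hessian matrix from whitespace-delimited text
#'
#' @param path file containing a square 3N x 3N matrix in eV/angstrom^2.
#' @param n_atoms expected atom count N.
#' @param warn_asymmetry warn when the max asymmetry exceeds this (eV/A^2).
#' @return the symmetrised matrix \eqn{(H + H^T)/2} with attribute
#'   `"max_asymmetry"` recording \eqn{\max|H - H^T|}.
#' @export
read_hessian <- function(path, n_atoms, warn_asymmetry = 1e-6) {
  vals <- scan(path, quiet = TRUE)
  side <- 3L * as.integer(n_atoms)
  if (length(vals) != side^2) {
    stop("Hessian file has ", length(vals), " entries; expected ", side, "^2",
         call. = FALSE)
  }
  H <- matrix(vals, side, side, byrow = TRUE)
  asym <- max(abs(H - t(H)))
  if (asym > warn_asymmetry) {
    warning(sprintf("Hessian asymmetry %.3g eV/A^2; symmetrising", asym), call. = FALSE)
  }
  Hs <- (H + t(H)) / 2
  attr(Hs, "max_asymmetry") <- asym
  Hs
}

#' @rdname read_hessian
#' @param hessian matrix to write.
#' @export
write_hessian <- function(hessian, path) {
  con <- file(path, "w")
  on.exit(close(con))
  apply(hessian, 1, function(row) {
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con)
  })
  invisible(path)
}

# minimal element mass table (amu) for files without a mass column
element_masses <- function(symbols) {
  tab <- c(H = 1.008, D = 2.014, He = 4.0026, C = 12.011, N = 14.007,
           O = 15.999, S = 32.06, Cu = 63.546, X = 1)
  m <- tab[symbols]
  if (anyNA(m)) {
    stop("no built-in mass for element(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "),
         "; supply `masses`", call. = FALSE)
  }
  unname(m)
}
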