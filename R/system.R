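#' Atomic system with surface/adsorbate role tags
#'
#' The shared structural container.  Coordinates are Cartesian angstrom in a
#' right-handed frame whose z axis is the outward surface normal (the surface
#' top sits at the maximum z of the surface-tagged atoms, or at a configured
#' plane when the surface is implicit).  Each atom carries a role tag:
#' `"adsorbate"` (the desorbing molecule), `"surface"` (substrate atoms, held
#' fixed by the integrator), or `"transferring_h"` (the hydrogen left behind
#' at the surface during dissociative desorption, tracked separately by the
#' distance marker).
#'
#' @param symbols character vector of element labels.
#' @param masses atomic masses in amu, one per atom, all positive.
#' @param positions numeric N x 3 matrix of Cartesian coordinates (angstrom).
#' @param cell optional 3 x 3 matrix of lattice vectors (angstrom rows);
#'   `NULL` for a gas-phase / implicit-surface system.
#' @param tags character vector of per-atom roles, each one of
#'   `"adsorbate"`, `"surface"`, `"transferring_h"`.  Defaults to all
#'   adsorbate.
#' @return an object of class `atomic_system`.
#' @examples
#' sys <- atomic_system(c("C", "H"), c(12.011, 1.008),
#'                      rbind(c(0, 0, 2), c(0, 0, 3.1)))
#' n_atoms(sys)
#' @export
atomic_system <- function(symbols, masses, positions, cell = NULL,
                          tags = rep("adsorbate", length(symbols))) {
  positions <- as_xyz_matrix(positions)
  n <- nrow(positions)
  stopifnot(length(symbols) == n, length(masses) == n, length(tags) == n)
  if (!all(is.finite(masses)) || any(masses <= 0)) {
    stop("all atomic masses must be finite and > 0", call. = FALSE)
  }
  if (!all(is.finite(positions))) stop("positions must be finite", call. = FALSE)
  bad <- setdiff(unique(tags), c("adsorbate", "surface", "transferring_h"))
  if (length(bad)) {
    stop("unknown atom tags: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!any(tags == "adsorbate")) {
    stop("system must contain at least one adsorbate-tagged atom", call. = FALSE)
  }
  if (!is.null(cell)) {
    cell <- matrix(as.numeric(cell), 3, 3)
    if (!all(is.finite(cell))) stop("cell must be finite", call. = FALSE)
  }
  structure(
    list(symbols = as.character(symbols), masses = as.numeric(masses),
         positions = positions, cell = cell, tags = as.character(tags)),
    class = "atomic_system"
  )
}

#' @rdname atomic_system
#' @param x an object.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.atomic_system <- function(x) nrow(x$positions)

#' @export
n_atoms.trajectory <- function(x) nrow(x$system$positions)

#' @export
print.atomic_system <- function(x, ...) {
  cat("<atomic_system> ", n_atoms(x), " atoms (",
      paste(sprintf("%s:%d", names(table(x$tags)), table(x$tags)), collapse = ", "),
      ")", if (is.null(x$cell)) " gas phase" else " periodic", "\n", sep = "")
  invisible(x)
}

# coerce to an N x 3 numeric matrix
as_xyz_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinate arrays must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# logical mask of atoms selected by tag filter; subset = "all" selects all
tag_mask <- function(system, subset = "adsorbate", exclude = character()) {
  m <- if (identical(subset, "all")) rep(TRUE, n_atoms(system)) else system$tags %in% subset
  m & !(system$tags %in% exclude)
}

#' Trajectory: time-ordered frames of positions and velocities
#'
#' Frames are stored as N x 3 x T arrays (atom, Cartesian component, frame).
#' Frame times must be strictly increasing on a constant grid with at least
#' two frames.  The `meta` list carries provenance: RNG `seed`, molecular
#' handedness `h_m` and surface handedness `h_s` (each +1/-1, `NA` when
#' unknown), and the translational `kick_energy` in eV.
#'
#' @param system an [atomic_system()].
#' @param times numeric vector of frame times in fs, strictly increasing with
#'   constant step.
#' @param positions N x 3 x T array, angstrom.
#' @param velocities N x 3 x T array, angstrom/fs.
#' @param meta named list of metadata (`seed`, `h_m`, `h_s`, `kick_energy`, ...).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(system, times, positions, velocities, meta = list()) {
  stopifnot(inherits(system, "atomic_system"))
  times <- as.numeric(times)
  nt <- length(times)
  if (nt < 2) stop("a trajectory needs at least 2 frames", call. = FALSE)
  if (any(times < 0)) stop("frame times must be >= 0", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("frame times must lie on a constant grid", call. = FALSE)
  }
  n <- n_atoms(system)
  positions <- as_frame_array(positions, n, nt, "positions")
  velocities <- as_frame_array(velocities, n, nt, "velocities")
  structure(
    list(system = system, times = times, positions = positions,
         velocities = velocities, meta = meta),
    class = "trajectory"
  )
}

as_frame_array <- function(a, n, nt, what) {
  a <- as.array(a)
  if (length(dim(a)) != 3 || dim(a)[1] != n || dim(a)[2] != 3 || dim(a)[3] != nt) {
    stop(what, " must be an ", n, " x 3 x ", nt, " array", call. = FALSE)
  }
  storage.mode(a) <- "double"
  a
}

#' @rdname trajectory
#' @param x an object.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.trajectory <- function(x) length(x$times)

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_atoms(x), " atoms x ", n_frames(x), " frames, t = ",
      x$times[1], " .. ", x$times[n_frames(x)], " fs", sep = "")
  if (!is.null(x$meta$h_m)) cat(sprintf("  [h_m=%+d h_s=%+d]", x$meta$h_m, x$meta$h_s))
  cat("\n")
  invisible(x)
}

# timestep of a trajectory (fs)
traj_dt <- function(traj) traj$times[2] - traj$times[1]

#' Ensemble of trajectories sharing one topology and time grid
#'
#' @param trajectories list of [trajectory()] objects with identical atom
#'   counts, tags and frame times.
#' @param label free-text ensemble label.
#' @return an object of class `ensemble` (a list with elements
#'   `trajectories` and `label`).
#' @export
ensemble <- function(trajectories, label = "") {
  stopifnot(is.list(trajectories))
  if (length(trajectories)) {
    ok <- vapply(trajectories, inherits, logical(1), "trajectory")
    if (!all(ok)) stop("all elements must be trajectory objects", call. = FALSE)
    ref <- trajectories[[1]]
    for (tr in trajectories[-1]) {
      if (n_atoms(tr) != n_atoms(ref) || !identical(tr$system$tags, ref$system$tags)) {
        stop("ensemble trajectories disagree in atom count or tags", call. = FALSE)
      }
      if (n_frames(tr) != n_frames(ref) ||
          max(abs(tr$times - ref$times)) > 1e-9 * max(1, max(ref$times))) {
        stop("ensemble trajectories disagree in time grid", call. = FALSE)
      }
    }
  }
  structure(list(trajectories = trajectories, label = label), class = "ensemble")
}

#' @export
length.ensemble <- function(x) length(x$trajectories)

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", length(x), " trajectories",
      if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  invisible(x)
}

#' Per-trajectory metadata of an ensemble
#'
#' @param ens an [ensemble()].
#' @return a tibble with one row per trajectory: `trajectory_id`, `seed`,
#'   `h_m`, `h_s`, `kick_energy` (columns absent from the metadata are `NA`).
#' @export
ensemble_meta <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  pull_meta <- function(tr, key) {
    v <- tr$meta[[key]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  tibble::tibble(
    trajectory_id = seq_along(ens$trajectories),
    seed = vapply(ens$trajectories, pull_meta, numeric(1), "seed"),
    h_m = vapply(ens$trajectories, pull_meta, numeric(1), "h_m"),
    h_s = vapply(ens$trajectories, pull_meta, numeric(1), "h_s"),
    kick_energy = vapply(ens$trajectories, pull_meta, numeric(1), "kick_energy")
  )
}
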