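#' Centre-of-mass position and velocity time series
#'
#' Mass-weighted COM over a tagged atom subset, per frame.
#'
#' @param traj a [trajectory()].
#' @param subset tag filter: a character vector of tags or `"all"`.
#' @param exclude tags to drop from the subset.
#' @return a tibble with columns `time`, `x`, `y`, `z`, `vx`, `vy`, `vz`
#'   (angstrom, angstrom/fs).
#' @export
com_series <- function(traj, subset = "adsorbate", exclude = character()) {
  stopifnot(inherits(traj, "trajectory"))
  mask <- tag_mask(traj$system, subset, exclude)
  if (!any(mask)) stop("tag subset selects no atoms", call. = FALSE)
  m <- traj$system$masses[mask]
  M <- sum(m)
  nt <- n_frames(traj)
  out <- matrix(NA_real_, nt, 6)
  for (k in seq_len(nt)) {
    out[k, 1:3] <- colSums(traj$positions[mask, , k, drop = FALSE] * m) / M
    out[k, 4:6] <- colSums(traj$velocities[mask, , k, drop = FALSE] * m) / M
  }
  tibble::tibble(time = traj$times, x = out[, 1], y = out[, 2], z = out[, 3],
                 vx = out[, 4], vy = out[, 5], vz = out[, 6])
}

#' Distance of a marker atom from the surface top
#'
#' Tracks the tagged atom (by default the transferring hydrogen left behind
#' during dissociative desorption) relative to either the topmost
#' surface-tagged atom of each frame or a fixed reference plane, and reports
#' the first (linearly interpolated) crossing of a threshold distance.  The
#' 4 angstrom default follows the common marker for the reassociating
#' hydrogen clearing the substrate.
#'
#' @param traj a [trajectory()].
#' @param marker_tag tag identifying exactly one marker atom.
#' @param reference `"surface_top"` (needs surface-tagged atoms) or
#'   `"plane"` (distance is the height above `z0`).
#' @param z0 reference plane height for `reference = "plane"`, angstrom.
#' @param threshold crossing distance to report, angstrom.
#' @return a tibble with columns `time`, `distance`; attribute
#'   `"crossing_time"` holds the interpolated first crossing (fs) or `NA`.
#' @export
marker_distance_series <- function(traj, marker_tag = "transferring_h",
                                   reference = c("surface_top", "plane"),
                                   z0 = 0, threshold = 4) {
  stopifnot(inherits(traj, "trajectory"))
  reference <- match.arg(reference)
  idx <- which(traj$system$tags == marker_tag)
  if (length(idx) != 1) {
    stop("need exactly one '", marker_tag, "' atom; found ", length(idx),
         call. = FALSE)
  }
  nt <- n_frames(traj)
  surf <- traj$system$tags == "surface"
  if (reference == "surface_top" && !any(surf)) {
    stop("reference 'surface_top' needs surface-tagged atoms; use 'plane'",
         call. = FALSE)
  }
  d <- numeric(nt)
  for (k in seq_len(nt)) {
    mp <- traj$positions[idx, , k]
    if (reference == "surface_top") {
      zs <- traj$positions[surf, 3, k]
      top <- which.max(zs)
      sp <- traj$positions[which(surf)[top], , k]
      d[k] <- sqrt(sum((mp - sp)^2))
    } else {
      d[k] <- mp[3] - z0
    }
  }
  out <- tibble::tibble(time = traj$times, distance = d)
  attr(out, "crossing_time") <- first_crossing_time(traj$times, d, threshold)
  out
}

#' First upward threshold crossing, linearly interpolated
#'
#' @param time,values numeric vectors of equal length.
#' @param threshold crossing level.
#' @return interpolated crossing time, or `NA` if `values` never reaches
#'   `threshold` (a series starting at or above the threshold crosses at
#'   `time[1]`).
#' @export
first_crossing_time <- function(time, values, threshold) {
  if (values[1] >= threshold) return(time[1])
  above <- which(values >= threshold)
  if (!length(above)) return(NA_real_)
  k <- above[1]
  frac <- (threshold - values[k - 1]) / (values[k] - values[k - 1])
  time[k - 1] + frac * (time[k] - time[k - 1])
}

#' Detect full desorption of the adsorbate
#'
#' A trajectory counts as desorbed when the adsorbate COM height above the
#' surface reference exceeds `z_threshold` continuously over the final
#' `persistence` fs \emph{and} the final COM z-velocity is positive (moving
#' away).  The persistence window guards against transient bounces.
#' `desorption_time` is the (interpolated) entry into the terminal
#' exceedance run.  COM speeds are reported in m/s (1 A/fs = 1e5 m/s); both
#' the full speed and the z-component are given because either convention
#' may be meant by a "mean velocity of desorbing molecules".
#'
#' @param traj a [trajectory()].
#' @param z_threshold COM height above the reference that counts as free,
#'   angstrom.
#' @param persistence length of the terminal window that must stay above
#'   the threshold, fs.
#' @param z0 surface reference height when no surface atoms are present,
#'   angstrom.
#' @param marker_threshold threshold for the transferring-H marker time,
#'   angstrom (reported when a marker atom exists).
#' @return a one-row tibble: `desorbed`, `desorption_time` (fs or `NA`),
#'   `final_com_speed_ms`, `final_com_vz_ms`, `marker_time_4A` (fs or `NA`).
#' @export
detect_desorption <- function(traj, z_threshold = 6, persistence = 20,
                              z0 = 0, marker_threshold = 4) {
  stopifnot(inherits(traj, "trajectory"), z_threshold > 0, persistence > 0)
  span <- traj$times[n_frames(traj)] - traj$times[1]
  if (span < persistence) {
    stop("trajectory (", span, " fs) shorter than the persistence window",
         call. = FALSE)
  }
  com <- com_series(traj, "adsorbate")
  surf <- traj$system$tags == "surface"
  zref <- if (any(surf)) {
    vapply(seq_len(n_frames(traj)),
           function(k) max(traj$positions[surf, 3, k]), numeric(1))
  } else z0
  h <- com$z - zref
  t_end <- com$time[length(com$time)]
  window <- com$time >= t_end - persistence
  desorbed <- all(h[window] > z_threshold) && com$vz[length(com$vz)] > 0

  desorption_time <- NA_real_
  if (desorbed) {
    below <- which(h <= z_threshold)
    if (!length(below)) {
      desorption_time <- com$time[1]
    } else {
      k <- max(below)   # last frame at/below threshold; run starts after it
      frac <- (z_threshold - h[k]) / (h[k + 1] - h[k])
      desorption_time <- com$time[k] + frac * (com$time[k + 1] - com$time[k])
    }
  }

  marker_time <- NA_real_
  if (any(traj$system$tags == "transferring_h")) {
    ref <- if (any(surf)) "surface_top" else "plane"
    md <- marker_distance_series(traj, reference = ref, z0 = z0,
                                 threshold = marker_threshold)
    marker_time <- attr(md, "crossing_time")
  }

  nlast <- length(com$time)
  tibble::tibble(
    desorbed = desorbed,
    desorption_time = desorption_time,
    final_com_speed_ms = sqrt(com$vx[nlast]^2 + com$vy[nlast]^2 + com$vz[nlast]^2) * .ms_per_Afs,
    final_com_vz_ms = com$vz[nlast] * .ms_per_Afs,
    marker_time_4A = marker_time
  )
}

#' Desorption records for every trajectory of an ensemble
#'
#' @param ens an [ensemble()].
#' @param ... passed to [detect_desorption()].
#' @return a tibble, one row per trajectory, binding [ensemble_meta()] with
#'   the [detect_desorption()] record.
#' @export
desorption_records <- function(ens, ...) {
  stopifnot(inherits(ens, "ensemble"))
  recs <- purrr::map(ens$trajectories, detect_desorption, ...)
  dplyr::bind_cols(ensemble_meta(ens), dplyr::bind_rows(recs))
}

#' Keep only the desorbing trajectories of an ensemble
#'
#' @inheritParams desorption_records
#' @return the filtered [ensemble()]; attribute `"records"` holds the full
#'   desorption table.  Emits a message with retained/discarded counts and a
#'   warning when nothing desorbs (the empty ensemble is still returned).
#' @export
filter_desorbed <- function(ens, ...) {
  recs <- desorption_records(ens, ...)
  keep <- recs$desorbed
  message("filter_desorbed: retained ", sum(keep), " of ", length(keep),
          " trajectories")
  if (!any(keep)) warning("no trajectory satisfies the desorption criterion",
                          call. = FALSE)
  out <- ensemble(ens$trajectories[keep], label = ens$label)
  attr(out, "records") <- recs
  out
}
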