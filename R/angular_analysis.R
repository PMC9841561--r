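#' Angular-momentum time series about the subset centre of mass
#'
#' Per frame, the intrinsic angular momentum of the tagged subset,
#' \deqn{\mathbf{L} = \sum_i m_i\,(\mathbf{r}_i - \mathbf{R})\times
#'   (\mathbf{v}_i - \mathbf{V}),}
#' with \eqn{\mathbf{R}, \mathbf{V}} the instantaneous COM position and
#' velocity of the same subset, so the series is invariant under a Galilean
#' boost and independent of the lab origin.  Values are reported in atomic
#' units (1 au = \eqn{\hbar}; 1 amu A^2/fs = 157.46 au).  By default the
#' transferring hydrogen is excluded: the desorbing molecule is analysed
#' while the H stays behind at the surface.
#'
#' @param traj a [trajectory()].
#' @param subset tag filter (character vector of tags, or `"all"`).
#' @param exclude tags excluded from the subset.
#' @param trajectory_id identifier copied into the output.
#' @return a tibble with columns `time` (fs), `Lx`, `Ly`, `Lz`, `Lmag` (au),
#'   `trajectory_id`, `h_m`, `h_s` (handedness from the trajectory metadata,
#'   `NA` when absent).
#' @export
angular_momentum_series <- function(traj, subset = "adsorbate",
                                    exclude = "transferring_h",
                                    trajectory_id = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  mask <- tag_mask(traj$system, subset, exclude)
  if (sum(mask) < 2) {
    stop("angular momentum needs >= 2 atoms in the subset", call. = FALSE)
  }
  m <- traj$system$masses[mask]
  M <- sum(m)
  nt <- n_frames(traj)
  L <- matrix(NA_real_, nt, 3)
  for (k in seq_len(nt)) {
    r <- traj$positions[, , k][mask, , drop = FALSE]
    v <- traj$velocities[, , k][mask, , drop = FALSE]
    R <- colSums(r * m) / M
    V <- colSums(v * m) / M
    dr <- sweep(r, 2, R)
    dv <- sweep(v, 2, V)
    # sum_i m_i (dr_i x dv_i), expanded by component
    L[k, 1] <- sum(m * (dr[, 2] * dv[, 3] - dr[, 3] * dv[, 2]))
    L[k, 2] <- sum(m * (dr[, 3] * dv[, 1] - dr[, 1] * dv[, 3]))
    L[k, 3] <- sum(m * (dr[, 1] * dv[, 2] - dr[, 2] * dv[, 1]))
  }
  L <- L * .au_per_amuA2fs
  meta_num <- function(key) {
    v <- traj$meta[[key]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  tibble::tibble(
    time = traj$times,
    Lx = L[, 1], Ly = L[, 2], Lz = L[, 3],
    Lmag = sqrt(rowSums(L^2)),
    trajectory_id = trajectory_id,
    h_m = meta_num("h_m"), h_s = meta_num("h_s")
  )
}

#' Angular-momentum series for every trajectory of an ensemble
#'
#' @param ens an [ensemble()].
#' @param ... passed to [angular_momentum_series()].
#' @return the row-bound tibble of per-trajectory series, with
#'   `trajectory_id` numbering the ensemble order.
#' @export
angular_momentum_ensemble <- function(ens, ...) {
  stopifnot(inherits(ens, "ensemble"))
  purrr::list_rbind(purrr::imap(
    ens$trajectories,
    function(tr, i) angular_momentum_series(tr, trajectory_id = i, ...)
  ))
}

#' z-component of an angular-momentum table
#'
#' The z-component is the only component of \eqn{\mathbf{L}} unique to a
#' chiral adsorbate/surface pair: under a vertical mirror plane the
#' pseudovector component parallel to the plane (\eqn{L_z}) changes sign,
#' so achiral systems average it to zero.
#'
#' @param L_tbl a tibble from [angular_momentum_series()] /
#'   [angular_momentum_ensemble()].
#' @return the tibble reduced to `time`, `Lz`, `trajectory_id`, `h_m`, `h_s`.
#' @export
lz_series <- function(L_tbl) {
  dplyr::select(L_tbl, dplyr::any_of(c("time", "Lz", "trajectory_id", "h_m", "h_s")))
}

#' Ensemble mean and dispersion of |L| or Lz over time
#'
#' Per-frame mean and sample standard deviation, optionally within groups
#' (e.g. sign subpopulations); the ungrouped overall mean is always included
#' as group `"all"`.
#'
#' @param L_tbl stacked per-trajectory angular-momentum tibble.
#' @param component `"Lmag"` or `"Lz"`.
#' @param groups optional named vector/list mapping `trajectory_id` to a
#'   group label.
#' @return a tibble with columns `group`, `time`, `mean`, `sd`, `n`.
#' @export
ensemble_mean_series <- function(L_tbl, component = c("Lmag", "Lz"),
                                 groups = NULL) {
  component <- match.arg(component)
  if (!nrow(L_tbl)) stop("empty angular-momentum table", call. = FALSE)
  base <- dplyr::tibble(time = L_tbl$time, value = L_tbl[[component]],
                        trajectory_id = L_tbl$trajectory_id)
  summarise_grp <- function(df, label) {
    dplyr::summarise(
      dplyr::group_by(df, .data$time),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |> dplyr::mutate(group = label, .before = 1)
  }
  out <- summarise_grp(base, "all")
  if (!is.null(groups)) {
    lab <- unlist(groups)[as.character(base$trajectory_id)]
    for (g in unique(stats::na.omit(lab))) {
      out <- dplyr::bind_rows(out, summarise_grp(base[lab == g & !is.na(lab), ], g))
    }
  }
  out
}

#' Percent growth of the ensemble-mean |L| over the simulation
#'
#' \eqn{100\,(\bar L(t_\mathrm{end}) - \bar L(t_0)) / \bar L(t_0)} with
#' \eqn{\bar L} the per-frame ensemble mean of \eqn{|\mathbf{L}|}; the
#' baseline is the first recorded frame (configurable via `t0`).
#'
#' @param L_tbl stacked per-trajectory angular-momentum tibble.
#' @param t0 baseline time, fs; defaults to the first frame.
#' @return a one-row tibble: `percent_change`, `L_start`, `L_end` (au),
#'   `n` trajectories.
#' @export
magnitude_growth <- function(L_tbl, t0 = NULL) {
  if (!nrow(L_tbl)) stop("empty angular-momentum table", call. = FALSE)
  mean_series <- ensemble_mean_series(L_tbl, "Lmag")
  mean_series <- mean_series[mean_series$group == "all", ]
  if (is.null(t0)) t0 <- min(mean_series$time)
  i0 <- which.min(abs(mean_series$time - t0))
  L0 <- mean_series$mean[i0]
  Lend <- mean_series$mean[nrow(mean_series)]
  if (L0 <= 0) stop("zero ensemble-mean |L| at the baseline frame", call. = FALSE)
  tibble::tibble(
    percent_change = 100 * (Lend - L0) / L0,
    L_start = L0, L_end = Lend,
    n = mean_series$n[1]
  )
}

#' Mean angle between individual L vectors and the ensemble mean
#'
#' At each probe time, the angle between each trajectory's
#' \eqn{\mathbf{L}_i} and the ensemble-mean vector
#' \eqn{\bar{\mathbf{L}}}, averaged over trajectories (unweighted
#' directions).  A narrowing spread over time signals increasingly directed
#' rotation.  Zero-magnitude individual vectors are skipped and counted;
#' a zero ensemble-mean vector makes the angle undefined at that time
#' (`NA`).
#'
#' @param L_tbl stacked per-trajectory angular-momentum tibble (>= 2
#'   trajectories).
#' @param times probe times, fs; each is matched to the nearest frame.
#' @return a tibble with columns `time` (the matched frame time),
#'   `mean_angle_deg`, `n_used`, `n_skipped`.
#' @export
spread_angle_series <- function(L_tbl, times = NULL) {
  ids <- unique(L_tbl$trajectory_id)
  if (length(ids) < 2) stop("spread angle needs >= 2 trajectories", call. = FALSE)
  frame_times <- sort(unique(L_tbl$time))
  if (is.null(times)) times <- frame_times
  probe <- vapply(times, function(t) frame_times[which.min(abs(frame_times - t))],
                  numeric(1))
  out <- purrr::map(unique(probe), function(tt) {
    sub <- L_tbl[L_tbl$time == tt, c("Lx", "Ly", "Lz")]
    V <- as.matrix(sub)
    vbar <- colMeans(V)
    nb <- sqrt(sum(vbar^2))
    ni <- sqrt(rowSums(V^2))
    skip <- ni == 0
    if (nb == 0) {
      return(tibble::tibble(time = tt, mean_angle_deg = NA_real_,
                            n_used = 0L, n_skipped = sum(skip)))
    }
    cosang <- pmin(1, pmax(-1, (V[!skip, , drop = FALSE] %*% vbar) / (ni[!skip] * nb)))
    tibble::tibble(time = tt,
                   mean_angle_deg = mean(acos(cosang)) * 180 / pi,
                   n_used = sum(!skip), n_skipped = sum(skip))
  })
  purrr::list_rbind(out)
}

#' Per-trajectory Lz summary statistic
#'
#' The classification statistic used for sign subpopulations: by default the
#' mean \eqn{L_z} over the final half of the frames (robust to terminal
#' oscillation); `"final_frame"` uses the last frame only.
#'
#' @param L_tbl stacked per-trajectory angular-momentum tibble.
#' @param window `"final_half"` or `"final_frame"`.
#' @return a tibble with columns `trajectory_id`, `lz_stat` (au), `h_m`,
#'   `h_s`.
#' @export
traj_lz_statistic <- function(L_tbl, window = c("final_half", "final_frame")) {
  window <- match.arg(window)
  t_end <- max(L_tbl$time)
  t_cut <- if (window == "final_half") (min(L_tbl$time) + t_end) / 2 else t_end
  dplyr::summarise(
    dplyr::group_by(L_tbl[L_tbl$time >= t_cut, ], .data$trajectory_id),
    lz_stat = mean(.data$Lz),
    h_m = .data$h_m[1], h_s = .data$h_s[1],
    .groups = "drop"
  )
}
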