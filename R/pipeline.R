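#' Assemble and validate a pipeline run configuration
#'
#' Bundles every knob of the simulate -> desorb-filter -> analyze -> stats
#' chain.  Validation happens here, before any computation.  Per-trajectory
#' seeds are expanded deterministically from `master_seed` (a fixed-stride
#' counter scheme, recorded in the report), so a configuration reproduces
#' its ensemble bit for bit.
#'
#' @param n_traj trajectories per ensemble.
#' @param temperature_K sampling temperature, kelvin.
#' @param kick_energy_eV translational kick; `NULL` = 1.2 x D per adsorbate
#'   atom.
#' @param dt_fs,n_steps,stride integration schedule (defaults 0.5 fs x 400).
#' @param master_seed integer; expanded into per-trajectory seeds unless
#'   `seeds` is given explicitly.
#' @param seeds optional explicit integer vector, one per trajectory.
#' @param h_m,h_s molecular and surface handedness of the simulated pair.
#' @param potential named list of [chiral_params()] overrides.
#' @param molecule named list of [build_toy_system()] overrides (`n_atoms`,
#'   `com_height`, `seed`, `bond_k`).
#' @param sampling_scheme see [sample_initial_velocities()].
#' @param z_threshold desorption height criterion; `NULL` = `z_e + 4`
#'   (where the Morse tail is below 2 percent of D).
#' @param persistence desorption persistence window, fs.
#' @param probe_times spread-angle probe times; `NULL` = 10, 30 and 100
#'   percent of the trajectory length (20/60/200 fs at the default
#'   schedule).
#' @param lz_window classification window for [traj_lz_statistic()].
#' @param n_boot bootstrap replicates for the mixture goodness of fit;
#'   0 skips the (slow) bootstrap.
#' @param stats_seed seed for mixture fitting and bootstrap.
#' @param ensemble_file optional stem of a stored ensemble
#'   ([write_ensemble()]); when set, simulation is skipped and the file is
#'   analysed instead.
#' @param out_dir optional output directory for report and tables.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(n_traj = 48, temperature_K = 300, kick_energy_eV = NULL,
                       dt_fs = 0.5, n_steps = 400, stride = 1,
                       master_seed = 1, seeds = NULL, h_m = 1, h_s = 1,
                       potential = list(), molecule = list(),
                       sampling_scheme = "total_energy_phase",
                       z_threshold = NULL, persistence = 20,
                       probe_times = NULL, lz_window = "final_half",
                       n_boot = 0, stats_seed = 1,
                       ensemble_file = NULL, out_dir = NULL) {
  stopifnot(n_traj >= 1, temperature_K >= 0, dt_fs > 0, n_steps >= 1,
            persistence > 0, n_boot >= 0)
  if (!h_m %in% c(-1, 1) || !h_s %in% c(-1, 1)) {
    stop("h_m and h_s must be +1 or -1", call. = FALSE)
  }
  if (!is.null(kick_energy_eV) && kick_energy_eV < 0) {
    stop("kick_energy_eV must be >= 0", call. = FALSE)
  }
  if (is.null(seeds)) seeds <- expand_seeds(master_seed, n_traj)
  if (length(seeds) != n_traj) stop("need one seed per trajectory", call. = FALSE)
  pot <- do.call(chiral_params, c(potential, list(h_s = h_s)))
  if (is.null(z_threshold)) z_threshold <- pot$z_e + 4
  cfg <- list(
    n_traj = n_traj, temperature_K = temperature_K,
    kick_energy_eV = kick_energy_eV, dt_fs = dt_fs, n_steps = n_steps,
    stride = stride, master_seed = as.integer(master_seed),
    seeds = as.integer(seeds), h_m = h_m, h_s = h_s,
    potential = potential, molecule = molecule,
    sampling_scheme = sampling_scheme, z_threshold = z_threshold,
    persistence = persistence, probe_times = probe_times,
    lz_window = lz_window, n_boot = n_boot,
    stats_seed = as.integer(stats_seed),
    ensemble_file = ensemble_file, out_dir = out_dir
  )
  structure(cfg, class = "run_config")
}

# deterministic per-trajectory seed expansion; keeps seeds in 32-bit range
expand_seeds <- function(master_seed, n) {
  as.integer((as.numeric(master_seed) + 104729 * seq_len(n)) %% 2147483629 + 1)
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys are [run_config()] arguments.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, raw)
}

#' Run the full desorption-analysis pipeline
#'
#' Simulate (or ingest) an ensemble, filter to desorbing trajectories,
#' compute angular-momentum series and ensemble statistics, fit the Lz sign
#' subpopulations and the two-component Gaussian mixture, and assemble a
#' machine-readable report.  With an empty post-filter ensemble the report
#' is still emitted with the analysis fields absent.
#'
#' @param config a [run_config()].
#' @return an object of class `chirodyn_report`: a list with `config`,
#'   `desorption` (per-trajectory table), `L` (per-trajectory angular
#'   momentum series), `growth`, `spread_angles`, `lz_stats`,
#'   `subpopulations`, `mixture` (tidy parameters or `NULL`), `cvm`
#'   (`NULL` unless `n_boot > 0`), `folded_modality`, `decision`,
#'   `n_desorbed`, `version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pot <- do.call(chiral_params, c(config$potential, list(h_s = config$h_s)))
  if (is.null(config$ensemble_file)) {
    mol <- do.call(build_toy_system, c(config$molecule, list(h_m = config$h_m)))
    ens <- generate_ensemble(
      pot, mol, n_traj = config$n_traj, temperature = config$temperature_K,
      kick_energy = config$kick_energy_eV, seeds = config$seeds,
      dt = config$dt_fs, n_steps = config$n_steps, stride = config$stride,
      scheme = config$sampling_scheme,
      label = sprintf("h_m=%+d h_s=%+d", config$h_m, config$h_s)
    )
  } else {
    ens <- read_ensemble(config$ensemble_file)
  }

  desorption <- desorption_records(ens, z_threshold = config$z_threshold,
                                   persistence = config$persistence)
  keep <- desorption$desorbed
  report <- list(config = unclass(config), desorption = desorption,
                 n_desorbed = sum(keep),
                 version = as.character(utils::packageVersion("chirodyn")))
  class(report) <- "chirodyn_report"
  if (!sum(keep)) {
    warning("no desorbing trajectories; analysis fields absent", call. = FALSE)
    write_report_outputs(report, config$out_dir)
    return(report)
  }
  sub_ens <- ensemble(ens$trajectories[keep], label = ens$label)

  L <- angular_momentum_ensemble(sub_ens)
  report$L <- L
  report$growth <- magnitude_growth(L)
  t_end <- max(L$time)
  probes <- if (is.null(config$probe_times)) c(0.1, 0.3, 1.0) * t_end else
    config$probe_times
  report$spread_angles <- if (length(unique(L$trajectory_id)) >= 2) {
    spread_angle_series(L, probes)
  }
  lz <- traj_lz_statistic(L, window = config$lz_window)
  report$lz_stats <- lz
  split <- split_subpopulations(lz$lz_stat)
  report$subpopulations <- attr(split, "group_stats")
  report$mean_series <- ensemble_mean_series(
    L, "Lz", groups = stats::setNames(split$label, lz$trajectory_id))

  fit <- tryCatch(
    fit_gaussian_mixture(lz$lz_stat, seed = config$stats_seed),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    report$mixture <- tidy(fit)
    report$mixture_glance <- glance(fit)
    folded <- folded_abs_distribution(fit)
    report$folded_modality <- attr(folded, "modality")
    if (config$n_boot > 0) {
      report$cvm <- tryCatch(
        cvm_pvalue(fit, n_boot = config$n_boot, seed = config$stats_seed),
        error = function(e) tibble::tibble(error = conditionMessage(e))
      )
    }
  }
  report$decision <- lz_decision(lz$lz_stat)
  write_report_outputs(report, config$out_dir)
  report
}

# decision rule on the per-trajectory Lz statistics: directed rotation when
# the ensemble mean is resolved at 2 standard errors of the mean
lz_decision <- function(lz_stat) {
  n <- length(lz_stat)
  m <- mean(lz_stat)
  sem <- if (n > 1) stats::sd(lz_stat) / sqrt(n) else Inf
  n_pos <- sum(lz_stat >= 0)
  tibble::tibble(
    n = n, mean_lz = m, sem = sem,
    label = if (abs(m) > 2 * sem) "directed rotation" else "no net preference",
    majority_sign = if (n_pos >= n / 2) "positive" else "negative",
    majority_frac = max(n_pos, n - n_pos) / n,
    sign_balance_p = stats::binom.test(n_pos, n)$p.value
  )
}

write_report_outputs <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    report_to_json(report), file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  utils::write.csv(report$desorption, file.path(out_dir, "desorption.csv"),
                   row.names = FALSE)
  if (!is.null(report$L)) {
    utils::write.csv(report$L, file.path(out_dir, "angular_momentum.csv"),
                     row.names = FALSE)
  }
  invisible()
}

report_to_json <- function(report) {
  drop <- c("L")   # bulky table goes to CSV, not JSON
  out <- report[setdiff(names(report), drop)]
  lapply(out, function(x) if (inherits(x, "tbl_df")) as.data.frame(x) else x)
}

#' @export
print.chirodyn_report <- function(x, ...) {
  cat("<chirodyn_report> ", x$n_desorbed, "/", nrow(x$desorption),
      " trajectories desorbed\n", sep = "")
  if (!is.null(x$growth)) {
    cat(sprintf("  |L| growth: %+.1f%% (%.1f -> %.1f au)\n",
                x$growth$percent_change, x$growth$L_start, x$growth$L_end))
  }
  if (!is.null(x$decision)) {
    cat(sprintf("  Lz: mean %+.2f au (SEM %.2f) -> %s (%.0f%% %s)\n",
                x$decision$mean_lz, x$decision$sem, x$decision$label,
                100 * x$decision$majority_frac, x$decision$majority_sign))
  }
  if (!is.null(x$folded_modality)) {
    cat("  folded |Lz| distribution:", x$folded_modality, "\n")
  }
  invisible(x)
}

#' Side-by-side diastereomer comparison with a mirror consistency check
#'
#' Runs the pipeline for the matched (`h_m = +1`) and mismatched
#' (`h_m = -1`) molecule on the same surface with the \emph{same} seed list,
#' then re-runs the mismatched molecule on the mirrored surface
#' (`h_m = -1, h_s = -1`), which must reproduce the matched run with every
#' Lz-derived quantity exactly negated (pseudovector transformation).
#'
#' @param config a [run_config()]; its `h_m`/`h_s` are overridden.
#' @return a list of class `diastereomer_comparison`: reports `matched`,
#'   `mismatched`, `mirror`, a `comparison` tibble, and
#'   `mirror_max_deviation` (au).
#' @export
compare_diastereomers <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg_m <- config; cfg_m$h_m <- 1;  cfg_m$h_s <- 1;  cfg_m$out_dir <- NULL
  cfg_x <- config; cfg_x$h_m <- -1; cfg_x$h_s <- 1;  cfg_x$out_dir <- NULL
  cfg_r <- config; cfg_r$h_m <- -1; cfg_r$h_s <- -1; cfg_r$out_dir <- NULL
  # mirroring the surface means mirroring the full parameter set
  pot_m <- do.call(chiral_params, c(config$potential, list(h_s = 1)))
  pot_r <- mirror_reflect(pot_m, "xz")
  cfg_r$potential <- config$potential
  cfg_r$potential$phi0 <- pot_r$phi0
  cfg_r$potential$axis_xy <- pot_r$axis_xy

  rep_m <- run_pipeline(cfg_m)
  rep_x <- run_pipeline(cfg_x)
  rep_r <- run_pipeline(cfg_r)

  mirror_dev <- if (!is.null(rep_m$L) && !is.null(rep_r$L) &&
                    nrow(rep_m$L) == nrow(rep_r$L)) {
    max(abs(rep_m$L$Lz + rep_r$L$Lz))
  } else NA_real_

  row <- function(rep, which) tibble::tibble(
    ensemble = which,
    n_desorbed = rep$n_desorbed,
    growth_pct = if (!is.null(rep$growth)) rep$growth$percent_change else NA_real_,
    mean_lz = if (!is.null(rep$decision)) rep$decision$mean_lz else NA_real_,
    sem = if (!is.null(rep$decision)) rep$decision$sem else NA_real_,
    label = if (!is.null(rep$decision)) rep$decision$label else NA_character_,
    majority_frac = if (!is.null(rep$decision)) rep$decision$majority_frac else NA_real_,
    sign_balance_p = if (!is.null(rep$decision)) rep$decision$sign_balance_p else NA_real_,
    folded_modality = if (!is.null(rep$folded_modality)) rep$folded_modality else NA_character_
  )
  structure(
    list(matched = rep_m, mismatched = rep_x, mirror = rep_r,
         comparison = dplyr::bind_rows(
           row(rep_m, "matched"), row(rep_x, "mismatched"),
           row(rep_r, "mirror_of_matched")),
         mirror_max_deviation = mirror_dev),
    class = "diastereomer_comparison"
  )
}

#' @export
print.diastereomer_comparison <- function(x, ...) {
  cat("<diastereomer_comparison>\n")
  print(x$comparison)
  cat("mirror-pair max |Lz_matched + Lz_mirror| =", x$mirror_max_deviation,
      "au\n")
  invisible(x)
}
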