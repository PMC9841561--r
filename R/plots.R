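#' Plot per-trajectory |L| or Lz with the ensemble mean band
#'
#' Spaghetti of individual trajectories with the ensemble mean (red) and a
#' one-standard-deviation band (gray), the standard way these ensembles are
#' displayed.
#'
#' @param L_tbl stacked angular-momentum tibble
#'   ([angular_momentum_ensemble()]).
#' @param component `"Lmag"` or `"Lz"`.
#' @return a ggplot object.
#' @export
plot_angular_momentum <- function(L_tbl, component = c("Lmag", "Lz")) {
  component <- match.arg(component)
  ms <- ensemble_mean_series(L_tbl, component)
  ms <- ms[ms$group == "all", ]
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = L_tbl,
      ggplot2::aes(.data$time, .data[[component]], group = .data$trajectory_id),
      linewidth = 0.2, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_ribbon(
      data = ms,
      ggplot2::aes(.data$time, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(data = ms, ggplot2::aes(.data$time, .data$mean),
                       colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "time (fs)",
      y = if (component == "Lmag") "|L| (au)" else expression(L[z] ~ "(au)")) +
    ggplot2::theme_minimal()
}

#' Histogram of Lz values with the fitted mixture overlaid
#'
#' Freedman-Diaconis bins (seed-independent) with the two-component
#' Gaussian fit drawn on top.
#'
#' @param values Lz statistics, au.
#' @param fit optional [fit_gaussian_mixture()] result.
#' @return a ggplot object.
#' @export
plot_lz_distribution <- function(values, fit = NULL) {
  df <- tibble::tibble(value = as.numeric(values))
  bw <- 2 * stats::IQR(df$value) / length(df$value)^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(df$value)) / 10
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = bw, fill = "grey75", colour = "grey30") +
    ggplot2::labs(x = expression(L[z] ~ "(au)"), y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(df$value) - bw, max(df$value) + bw, length.out = 400)
    gg <- gg + ggplot2::geom_line(
      data = tibble::tibble(x = xs, y = mixture_density(fit, xs)),
      ggplot2::aes(.data$x, .data$y), colour = "red", linewidth = 0.8)
  }
  gg
}

#' @rdname tidy.gaussian_mixture_fit
#' @param object a `gaussian_mixture_fit`.
#' @export
autoplot.gaussian_mixture_fit <- function(object, ...) {
  plot_lz_distribution(object$data, object)
}

#' Plot the folded |Lz| density
#'
#' @param fit a [fit_gaussian_mixture()] result.
#' @param grid optional non-negative grid, see [folded_abs_distribution()].
#' @return a ggplot object, annotated with the modality classification.
#' @export
plot_folded_distribution <- function(fit, grid = NULL) {
  folded <- folded_abs_distribution(fit, grid)
  ggplot2::ggplot(folded, ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_line(colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = expression("|" * L[z] * "| (au)"), y = "density",
                  subtitle = paste("folded shape:", attr(folded, "modality"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
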