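#' Stacked-bar chart of locality classes through time
#'
#' One bar per scenario x date, stacked by threshold class — the standard
#' overview of how localities redistribute across classes as the climate
#' scenarios advance.
#'
#' @param table Classification counts (`scenario_id, date, class, count`),
#'   e.g. from [tabulate_localities()] or [arabica_reference_counts()].
#' @return A ggplot object.
#' @export
plot_locality_classes <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$date, y = .data$count,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario_id), nrow = 1) +
    ggplot2::scale_fill_manual(values = c(
      unsuitable = "grey70", marginal = "#d73027",
      intermediate = "#fee08b", optimal = "#1a9850")) +
    ggplot2::labs(x = NULL, y = "localities", fill = "class") +
    ggplot2::theme_minimal()
}

#' Histograms of locality scores per scenario and date
#'
#' 40 equal bins on \[0, 1\], with the three threshold cutoffs drawn as
#' dashed lines — shows the fine-scale shifts around the cutoffs that a
#' class count hides.
#'
#' @param trajectories Trajectory table from [tabulate_localities()].
#' @param thresholds Optional [derive_thresholds()] result for cutoff
#'   lines.
#' @return A ggplot object.
#' @export
plot_score_histograms <- function(trajectories, thresholds = NULL) {
  p <- ggplot2::ggplot(trajectories, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = 41),
                            fill = "grey40") +
    ggplot2::facet_grid(ggplot2::vars(.data$date),
                        ggplot2::vars(.data$scenario_id)) +
    ggplot2::labs(x = "logistic suitability", y = "localities") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    cuts <- c(thresholds$tau_optimal, thresholds$tau_intermediate,
              thresholds$tau_marginal)
    p <- p + ggplot2::geom_vline(xintercept = cuts, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Percent change of cumulative suitable area
#'
#' @param cumulative The `cumulative` table from [compute_area_change()].
#' @return A ggplot object.
#' @export
plot_area_change <- function(cumulative) {
  dat <- dplyr::filter(cumulative, .data$scenario_id != "baseline")
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$date,
                               y = .data$pct_change_vs_baseline,
                               group = .data$level,
                               colour = .data$level)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario_id), nrow = 1) +
    ggplot2::labs(x = NULL, y = "% change vs baseline",
                  colour = "threshold level") +
    ggplot2::theme_minimal()
}

#' Map a suitability or class surface
#'
#' @param surface A matrix on `spec` (suitability scores or class codes).
#' @param spec The [grid_spec()].
#' @param localities Optional tibble with `lon`, `lat` to overlay.
#' @return A ggplot object.
#' @export
plot_surface <- function(surface, spec, localities = NULL) {
  df <- as_tibble.clim_stack(
    clim_stack(list(value = surface), spec, "temperature"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(localities)) {
    p <- p + ggplot2::geom_point(
      data = localities, ggplot2::aes(.data$lon, .data$lat),
      inherit.aes = FALSE, size = 0.6, colour = "black")
  }
  p
}

#' Response curves for every model variable
#'
#' @param model A `maxent_model`.
#' @param background_env Background environments.
#' @param n_points Sweep resolution per variable.
#' @return A ggplot object.
#' @export
plot_response_curves <- function(model, background_env, n_points = 100) {
  curves <- purrr::map_dfr(model$feature_set$vars, function(v) {
    response_curve(model, background_env, v, n_points)
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$value, .data$response)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "logistic suitability") +
    ggplot2::theme_minimal()
}
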