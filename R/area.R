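#' Reclassify suitability surfaces with the no-migration rule
#'
#' Converts each projected surface into a per-cell class grid using the
#' threshold set, then applies the no-gain mask: any cell unsuitable at
#' baseline is forced unsuitable at every future date, because natural
#' range extension by dispersal and colonisation is treated as
#' negligible. With `ratchet = TRUE` a stricter exclusivity rule also
#' applies within each scenario: a cell's class at a later date can never
#' improve on its class at any earlier date, even if its score recovers.
#' Cells that are nodata at baseline are masked everywhere.
#'
#' @param projections Output of [project_scenarios()], baseline included
#'   (`scenario_id == "baseline"`); dates must be ordered within each
#'   scenario.
#' @param thresholds A [derive_thresholds()] result.
#' @param ratchet Apply the within-scenario exclusivity rule.
#' @return A tibble `scenario_id, date, class_grid` where each class grid
#'   is an integer matrix coded 0 unsuitable, 1 marginal,
#'   2 intermediate, 3 optimal, `NA` masked.
#' @export
reclassify_surfaces <- function(projections, thresholds, ratchet = FALSE) {
  base_row <- projections$scenario_id == "baseline"
  if (!any(base_row)) stop("baseline projection required", call. = FALSE)
  base_surface <- projections$surface[[which(base_row)[1]]]
  to_codes <- function(surface) {
    cls <- classify_scores(pmax(as.vector(surface), 0), thresholds)
    m <- matrix(as.integer(cls) - 1L, nrow(surface), ncol(surface))
    m[is.na(surface)] <- NA_integer_
    m
  }
  base_codes <- to_codes(base_surface)
  out <- projections |>
    dplyr::mutate(order_key = suppressWarnings(as.numeric(.data$date))) |>
    dplyr::arrange(.data$scenario_id, .data$order_key)
  if (any(is.na(out$order_key))) {
    stop("sequencing error: dates must be numeric-ordered labels",
         call. = FALSE)
  }
  grids <- vector("list", nrow(out))
  prev_by_scenario <- list()
  for (i in seq_len(nrow(out))) {
    g <- to_codes(out$surface[[i]])
    g[is.na(base_codes)] <- NA_integer_
    if (out$scenario_id[i] != "baseline") {
      g[base_codes == 0L] <- 0L                  # no-gain mask
      if (ratchet) {
        prev <- prev_by_scenario[[out$scenario_id[i]]]
        if (!is.null(prev)) g <- pmin(g, prev)
        prev_by_scenario[[out$scenario_id[i]]] <- g
      }
    }
    grids[[i]] <- g
  }
  tibble::tibble(scenario_id = out$scenario_id, date = out$date,
                 class_grid = grids)
}

#' Per-cell area of a geographic grid
#'
#' Cell area in km^2 from the cell size at each row's center latitude:
#' `(111.320 * cos(lat) * cell) * (110.574 * cell)`.
#'
#' @param spec A [grid_spec()].
#' @return Numeric vector of length `n_rows` (north to south).
#' @export
cell_area_km2 <- function(spec) {
  lat <- cell_centers(spec)$lat
  111.320 * cos(lat * pi / 180) * spec$cell_size * 110.574 * spec$cell_size
}

#' Class areas and percent change versus baseline
#'
#' For every scenario x date class grid: the area in each disjoint class,
#' the cumulative areas at the optimal / intermediate / marginal levels
#' (optimal; optimal+intermediate; all suitable), and the percent change
#' of each cumulative area relative to the baseline cumulative area at
#' the same level. Relative change is the meaningful quantity for a
#' clipped study region; absolute areas are reported but depend on the
#' extent chosen.
#'
#' @param class_grids Output of [reclassify_surfaces()].
#' @param spec The shared [grid_spec()].
#' @return A tibble per scenario x date x level: `area_km2` (disjoint),
#'   `cum_area_km2`, `pct_change_vs_baseline`.
#' @export
compute_area_change <- function(class_grids, spec) {
  areas <- cell_area_km2(spec)
  class_names <- c("unsuitable", "marginal", "intermediate", "optimal")
  per <- purrr::pmap_dfr(class_grids, function(scenario_id, date,
                                               class_grid) {
    row_area <- matrix(rep(areas, ncol(class_grid)), nrow(class_grid))
    by_class <- vapply(0:3, function(code) {
      sum(row_area[!is.na(class_grid) & class_grid == code])
    }, numeric(1))
    tibble::tibble(scenario_id = scenario_id, date = date,
                   class = factor(class_names, levels = class_names,
                                  ordered = TRUE),
                   area_km2 = by_class)
  })
  cum <- per |>
    dplyr::group_by(.data$scenario_id, .data$date) |>
    dplyr::reframe(
      level = c("optimal", "intermediate", "marginal"),
      cum_area_km2 = c(
        sum(.data$area_km2[.data$class == "optimal"]),
        sum(.data$area_km2[.data$class %in% c("optimal", "intermediate")]),
        sum(.data$area_km2[.data$class != "unsuitable"])
      )
    )
  base <- cum |>
    dplyr::filter(.data$scenario_id == "baseline") |>
    dplyr::select("level", base_area = "cum_area_km2")
  cum <- cum |>
    dplyr::left_join(base, by = "level") |>
    dplyr::mutate(pct_change_vs_baseline =
                    100 * (.data$cum_area_km2 - .data$base_area) /
                    .data$base_area) |>
    dplyr::select(-"base_area")
  list(by_class = per, cumulative = cum)
}
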