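#' Project a fitted model onto scenario stacks
#'
#' Produces one logistic suitability surface per scenario x date,
#' baseline included. Variables outside the training bounds are clamped
#' by the feature expansion (no extrapolation).
#'
#' @param model A `maxent_model`.
#' @param stacks Named list of [clim_stack()]s; names `"scenario_date"`
#'   or provide `scenario_date` as a two-column tibble via `meta`.
#' @param meta Optional tibble with `name`, `scenario_id`, `date` rows
#'   matching `stacks`; by default names are split on the last `_`.
#' @return A tibble of projections: `scenario_id`, `date`, `surface`
#'   (list of matrices).
#' @export
project_scenarios <- function(model, stacks, meta = NULL) {
  stopifnot(is.list(stacks), !is.null(names(stacks)))
  if (is.null(meta)) {
    parts <- strsplit(names(stacks), "_(?=[^_]+$)", perl = TRUE)
    meta <- tibble::tibble(
      name = names(stacks),
      scenario_id = vapply(parts, `[`, "", 1),
      date = vapply(parts, `[`, "", 2)
    )
  }
  surfaces <- purrr::map(stacks, function(st) {
    predict_surface(model, st, type = "logistic")
  })
  tibble::tibble(scenario_id = meta$scenario_id, date = meta$date,
                 surface = unname(surfaces))
}

#' Classify localities across scenario projections
#'
#' Looks up each locality's logistic score on every projected surface
#' (nearest-cell-center), classifies it with the threshold set, and
#' returns both the per-locality trajectory table and the classification
#' table of disjoint class counts per scenario x date. Localities falling
#' on nodata cells are flagged, excluded from the counts, and reported.
#'
#' @param localities Tibble with `locality_id`, `lon`, `lat`.
#' @param projections Output of [project_scenarios()].
#' @param thresholds A [derive_thresholds()] result.
#' @param spec The shared [grid_spec()].
#' @return A list: `trajectories` (locality x scenario x date scores and
#'   classes), `table` (class counts per column), `flagged`
#'   (locality ids on nodata).
#' @export
tabulate_localities <- function(localities, projections, thresholds,
                                spec) {
  located <- locate_cells(localities, spec)
  if (anyNA(located$row)) {
    stop("localities outside grid extent", call. = FALSE)
  }
  idx <- cbind(located$row, located$col)
  traj <- purrr::pmap_dfr(projections, function(scenario_id, date,
                                                surface) {
    sc <- surface[idx]
    tibble::tibble(locality_id = localities$locality_id,
                   scenario_id = scenario_id, date = date, score = sc)
  })
  flagged <- unique(traj$locality_id[is.na(traj$score)])
  traj <- dplyr::mutate(traj,
                        class = classify_scores(pmax(.data$score, 0),
                                                thresholds))
  counted <- traj |>
    dplyr::filter(!.data$locality_id %in% flagged) |>
    dplyr::count(.data$scenario_id, .data$date, .data$class,
                 .drop = FALSE, name = "count")
  list(trajectories = traj, table = counted, flagged = flagged)
}

#' Summarise a classification table
#'
#' Suitable remainder and unsuitable percentage per scenario x date.
#'
#' @param table Classification counts from [tabulate_localities()] (or
#'   [arabica_reference_counts()]).
#' @return A tibble per scenario x date: `n`, `suitable`, `unsuitable`,
#'   `pct_unsuitable`.
#' @export
summarise_classes <- function(table) {
  table |>
    dplyr::group_by(.data$scenario_id, .data$date) |>
    dplyr::summarise(
      n = sum(.data$count),
      suitable = sum(.data$count[.data$class != "unsuitable"]),
      unsuitable = sum(.data$count[.data$class == "unsuitable"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_unsuitable = 100 * .data$unsuitable / .data$n)
}
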