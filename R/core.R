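#' Score locality persistence across all scenarios and dates
#'
#' A locality's viability total is the sum of its logistic scores across
#' every projected surface, baseline included; localities with
#' consistently high predictions sit in bioclimatic space expected to
#' stay near-optimal, and are candidate in-situ conservation refugia
#' ("core localities"). The standard deviation across the same surfaces
#' measures how changeable each locality's environment is. Core status is
#' the top `core_fraction` by total, ties broken by lower standard
#' deviation, then by locality id.
#'
#' @param trajectories Trajectory table from [tabulate_localities()].
#' @param core_fraction Fraction flagged as core (default 0.1, an
#'   interpretation — no published numeric criterion exists).
#' @return A tibble per locality: `total`, `mean_score`, `std_dev`,
#'   `n_surfaces`, `rank`, `is_core`, ordered by rank.
#' @export
score_core <- function(trajectories, core_fraction = 0.1) {
  n_surfaces <- dplyr::n_distinct(paste(trajectories$scenario_id,
                                        trajectories$date))
  counts <- dplyr::count(trajectories, .data$locality_id)
  if (any(counts$n != n_surfaces) || anyNA(trajectories$score)) {
    stop("completeness error: every locality needs a score on every surface",
         call. = FALSE)
  }
  scores <- trajectories |>
    dplyr::group_by(.data$locality_id) |>
    dplyr::summarise(total = sum(.data$score),
                     mean_score = mean(.data$score),
                     std_dev = stats::sd(.data$score),
                     n_surfaces = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$std_dev,
                   .data$locality_id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  is_core = .data$rank <=
                    max(1L, round(core_fraction * dplyr::n())))
  scores
}

#' Point-in-polygon overlay against protected areas
#'
#' Even-odd ray-casting test of each locality against each polygon;
#' points on a boundary count as inside. Reports, per locality, whether
#' it falls inside any protected area, per-polygon counts of core
#' localities, and the gap list of core localities outside all polygons.
#'
#' @param core_scores Output of [score_core()].
#' @param localities Tibble with `locality_id`, `lon`, `lat`.
#' @param polygons A list of polygons, each a matrix / data frame with
#'   columns `lon`, `lat` (closed or open ring), optionally named; or a
#'   path handled by [read_geojson_polygons()].
#' @return A list: `localities` (with `inside`, `polygon`), `by_polygon`
#'   (core counts), `gap` (core localities outside all polygons).
#' @export
overlay_protected <- function(core_scores, localities, polygons) {
  if (is.character(polygons)) polygons <- read_geojson_polygons(polygons)
  if (is.null(names(polygons)) || any(names(polygons) == "")) {
    names(polygons) <- paste0("polygon_", seq_along(polygons))
  }
  polygons <- lapply(names(polygons), function(nm) {
    p <- as.data.frame(polygons[[nm]])
    if (!all(c("lon", "lat") %in% names(p))) {
      names(p)[1:2] <- c("lon", "lat")
    }
    if (nrow(p) < 3) stop("invalid polygon: ", nm, call. = FALSE)
    # drop a closing vertex if present; ring closure is implicit
    if (p$lon[1] == p$lon[nrow(p)] && p$lat[1] == p$lat[nrow(p)]) {
      p <- p[-nrow(p), ]
    }
    if (nrow(p) < 3) stop("invalid polygon: ", nm, call. = FALSE)
    p
  }) |> stats::setNames(names(polygons))

  hit <- vapply(seq_len(nrow(localities)), function(i) {
    for (nm in names(polygons)) {
      if (point_in_polygon(localities$lon[i], localities$lat[i],
                           polygons[[nm]])) {
        return(nm)
      }
    }
    NA_character_
  }, character(1))
  loc <- dplyr::mutate(
    dplyr::left_join(localities,
                     dplyr::select(core_scores, "locality_id", "total",
                                   "rank", "is_core"),
                     by = "locality_id"),
    polygon = hit, inside = !is.na(hit))
  by_polygon <- loc |>
    dplyr::filter(.data$inside) |>
    dplyr::count(.data$polygon, wt = .data$is_core, name = "n_core")
  gap <- dplyr::filter(loc, .data$is_core, !.data$inside)
  list(localities = loc, by_polygon = by_polygon, gap = gap)
}

# even-odd ray casting; boundary points count as inside
point_in_polygon <- function(x, y, ring) {
  px <- ring$lon; py <- ring$lat
  n <- length(px)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # boundary check: point on segment (j -> i)
    dx <- px[i] - px[j]; dy <- py[i] - py[j]
    cross <- (x - px[j]) * dy - (y - py[j]) * dx
    if (abs(cross) < 1e-12 &&
        x >= min(px[i], px[j]) - 1e-12 && x <= max(px[i], px[j]) + 1e-12 &&
        y >= min(py[i], py[j]) - 1e-12 && y <= max(py[i], py[j]) + 1e-12) {
      return(TRUE)
    }
    if ((py[i] > y) != (py[j] > y)) {
      x_int <- px[j] + (y - py[j]) * dx / dy
      if (x < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Read polygons from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon / MultiPolygon features (outer
#' rings only; holes are not supported and raise an error).
#'
#' @param path GeoJSON file path.
#' @return A named list of rings (data frames with `lon`, `lat`).
#' @export
read_geojson_polygons <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- if (identical(j$type, "FeatureCollection")) j$features else
    list(j)
  out <- list()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    nm <- if (!is.null(f$properties$name)) f$properties$name else
      paste0("feature_", k)
    ring_df <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) {
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
      }))
      data.frame(lon = m[, 1], lat = m[, 2])
    }
    if (identical(geom$type, "Polygon")) {
      if (length(geom$coordinates) > 1) {
        stop("geometry error in ", nm, ": polygon holes unsupported",
             call. = FALSE)
      }
      out[[nm]] <- ring_df(geom$coordinates[[1]])
    } else if (identical(geom$type, "MultiPolygon")) {
      for (p in seq_along(geom$coordinates)) {
        out[[paste0(nm, "_", p)]] <- ring_df(geom$coordinates[[p]][[1]])
      }
    } else {
      stop("geometry error in ", nm, ": unsupported type ", geom$type,
           call. = FALSE)
    }
  }
  out
}
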