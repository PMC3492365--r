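#' Filter records by positional confidence
#'
#' Partitions raw records into those usable for modelling and those
#' rejected, mirroring the screening applied to collection-based data:
#' records with no usable georeference are rejected with reason
#' `"no_georeference"`, and records whose confidence-circle diameter
#' exceeds `max_diameter_km` (default 5 km, roughly a 5 arc-minute cell)
#' with reason `"low_precision"`. The boundary is kept: exactly 5 km
#' passes. Records with a missing confidence are assumed precise.
#'
#' @param records Occurrence tibble (`record_id, lon, lat, confidence_km,
#'   source, year`).
#' @param max_diameter_km Strict rejection threshold on the confidence
#'   diameter; must be > 0.
#' @return A list with tibbles `accepted` and `rejected` (the latter with
#'   a `reason` column); together they partition the input.
#' @examples
#' recs <- tibble::tibble(
#'   record_id = c("a", "b", "c"), lon = c(36, NA, 36.5),
#'   lat = c(7, NA, 7.5), confidence_km = c(0.05, 1, 10),
#'   source = "x", year = 2001L
#' )
#' filter_records(recs)$rejected
#' @export
filter_records <- function(records, max_diameter_km = 5) {
  if (max_diameter_km <= 0) stop("max_diameter_km must be > 0",
                                 call. = FALSE)
  records <- tibble::as_tibble(records)
  no_geo <- is.na(records$lon) | is.na(records$lat)
  low_prec <- !no_geo & !is.na(records$confidence_km) &
    records$confidence_km > max_diameter_km
  rejected <- records[no_geo | low_prec, ]
  rejected$reason <- ifelse(is.na(rejected$lon) | is.na(rejected$lat),
                            "no_georeference", "low_precision")
  list(accepted = records[!(no_geo | low_prec), ], rejected = rejected)
}

#' Collapse records to unique localities
#'
#' One locality per distinct coordinate pair after rounding to
#' `precision` decimal places (default 4, about 11 m — finer than any
#' stated confidence). Member record ids are preserved; the locality
#' coordinate is the rounded value, and localities keep first-seen order.
#'
#' @param records Accepted occurrence tibble (coordinates present).
#' @param precision Decimal places used for coordinate comparison.
#' @return A tibble of localities: `locality_id, lon, lat, n_records,
#'   member_record_ids` (list column).
#' @export
deduplicate <- function(records, precision = 4) {
  stopifnot(!anyNA(records$lon), !anyNA(records$lat))
  out <- records |>
    dplyr::mutate(lon = round(.data$lon, precision),
                  lat = round(.data$lat, precision)) |>
    dplyr::group_by(.data$lon, .data$lat) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      member_record_ids = list(.data$record_id),
      first_seen = min(match(.data$record_id, records$record_id)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$first_seen) |>
    dplyr::select(-"first_seen")
  dplyr::mutate(out,
                locality_id = sprintf("loc%04d", dplyr::row_number()),
                .before = 1)
}

#' Reduce localities to one modelling sample per grid cell
#'
#' Keeps the first locality (input order) in each occupied cell —
#' equivalent to retaining one sample per ~1 km cell before fitting.
#' Idempotent: re-running on its own output changes nothing.
#'
#' @param localities Locality tibble with `lon`, `lat`.
#' @param spec The modelling [grid_spec()].
#' @return The retained subset, with `row`/`col` columns appended.
#' @export
one_per_cell <- function(localities, spec) {
  located <- locate_cells(localities, spec)
  outside <- is.na(located$row)
  if (any(outside)) {
    ids <- if ("locality_id" %in% names(located)) {
      located$locality_id[outside]
    } else which(outside)
    stop("localities outside grid extent: ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }
  located[!duplicated(located[c("row", "col")]), ]
}

#' Thin localities to a minimum pairwise separation
#'
#' Greedy spatial thinning in seeded-shuffle order: localities are visited
#' in a random permutation and kept if no already-kept locality lies
#' within `min_sep_degrees` (planar degrees, matching a degree-based
#' separation criterion rather than great-circle km). The result is
#' maximal for the visit order but not guaranteed to be the largest
#' possible subset.
#'
#' @param localities Locality tibble with `lon`, `lat`.
#' @param min_sep_degrees Minimum pairwise separation; 0 keeps everything.
#' @param seed Integer seed for the shuffle.
#' @return The thinned subset, in original input order.
#' @export
thin_min_distance <- function(localities, min_sep_degrees = 0.2, seed = 1) {
  stopifnot(min_sep_degrees >= 0)
  n <- nrow(localities)
  if (n == 0 || min_sep_degrees == 0) return(localities)
  withr_seed(seed)
  ord <- sample.int(n)
  lon <- localities$lon[ord]; lat <- localities$lat[ord]
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (lon[i] - lon[keep])^2 + (lat[i] - lat[keep])^2
    if (min(d2) >= min_sep_degrees^2) keep[i] <- TRUE
  }
  localities[sort(ord[keep]), ]
}

#' Average nearest-neighbour clustering index
#'
#' Clark-Evans statistic: the ratio of the observed mean
#' nearest-neighbour distance to the expectation `0.5 * sqrt(A / n)`
#' under complete spatial randomness in a study area of size `A`. The z
#' score uses the Donnelly edge-corrected expectation and variance
#' (`E[d] = 0.5 sqrt(A/n) + (0.0514 + 0.041/sqrt(n)) P/n` with perimeter
#' `P`), which keeps the test calibrated on bounded rectangles — the
#' uncorrected normal approximation over-calls dispersion because
#' boundary points have inflated nearest-neighbour distances.
#' Classification is two-sided at |z| = 1.96: significantly small
#' distances give `"clustered"`, significantly large `"dispersed"`,
#' otherwise `"random"`.
#'
#' @param points Tibble with `lon`, `lat` (>= 2 points).
#' @param study_area Optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of the points.
#' @return A one-row tibble: `r`, `z`, `class`, `n`, `area`.
#' @export
nearest_neighbour_index <- function(points, study_area = NULL) {
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (is.null(study_area)) {
    study_area <- c(min(points$lon), max(points$lon),
                    min(points$lat), max(points$lat))
  }
  area <- (study_area[2] - study_area[1]) * (study_area[4] - study_area[3])
  if (area <= 0) stop("study area must have positive area", call. = FALSE)
  d <- as.matrix(stats::dist(cbind(points$lon, points$lat)))
  diag(d) <- Inf
  obs <- mean(apply(d, 1, min))
  expd <- 0.5 * sqrt(area / n)
  r <- obs / expd
  perim <- 2 * ((study_area[2] - study_area[1]) +
                  (study_area[4] - study_area[3]))
  expd_edge <- expd + (0.0514 + 0.041 / sqrt(n)) * perim / n
  se <- sqrt(0.0703 * area / n^2 + 0.037 * perim * sqrt(area) / n^2.5)
  z <- (obs - expd_edge) / se
  cls <- if (z < -1.96) "clustered" else if (z > 1.96) "dispersed" else
    "random"
  if (obs == 0) cls <- "clustered"
  tibble::tibble(r = r, z = z, class = cls, n = n, area = area)
}

#' Synthetic survey fixture with the historical count structure
#'
#' Builds a raw occurrence table engineered so the cleaning chain
#' reproduces the count structure of the original arabica survey
#' compilation: 719 raw records, of which 3 lack coordinates and 3 carry
#' a confidence diameter over 5 km (so 713 are accepted), collapsing to
#' 349 unique localities that occupy exactly 197 cells of the modelling
#' grid. Points are clustered to mimic survey effort. This is synthetic
#' data — the real field localities are unpublished.
#'
#' @param spec Modelling [grid_spec()]; needs at least 197 free cells in
#'   its interior.
#' @param seed Integer seed.
#' @param weights Optional matrix of cell weights (e.g. a true-niche
#'   suitability surface) biasing where localities fall.
#' @return A tibble of 719 raw occurrence records.
#' @export
make_survey_fixture <- function(spec, seed = 1, weights = NULL) {
  n_cells_target <- 197; n_localities <- 349; n_accepted <- 713
  n_cells <- spec$n_rows * spec$n_cols
  if (n_cells < n_cells_target) {
    stop("grid too small for the fixture", call. = FALSE)
  }
  withr_seed(seed)
  w <- if (is.null(weights)) rep(1, n_cells) else {
    v <- as.vector(weights); v[is.na(v)] <- 0; v + 1e-9
  }
  cells <- sample.int(n_cells, n_cells_target, prob = w)
  row <- (cells - 1) %% spec$n_rows + 1
  col <- (cells - 1) %/% spec$n_rows + 1
  ctr <- cell_centers(spec)
  # first point per cell at a jittered position; extra distinct localities
  # (349 - 197) go into a random subset of the same cells, offset so the
  # 4-decimal rounding keeps them distinct
  off1 <- spec$cell_size * 0.25
  pts <- tibble::tibble(lon = round(ctr$lon[col] - off1, 4),
                        lat = round(ctr$lat[row] - off1, 4))
  extra_cells <- sample.int(n_cells_target, n_localities - n_cells_target,
                            replace = FALSE)
  pts2 <- tibble::tibble(lon = round(ctr$lon[col[extra_cells]] + off1, 4),
                         lat = round(ctr$lat[row[extra_cells]] + off1, 4))
  localities <- dplyr::bind_rows(pts, pts2)[sample.int(n_localities), ]
  # spread 713 accepted records over the 349 localities
  reps <- rep(1L, n_localities)
  extra <- n_accepted - n_localities
  bump <- sample.int(n_localities, extra, replace = TRUE,
                     prob = stats::runif(n_localities)^2)
  for (b in bump) reps[b] <- reps[b] + 1L
  good <- localities[rep(seq_len(n_localities), reps), ]
  good$confidence_km <- sample(c(0.01, 0.05, 1, 5), nrow(good),
                               replace = TRUE, prob = c(.6, .3, .08, .02))
  good$source <- "field_survey"
  good$year <- sample(2000:2006, nrow(good), replace = TRUE)
  bad <- tibble::tibble(
    lon = c(NA, NA, NA, ctr$lon[col[1:3]]),
    lat = c(NA, NA, NA, ctr$lat[row[1:3]]),
    confidence_km = c(1, 1, 1, 10, 50, 100),
    source = c(rep("literature", 3), rep("herbarium", 3)),
    year = sample(1941:1984, 6, replace = TRUE)
  )
  out <- dplyr::bind_rows(good, bad)
  out <- out[sample.int(nrow(out)), ]
  out$record_id <- sprintf("rec%05d", seq_len(nrow(out)))
  dplyr::select(out, "record_id", "lon", "lat", "confidence_km",
                "source", "year")
}

#' Run the full cleaning chain
#'
#' `filter_records()` then [deduplicate()] then [one_per_cell()], the
#' standard preparation from raw records to modelling samples.
#'
#' @param records Raw occurrence tibble.
#' @param spec Modelling [grid_spec()].
#' @param max_diameter_km,precision Passed through to the stages.
#' @return A list: `accepted`, `rejected`, `localities`, `samples`.
#' @export
prepare_occurrences <- function(records, spec, max_diameter_km = 5,
                                precision = 4) {
  flt <- filter_records(records, max_diameter_km)
  localities <- deduplicate(flt$accepted, precision)
  samples <- one_per_cell(localities, spec)
  list(accepted = flt$accepted, rejected = flt$rejected,
       localities = localities, samples = samples)
}
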