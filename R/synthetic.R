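#' Synthetic bioclim-like landscapes
#'
#' Generates a baseline climate stack with the statistical structure the
#' downstream pipeline assumes: each layer is spatially autocorrelated
#' Gaussian noise (separable Gaussian-kernel smoothing of white noise,
#' kernel sd = `autocorrelation_length` cells) plus a deterministic
#' north-south gradient, rescaled to a realistic mean and spread for its
#' variable. The default four layers mirror the strongest predictors in
#' highland coffee-niche models: temperature seasonality, mean temperature
#' of the warmest quarter, precipitation of the driest month, and mean
#' temperature of the wettest quarter.
#'
#' @param spec A [grid_spec()].
#' @param n_layers Number of layers (>= 2); the first four take the named
#'   bioclim-like roles, extras are generic temperature-like layers.
#' @param autocorrelation_length Smoothing length in cells; 0 disables
#'   smoothing (pure white noise plus gradient).
#' @param seed Integer seed fixing all randomness.
#' @return A [clim_stack()].
#' @examples
#' base <- generate_baseline(grid_spec(40, 40, 0.02), seed = 1)
#' names(base)
#' @export
generate_baseline <- function(spec, n_layers = 4,
                              autocorrelation_length = 5, seed = 1) {
  if (!inherits(spec, "grid_spec")) stop("spec must be a grid_spec",
                                         call. = FALSE)
  if (n_layers < 2) stop("n_layers must be >= 2", call. = FALSE)
  defs <- list(
    list(name = "temp_seasonality",   kind = "seasonality",
         mean = 60,  sd = 15, grad = 10),
    list(name = "warm_quarter_temp",  kind = "temperature",
         mean = 22,  sd = 2.5, grad = 4),
    list(name = "dry_month_precip",   kind = "precipitation",
         mean = 25,  sd = 10, grad = -8),
    list(name = "wet_quarter_temp",   kind = "temperature",
         mean = 19,  sd = 2.0, grad = 3)
  )
  if (n_layers > 4) {
    for (k in seq(5, n_layers)) {
      defs[[k]] <- list(name = paste0("aux_temp_", k), kind = "temperature",
                        mean = 20, sd = 2, grad = 2)
    }
  }
  defs <- defs[seq_len(n_layers)]

  withr_seed(seed)
  # gradient: scaled row position, 0 at the north edge, 1 at the south
  grad01 <- matrix(rep((seq_len(spec$n_rows) - 0.5) / spec$n_rows,
                       times = spec$n_cols),
                   nrow = spec$n_rows)
  layers <- list(); kind <- character(0)
  for (d in defs) {
    noise <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                    nrow = spec$n_rows)
    sm <- smooth_gaussian(noise, autocorrelation_length)
    sm <- (sm - mean(sm)) / stats::sd(as.vector(sm))
    field <- d$mean + d$sd * sm + d$grad * (grad01 - 0.5)
    if (d$kind == "precipitation") field[field < 0] <- 0
    layers[[d$name]] <- field
    kind <- c(kind, d$kind)
  }
  clim_stack(layers, spec, kind)
}

# separable Gaussian blur; sigma in cells, truncated at 3 sigma.
# sigma = 0 is the identity.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    # reflect-pad so edges keep comparable variance
    vp <- c(rev(v[seq_len(half)]), v, rev(v[seq(length(v) - half + 1,
                                                length(v))]))
    stats::filter(vp, k, sides = 2)[seq(half + 1, half + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

# all generator randomness funnels through here so determinism is
# auditable in one place
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(NULL)
}

#' Define an emission-scenario / date delta
#'
#' A scenario spec carries the climate deltas applied to a baseline stack
#' for one scenario at one date: an additive temperature shift (degrees
#' C), a multiplicative precipitation factor, and an additive shift to the
#' seasonality layer.
#'
#' @param scenario_id Scenario label (e.g. `"B2A"`).
#' @param date Date label (e.g. `"2050"`).
#' @param temp_delta Additive shift for temperature-kind layers, degrees C.
#' @param precip_factor Multiplier for precipitation-kind layers (>= 0).
#' @param seasonality_delta Additive shift for the seasonality-kind layer.
#' @return A `scenario_spec` object (a one-row tibble subclass).
#' @export
scenario_spec <- function(scenario_id, date, temp_delta = 0,
                          precip_factor = 1, seasonality_delta = 0) {
  if (!is.finite(temp_delta) || !is.finite(precip_factor) ||
      !is.finite(seasonality_delta)) {
    stop("scenario deltas must be finite", call. = FALSE)
  }
  if (precip_factor < 0) {
    stop("invalid scenario: precip_factor must be >= 0", call. = FALSE)
  }
  structure(
    tibble::tibble(scenario_id = scenario_id, date = as.character(date),
                   temp_delta = temp_delta, precip_factor = precip_factor,
                   seasonality_delta = seasonality_delta),
    class = c("scenario_spec", "tbl_df", "tbl", "data.frame")
  )
}

#' Default scenario set
#'
#' Three SRES-style emission scenarios over three future dates, plus a
#' neutral baseline (2000). The strongest scenario (A1B analogue) warms by
#' +1 / +2 / +3 degrees C at 2020 / 2050 / 2080 with progressive drying;
#' the milder scenarios (A2A, B2A analogues) scale those deltas by 0.9 and
#' 0.7. Warming is monotone with date within each scenario.
#'
#' @return A tibble with one row per scenario x date, baseline included.
#' @export
default_scenarios <- function() {
  dates <- c("2020", "2050", "2080")
  dt <- c(1, 2, 3)
  scale <- c(A1B = 1, A2A = 0.9, B2A = 0.7)
  rows <- list(scenario_spec("baseline", "2000"))
  for (sc in names(scale)) {
    for (i in seq_along(dates)) {
      d <- dt[i] * scale[[sc]]
      rows[[length(rows) + 1]] <- scenario_spec(
        sc, dates[i],
        temp_delta = d,
        precip_factor = 1 - 0.05 * d,
        seasonality_delta = 2 * d
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Apply a scenario delta to a baseline stack
#'
#' Temperature-kind layers are shifted by `temp_delta`, precipitation-kind
#' layers multiplied by `precip_factor`, the seasonality layer shifted by
#' `seasonality_delta`. Nodata (`NA`) cells stay nodata.
#'
#' @param baseline A [clim_stack()].
#' @param scenario A [scenario_spec()] (or one row of [default_scenarios()]).
#' @return A new `clim_stack`.
#' @export
generate_future <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "clim_stack"))
  if (!all(c("temp_delta", "precip_factor", "seasonality_delta") %in%
           names(scenario))) {
    stop("scenario must carry temp_delta, precip_factor, seasonality_delta",
         call. = FALSE)
  }
  if (scenario$precip_factor < 0) {
    stop("invalid scenario: precip_factor must be >= 0", call. = FALSE)
  }
  layers <- baseline$layers
  for (nm in names(layers)) {
    layers[[nm]] <- switch(
      baseline$kind[[nm]],
      temperature   = layers[[nm]] + scenario$temp_delta,
      precipitation = layers[[nm]] * scenario$precip_factor,
      seasonality   = layers[[nm]] + scenario$seasonality_delta
    )
  }
  clim_stack(layers, baseline$spec, unname(baseline$kind))
}

#' Downscale a coarse anomaly onto a fine baseline
#'
#' Bilinear interpolation of a coarse anomaly grid to the fine grid's cell
#' centers, then combined with the fine baseline: added for temperature
#' anomalies, multiplied for precipitation factors. This is the simplified
#' delta-method stand-in used by the synthetic scenarios; it is not a
#' thin-plate-spline interpolator.
#'
#' @param coarse_anomaly Matrix of anomaly values on `coarse_spec`.
#' @param coarse_spec [grid_spec()] of the anomaly grid; must cover the
#'   fine grid's cell centers.
#' @param fine_baseline Matrix on `fine_spec`.
#' @param fine_spec [grid_spec()] of the baseline.
#' @param mode `"add"` (temperature) or `"multiply"` (precipitation).
#' @return Matrix on the fine grid; `NA` cells in the baseline preserved.
#' @export
delta_downscale <- function(coarse_anomaly, coarse_spec,
                            fine_baseline, fine_spec, mode = c("add",
                                                               "multiply")) {
  mode <- match.arg(mode)
  ctr_c <- cell_centers(coarse_spec)
  ctr_f <- cell_centers(fine_spec)
  if (min(ctr_f$lon) < min(ctr_c$lon) - coarse_spec$cell_size ||
      max(ctr_f$lon) > max(ctr_c$lon) + coarse_spec$cell_size ||
      min(ctr_f$lat) < min(ctr_c$lat) - coarse_spec$cell_size ||
      max(ctr_f$lat) > max(ctr_c$lat) + coarse_spec$cell_size) {
    stop("coverage error: coarse grid does not cover the fine extent",
         call. = FALSE)
  }
  interp <- bilinear_grid(coarse_anomaly, ctr_c$lon, ctr_c$lat,
                          ctr_f$lon, ctr_f$lat)
  out <- if (mode == "add") fine_baseline + interp else fine_baseline * interp
  out[is.na(fine_baseline)] <- NA
  out
}

# bilinear interpolation from (xs west->east, ys north->south) grid values
# onto the outer product of (x0, y0); clamped at the coarse cell-center hull
bilinear_grid <- function(vals, xs, ys, x0, y0) {
  ys_s <- rev(ys)                      # ascending for interval lookup
  vals_s <- vals[rev(seq_along(ys)), , drop = FALSE]
  ix <- findInterval(x0, xs, all.inside = TRUE)
  iy <- findInterval(y0, ys_s, all.inside = TRUE)
  tx <- (x0 - xs[ix]) / (xs[pmin(ix + 1, length(xs))] - xs[ix])
  ty <- (y0 - ys_s[iy]) / (ys_s[pmin(iy + 1, length(ys_s))] - ys_s[iy])
  tx[!is.finite(tx)] <- 0
  ty[!is.finite(ty)] <- 0
  tx <- pmin(pmax(tx, 0), 1)
  ty <- pmin(pmax(ty, 0), 1)
  n_r <- length(y0); n_c <- length(x0)
  out <- matrix(NA_real_, n_r, n_c)
  ix2 <- pmin(ix + 1, length(xs)); iy2 <- pmin(iy + 1, length(ys_s))
  for (j in seq_len(n_c)) {
    v00 <- vals_s[iy,  ix[j]];  v01 <- vals_s[iy,  ix2[j]]
    v10 <- vals_s[iy2, ix[j]];  v11 <- vals_s[iy2, ix2[j]]
    out[, j] <- (1 - ty) * ((1 - tx[j]) * v00 + tx[j] * v01) +
      ty * ((1 - tx[j]) * v10 + tx[j] * v11)
  }
  out
}

#' Define a known true niche
#'
#' Ground truth for recovery tests: suitability is a product of Gaussian
#' bells, one per variable, scaled to `max_suitability`:
#' `s(x) = max_suitability * prod_v exp(-((x_v - opt_v) / tol_v)^2 / 2)`.
#'
#' @param optimum Named numeric vector of per-variable optima (layer units).
#' @param tolerance Named numeric vector of per-variable tolerances (> 0).
#' @param max_suitability Peak suitability in (0, 1].
#' @return A `true_niche` object.
#' @export
true_niche <- function(optimum, tolerance, max_suitability = 1) {
  stopifnot(length(optimum) == length(tolerance),
            !is.null(names(optimum)))
  if (any(tolerance <= 0)) stop("tolerances must be > 0", call. = FALSE)
  if (max_suitability <= 0 || max_suitability > 1) {
    stop("max_suitability must be in (0, 1]", call. = FALSE)
  }
  structure(list(optimum = optimum,
                 tolerance = stats::setNames(tolerance, names(optimum)),
                 max_suitability = max_suitability),
            class = "true_niche")
}

#' Evaluate the true niche over a stack
#'
#' @param stack A [clim_stack()] containing every niche variable.
#' @param niche A [true_niche()].
#' @return Matrix of suitabilities in `[0, max_suitability]`.
#' @export
true_suitability <- function(stack, niche) {
  missing <- setdiff(names(niche$optimum), names(stack$layers))
  if (length(missing)) {
    stop("missing layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- matrix(niche$max_suitability, stack$spec$n_rows, stack$spec$n_cols)
  for (v in names(niche$optimum)) {
    z <- (stack$layers[[v]] - niche$optimum[[v]]) / niche$tolerance[[v]]
    s <- s * exp(-z^2 / 2)
  }
  s
}

#' Sample occurrence records from a suitability surface
#'
#' Presences are drawn with probability proportional to suitability. With
#' `clustering > 1` a parent-offspring (Thomas-style) process mimics
#' survey clustering: parents are suitability-weighted, each spawns a
#' cluster of nearby records. A fraction `frac_bad` of records is made
#' unusable for modelling — either assigned a confidence diameter above
#' 5 km (imprecise historical records) or stripped of coordinates — and
#' exact duplicate records are injected to emulate repeat visits.
#'
#' @param suitability Matrix of sampling weights (>= 0, not all zero).
#' @param spec The [grid_spec()] of the surface.
#' @param n_records Number of records to return.
#' @param clustering Expected records per cluster (1 = no clustering).
#' @param frac_bad Proportion of records made rejectable.
#' @param frac_duplicate Proportion of records that are exact duplicates of
#'   earlier ones.
#' @param seed Integer seed.
#' @return A tibble of occurrence records:
#'   `record_id, lon, lat, confidence_km, source, year`.
#' @export
sample_occurrences <- function(suitability, spec, n_records,
                               clustering = 3, frac_bad = 0.01,
                               frac_duplicate = 0.3, seed = 1) {
  if (frac_bad < 0 || frac_bad > 1) stop("frac_bad must be in [0, 1]",
                                         call. = FALSE)
  if (n_records == 0) {
    return(tibble::tibble(record_id = character(0), lon = numeric(0),
                          lat = numeric(0), confidence_km = numeric(0),
                          source = character(0), year = integer(0)))
  }
  w <- as.vector(suitability)
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("sampling impossible: all-zero suitability",
                        call. = FALSE)
  withr_seed(seed)
  ctr <- cell_centers(spec)
  n_cells <- length(w)
  cell_lon <- ctr$lon[(seq_len(n_cells) - 1) %/% spec$n_rows + 1]
  cell_lat <- ctr$lat[(seq_len(n_cells) - 1) %% spec$n_rows + 1]

  n_dup <- round(frac_duplicate * n_records)
  n_new <- n_records - n_dup
  pts <- list()
  n_got <- 0
  while (n_got < n_new) {
    parent <- sample.int(n_cells, 1, prob = w)
    size <- if (clustering <= 1) 1 else stats::rpois(1, clustering - 1) + 1
    jit <- spec$cell_size * (if (clustering <= 1) 0.5 else 2)
    lon <- cell_lon[parent] + stats::runif(size, -jit, jit)
    lat <- cell_lat[parent] + stats::runif(size, -jit, jit)
    keep <- !is.na(extract_at(tibble::tibble(lon = lon, lat = lat),
                              suitability, spec)$value)
    lon <- lon[keep]; lat <- lat[keep]
    if (!length(lon)) next
    take <- min(length(lon), n_new - n_got)
    pts[[length(pts) + 1]] <- tibble::tibble(lon = lon[seq_len(take)],
                                             lat = lat[seq_len(take)])
    n_got <- n_got + take
  }
  recs <- dplyr::bind_rows(pts)
  recs <- dplyr::mutate(
    recs,
    lon = round(.data$lon, 4), lat = round(.data$lat, 4),
    confidence_km = sample(c(0.01, 0.05, 1, 2), dplyr::n(),
                           replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05)),
    source = "field_survey",
    year = sample(2000:2006, dplyr::n(), replace = TRUE)
  )
  if (n_dup > 0) {
    dup <- recs[sample.int(nrow(recs), n_dup, replace = TRUE), ]
    recs <- dplyr::bind_rows(recs, dup)
  }
  n_bad <- round(frac_bad * nrow(recs))
  if (n_bad > 0) {
    bad_idx <- sample.int(nrow(recs), n_bad)
    half <- ceiling(n_bad / 2)
    lose_coords <- bad_idx[seq_len(half)]
    low_prec <- setdiff(bad_idx, lose_coords)
    recs$lon[lose_coords] <- NA_real_
    recs$lat[lose_coords] <- NA_real_
    recs$source[lose_coords] <- "literature"
    if (length(low_prec)) {
      recs$confidence_km[low_prec] <- sample(c(10, 25, 50, 100),
                                             length(low_prec), replace = TRUE)
      recs$source[low_prec] <- "herbarium"
      recs$year[low_prec] <- sample(1941:1984, length(low_prec),
                                    replace = TRUE)
    }
  }
  recs$record_id <- sprintf("rec%05d", seq_len(nrow(recs)))
  dplyr::select(recs, "record_id", "lon", "lat", "confidence_km",
                "source", "year")
}

#' Read / write occurrence CSVs
#'
#' The occurrence CSV dialect used throughout:
#' `record_id,lon,lat,confidence_km,source,year`.
#'
#' @param path File path.
#' @param data A tibble of occurrence records.
#' @return `read_occurrences()` a tibble; `write_occurrences()` the path,
#'   invisibly.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "lon", "lat", "confidence_km", "source", "year")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("occurrence CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}
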