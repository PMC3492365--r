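toy_records <- function(lon, lat, conf, id = NULL) {
  n <- length(lon)
  tibble::tibble(
    record_id = id %||% sprintf("r%02d", seq_len(n)),
    lon = lon, lat = lat, confidence_km = conf,
    source = "test", year = 2001L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("confidence filter partitions records with reasons", {
  recs <- toy_records(
    lon = c(rep(NA, 3), rep(36, 3), rep(36.5, 3)),
    lat = c(rep(NA, 3), rep(7, 3), rep(7.5, 3)),
    conf = c(1, 1, 1, 10, 10, 10, 0.05, 0.05, 0.05))
  out <- filter_records(recs)
  expect_equal(nrow(out$accepted), 3)
  expect_equal(nrow(out$rejected), 6)
  expect_equal(sum(out$rejected$reason == "no_georeference"), 3)
  expect_equal(sum(out$rejected$reason == "low_precision"), 3)
  expect_setequal(c(out$accepted$record_id, out$rejected$record_id),
                  recs$record_id)

  # the 5 km boundary is kept (strict > rejection)
  edge <- toy_records(36, 7, 5.0)
  expect_equal(nrow(filter_records(edge)$accepted), 1)
  # empty input partitions into two empties
  none <- filter_records(toy_records(numeric(0), numeric(0), numeric(0)))
  expect_equal(nrow(none$accepted), 0)
  expect_equal(nrow(none$rejected), 0)
  expect_error(filter_records(edge, max_diameter_km = 0), "> 0")
})

test_that("deduplication collapses identical and near-identical points", {
  five <- toy_records(rep(36.1234, 5), rep(7.5678, 5), rep(0.05, 5))
  loc <- deduplicate(five)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$n_records, 5)
  expect_length(loc$member_record_ids[[1]], 5)

  # differences past the 4th decimal collapse at default precision
  close <- toy_records(c(36.12341, 36.12339), c(7, 7), c(0.05, 0.05))
  expect_equal(nrow(deduplicate(close)), 1)
  expect_equal(nrow(deduplicate(close, precision = 6)), 2)
})

test_that("one_per_cell keeps the first locality per cell, idempotently", {
  s <- grid_spec(10, 10, cell_size = 0.1, origin_lon = 0,
                 origin_lat = 1)
  loc <- tibble::tibble(
    locality_id = sprintf("loc%d", 1:4),
    lon = c(0.01, 0.02, 0.03, 0.55),
    lat = c(0.95, 0.96, 0.94, 0.55))
  out <- one_per_cell(loc, s)
  expect_equal(out$locality_id, c("loc1", "loc4"))
  # all-distinct cells: identity
  spread <- tibble::tibble(locality_id = sprintf("loc%d", 1:3),
                           lon = c(0.05, 0.35, 0.75),
                           lat = c(0.95, 0.55, 0.15))
  expect_equal(nrow(one_per_cell(spread, s)), 3)
  # idempotence
  again <- one_per_cell(out, s)
  expect_equal(again$locality_id, out$locality_id)
  # out-of-extent localities are named in the error
  off <- tibble::tibble(locality_id = "locX", lon = 50, lat = 50)
  expect_error(one_per_cell(off, s), "locX")
})

test_that("thinning enforces the minimum separation (pairwise oracle)", {
  set.seed(77)
  # clustered cloud: pairs guaranteed closer than the threshold
  centers <- tibble::tibble(lon = runif(60, 0, 3), lat = runif(60, 0, 3))
  cloud <- dplyr::bind_rows(centers, dplyr::mutate(
    centers, lon = lon + 0.05, lat = lat - 0.05))
  cloud$locality_id <- sprintf("loc%03d", seq_len(nrow(cloud)))

  expect_equal(thin_min_distance(cloud, 0), cloud)
  two <- cloud[c(1, 61), ]    # 0.1 degrees apart roughly
  expect_equal(nrow(thin_min_distance(two, 0.2, seed = 1)), 1)

  for (seed in 1:5) {
    kept <- thin_min_distance(cloud, 0.2, seed = seed)
    d <- as.matrix(stats::dist(cbind(kept$lon, kept$lat)))
    diag(d) <- Inf
    expect_true(all(d >= 0.2))
    # greedy maximality: every dropped point is within 0.2 of a kept one
    dropped <- cloud[!cloud$locality_id %in% kept$locality_id, ]
    for (i in seq_len(nrow(dropped))) {
      dd <- sqrt((dropped$lon[i] - kept$lon)^2 +
                   (dropped$lat[i] - kept$lat)^2)
      expect_lt(min(dd), 0.2)
    }
  }
})

test_that("nearest-neighbour index separates lattice, clump and random", {
  # perfect square lattice: dispersed, R > 1
  g <- expand.grid(lon = seq(0.05, 0.95, by = 0.1),
                   lat = seq(0.05, 0.95, by = 0.1))
  latt <- nearest_neighbour_index(tibble::as_tibble(g),
                                  study_area = c(0, 1, 0, 1))
  expect_gt(latt$r, 1)
  expect_equal(latt$class, "dispersed")

  # near-coincident points: R -> 0, clustered
  clump <- tibble::tibble(lon = 0.5 + runif(30, 0, 1e-6),
                          lat = 0.5 + runif(30, 0, 1e-6))
  cl <- nearest_neighbour_index(clump, study_area = c(0, 1, 0, 1))
  expect_lt(cl$r, 0.01)
  expect_equal(cl$class, "clustered")

  # uniform random points classify random with R near 1 (Monte Carlo);
  # a calibrated two-sided 5% test accepts ~95 of 100 draws, so the
  # frozen bound allows ~3 binomial standard deviations of slack
  hits <- 0
  zs <- rs <- numeric(100)
  for (seed in 1:100) {
    set.seed(seed)
    pts <- tibble::tibble(lon = runif(500), lat = runif(500))
    nn <- nearest_neighbour_index(pts, study_area = c(0, 1, 0, 1))
    rs[seed] <- nn$r
    zs[seed] <- nn$z
    if (nn$class == "random") hits <- hits + 1
  }
  expect_true(all(rs > 0.9 & rs < 1.1))
  expect_gte(hits, 89)
  expect_lt(abs(mean(zs)), 0.3)    # no systematic edge bias

  expect_error(nearest_neighbour_index(clump[1, ]), "at least 2")
})

test_that("survey fixture reproduces the historical cleaning counts", {
  s <- grid_spec(40, 40, cell_size = 1 / 120, origin_lon = 35,
                 origin_lat = 8)
  raw <- make_survey_fixture(s, seed = 9)
  expect_equal(nrow(raw), 719)
  prep <- prepare_occurrences(raw, s)
  expect_equal(nrow(prep$accepted), 713)
  expect_equal(nrow(prep$rejected), 6)
  expect_equal(nrow(prep$localities), 349)
  expect_equal(nrow(prep$samples), 197)
  # cleaning chain counts never increase
  expect_true(nrow(raw) >= nrow(prep$accepted))
  expect_true(nrow(prep$accepted) >= nrow(prep$localities))
  expect_true(nrow(prep$localities) >= nrow(prep$samples))
  # member ids preserved through deduplication
  expect_equal(sum(prep$localities$n_records), 713)
})
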