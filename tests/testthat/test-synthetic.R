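test_that("baseline generation is deterministic and validates input", {
  s <- tiny_spec()
  a <- generate_baseline(s, seed = 7)
  b <- generate_baseline(s, seed = 7)
  expect_identical(a$layers, b$layers)
  d <- generate_baseline(s, seed = 8)
  expect_false(identical(a$layers, d$layers))
  expect_error(generate_baseline(s, n_layers = 1), "n_layers")
  expect_error(generate_baseline("not a spec"), "grid_spec")
  expect_true(all(vapply(a$layers, function(m) all(is.finite(m)),
                         logical(1))))
})

test_that("smoothing raises spatial autocorrelation (Moran's I oracle)", {
  s <- grid_spec(50, 50, cell_size = 0.02)
  smooth <- generate_baseline(s, autocorrelation_length = 5, seed = 7)
  rough <- generate_baseline(s, autocorrelation_length = 0, seed = 7)
  for (nm in names(smooth$layers)) {
    expect_gt(morans_i_brute(smooth$layers[[nm]]),
              morans_i_brute(rough$layers[[nm]]))
  }
  # Moran's I of the smoothed field should itself be strongly positive
  expect_gt(morans_i_brute(smooth$layers[[1]]), 0.5)
})

test_that("zero autocorrelation length leaves noise variance untouched", {
  s <- grid_spec(80, 80, cell_size = 0.01)
  rough <- generate_baseline(s, autocorrelation_length = 0, seed = 3)
  # warm-quarter layer: sd target 2.5 plus a gradient of 4 over the rows
  v <- rough$layers$warm_quarter_temp
  detrended <- v - rowMeans(v) %o% rep(1, ncol(v))
  expect_equal(sd(as.vector(detrended)), 2.5, tolerance = 0.1)
})

test_that("scenario deltas act additively / multiplicatively by kind", {
  s <- tiny_spec()
  base <- generate_baseline(s, seed = 7)
  ident <- generate_future(base, scenario_spec("x", "2050", 0, 1, 0))
  expect_identical(ident$layers, base$layers)

  warm <- generate_future(base, scenario_spec("x", "2050",
                                              temp_delta = 2))
  for (nm in names(base$layers)) {
    if (base$kind[[nm]] == "temperature") {
      expect_equal(warm$layers[[nm]], base$layers[[nm]] + 2)
    } else {
      expect_equal(warm$layers[[nm]], base$layers[[nm]])
    }
  }
  dry <- generate_future(base, scenario_spec("x", "2050",
                                             precip_factor = 0.8))
  expect_equal(dry$layers$dry_month_precip,
               base$layers$dry_month_precip * 0.8)
  expect_error(scenario_spec("x", "2050", precip_factor = -1),
               "invalid scenario")
  # nodata preserved
  base$layers$warm_quarter_temp[1, 1] <- NA
  warm2 <- generate_future(base, scenario_spec("x", "2050", 2))
  expect_true(is.na(warm2$layers$warm_quarter_temp[1, 1]))
})

test_that("default scenarios warm monotonically within each scenario", {
  sc <- default_scenarios()
  expect_true("baseline" %in% sc$scenario_id)
  base_row <- sc[sc$scenario_id == "baseline", ]
  expect_equal(base_row$temp_delta, 0)
  expect_equal(base_row$precip_factor, 1)
  for (id in setdiff(unique(sc$scenario_id), "baseline")) {
    d <- sc[sc$scenario_id == id, ]
    d <- d[order(as.numeric(d$date)), ]
    expect_true(all(diff(abs(d$temp_delta)) >= 0))
  }
})

test_that("delta downscaling: constant, pass-through and bilinear cases", {
  fine <- grid_spec(8, 8, cell_size = 0.25, origin_lon = 0,
                    origin_lat = 2)
  baseline <- matrix(runif(64), 8, 8)
  # constant anomaly on a coarse grid covering the fine extent
  coarse <- grid_spec(2, 2, cell_size = 1, origin_lon = 0, origin_lat = 2)
  anom <- matrix(3, 2, 2)
  out <- delta_downscale(anom, coarse, baseline, fine, mode = "add")
  expect_equal(out, baseline + 3)
  # equal-resolution anomaly is exact pass-through addition
  anom_f <- matrix(rnorm(64), 8, 8)
  out2 <- delta_downscale(anom_f, fine, baseline, fine, mode = "add")
  expect_equal(out2, baseline + anom_f)
  # midpoint of a 2x2 coarse ramp gets the mean of the 4 corner values
  ramp <- matrix(c(0, 2, 4, 10), 2, 2)
  mid_spec <- grid_spec(1, 1, cell_size = 2, origin_lon = 0,
                        origin_lat = 2)
  mid_base <- matrix(0, 1, 1)
  out3 <- delta_downscale(ramp, coarse, mid_base, mid_spec, mode = "add")
  expect_equal(out3[1, 1], mean(ramp))
  # multiplicative mode
  out4 <- delta_downscale(matrix(0.5, 2, 2), coarse, baseline, fine,
                          mode = "multiply")
  expect_equal(out4, baseline * 0.5)
  # coverage error
  far <- grid_spec(8, 8, cell_size = 0.25, origin_lon = 50,
                   origin_lat = 50)
  expect_error(delta_downscale(anom, coarse, baseline, far), "coverage")
})

test_that("true suitability is a scaled Gaussian-bell product", {
  land <- niche_landscape(n = 20)
  niche <- land$niche
  expect_true(all(land$truth >= 0 & land$truth <= niche$max_suitability))
  # at the optimum exactly: max suitability
  env_opt <- lapply(niche$optimum, function(x) matrix(x, 1, 1))
  st <- clim_stack(env_opt, grid_spec(1, 1, 1),
                   c("seasonality", "temperature", "precipitation",
                     "temperature"))
  expect_equal(true_suitability(st, niche)[1, 1], niche$max_suitability)
  # k tolerances away in one variable reduces by exp(-k^2/2)
  for (k in c(1, 2)) {
    env_k <- env_opt
    env_k$warm_quarter_temp <- matrix(
      niche$optimum[["warm_quarter_temp"]] +
        k * niche$tolerance[["warm_quarter_temp"]], 1, 1)
    st_k <- clim_stack(env_k, grid_spec(1, 1, 1),
                       c("seasonality", "temperature", "precipitation",
                         "temperature"))
    expect_equal(true_suitability(st_k, niche)[1, 1],
                 niche$max_suitability * exp(-k^2 / 2))
  }
  # missing layer is a schema error
  st2 <- clim_stack(env_opt[1:2], grid_spec(1, 1, 1),
                    c("seasonality", "temperature"))
  expect_error(true_suitability(st2, niche), "missing layer")
})

test_that("warming-sensitive niche loses suitability along each scenario", {
  land <- niche_landscape(n = 30)
  sc <- default_scenarios()
  for (id in setdiff(unique(sc$scenario_id), "baseline")) {
    rows <- sc[sc$scenario_id == id, ]
    rows <- rows[order(as.numeric(rows$date)), ]
    means <- vapply(seq_len(nrow(rows)), function(i) {
      mean(true_suitability(generate_future(land$base, rows[i, ]),
                            land$niche))
    }, numeric(1))
    expect_true(all(diff(c(mean(land$truth), means)) <= 0))
  }
})

test_that("occurrence sampling is suitability-biased and well-formed", {
  land <- niche_landscape(n = 40)
  empty <- sample_occurrences(land$truth, land$spec, 0)
  expect_equal(nrow(empty), 0)
  expect_error(
    sample_occurrences(matrix(0, 40, 40), land$spec, 10),
    "sampling impossible")
  expect_error(
    sample_occurrences(land$truth, land$spec, 10, frac_bad = 2),
    "frac_bad")

  recs <- sample_occurrences(land$truth, land$spec, 500, clustering = 1,
                             frac_bad = 0, frac_duplicate = 0, seed = 5)
  expect_equal(nrow(recs), 500)
  # frac_bad = 0: everything passes the 5 km filter
  flt <- filter_records(recs)
  expect_equal(nrow(flt$accepted), 500)
  # sampled cells are markedly more suitable than the landscape average
  vals <- extract_at(recs[c("lon", "lat")], land$truth, land$spec)$value
  expect_gt(mean(vals), mean(land$truth))
  # determinism
  recs2 <- sample_occurrences(land$truth, land$spec, 500, clustering = 1,
                              frac_bad = 0, frac_duplicate = 0, seed = 5)
  expect_identical(recs, recs2)
  # frac_bad > 0 produces both rejection reasons
  bad <- sample_occurrences(land$truth, land$spec, 300, frac_bad = 0.1,
                            seed = 6)
  rej <- filter_records(bad)$rejected
  expect_setequal(unique(rej$reason), c("no_georeference",
                                        "low_precision"))
})

test_that("occurrence CSVs round-trip", {
  land <- niche_landscape(n = 20)
  recs <- sample_occurrences(land$truth, land$spec, 50, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(recs, path)
  back <- read_occurrences(path)
  expect_equal(back$lon, recs$lon)
  expect_equal(back$confidence_km, recs$confidence_km)
  expect_error(read_occurrences(withr::local_tempfile(lines = "a,b\n1,2")),
               "missing column")
})
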