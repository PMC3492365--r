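# small hand-built projection set for exhaustive per-cell checks
toy_projections <- function() {
  spec <- grid_spec(6, 6, cell_size = 0.1, origin_lon = 0,
                    origin_lat = 1)
  set.seed(55)
  base <- matrix(runif(36), 6, 6)
  base[1, 1] <- NA                      # nodata cell
  base[2, 1] <- 0.01                    # unsuitable at baseline
  th <- structure(list(tau_optimal = 0.7, tau_intermediate = 0.4,
                       tau_marginal = 0.1, levels = c(0.68, 0.95, 1)),
                  class = "threshold_set")
  mk <- function(m) m
  proj <- tibble::tibble(
    scenario_id = c("baseline", "X", "X", "X"),
    date = c("2000", "2020", "2050", "2080"),
    surface = list(
      mk(base),
      mk(pmin(base * 1.3, 0.99)),       # some cells improve
      mk(base * 0.6),
      mk(base * 0.3)))
  list(spec = spec, base = base, th = th, proj = proj)
}

test_that("no-gain rule: baseline-unsuitable cells stay unsuitable", {
  tp <- toy_projections()
  cg <- reclassify_surfaces(tp$proj, tp$th)
  base_codes <- cg$class_grid[[which(cg$scenario_id == "baseline")]]
  for (i in which(cg$scenario_id != "baseline")) {
    g <- cg$class_grid[[i]]
    # per-cell: future suitable set is a subset of the baseline suitable set
    expect_true(all(g[base_codes == 0L] == 0L, na.rm = TRUE))
    # masked wherever baseline is nodata
    expect_true(all(is.na(g[is.na(base_codes)])))
  }
  # the improving 2020 surface would climb without the rule
  th <- tp$th
  raw_2020 <- classify_scores(as.vector(pmin(tp$base * 1.3, 0.99)), th)
  gained <- which(as.integer(raw_2020) - 1L > 0 &
                    as.vector(tp$base) < th$tau_marginal)
  expect_gt(length(gained), 0)          # the rule actually bites
})

test_that("ratchet makes per-cell classes non-improving through time", {
  tp <- toy_projections()
  cg <- reclassify_surfaces(tp$proj, tp$th, ratchet = TRUE)
  fut <- cg[cg$scenario_id == "X", ]
  fut <- fut[order(as.numeric(fut$date)), ]
  for (i in seq_len(nrow(fut) - 1)) {
    a <- fut$class_grid[[i]]; b <- fut$class_grid[[i + 1]]
    expect_true(all(b <= a, na.rm = TRUE))
  }
  # without the ratchet the improving surface must beat the later ones
  cg0 <- reclassify_surfaces(tp$proj, tp$th, ratchet = FALSE)
  expect_error(reclassify_surfaces(
    dplyr::mutate(tp$proj, date = c("2000", "a", "b", "c")), tp$th),
    "sequencing")
})

test_that("constant scores give identical class grids across dates", {
  tp <- toy_projections()
  proj_const <- tp$proj
  for (i in seq_len(nrow(proj_const))) proj_const$surface[[i]] <- tp$base
  cg <- reclassify_surfaces(proj_const, tp$th, ratchet = TRUE)
  for (i in 2:nrow(cg)) {
    expect_equal(cg$class_grid[[i]], cg$class_grid[[1]])
  }
})

test_that("area accounting: disjoint classes sum to the unmasked total", {
  tp <- toy_projections()
  cg <- reclassify_surfaces(tp$proj, tp$th)
  ac <- compute_area_change(cg, tp$spec)
  areas <- cell_area_km2(tp$spec)
  total_unmasked <- sum(matrix(rep(areas, 6), 6)[!is.na(tp$base)])
  by_col <- ac$by_class |>
    dplyr::group_by(scenario_id, date) |>
    dplyr::summarise(total = sum(area_km2), .groups = "drop")
  expect_true(all(abs(by_col$total - total_unmasked) < 1e-9))
  # baseline percent change is zero at every level
  base_pc <- ac$cumulative[ac$cumulative$scenario_id == "baseline", ]
  expect_true(all(base_pc$pct_change_vs_baseline == 0))
})

test_that("halving the suitable area reports -50% at the marginal level", {
  spec <- grid_spec(4, 1, cell_size = 0.1, origin_lon = 0,
                    origin_lat = 0.05)  # near-equator: equal cell areas
  th <- structure(list(tau_optimal = 0.9, tau_intermediate = 0.8,
                       tau_marginal = 0.5, levels = c(0.68, 0.95, 1)),
                  class = "threshold_set")
  base <- matrix(c(0.6, 0.6, 0.6, 0.6), 4, 1)
  fut <- matrix(c(0.6, 0.6, 0.1, 0.1), 4, 1)
  proj <- tibble::tibble(scenario_id = c("baseline", "X"),
                         date = c("2000", "2050"),
                         surface = list(base, fut))
  ac <- compute_area_change(reclassify_surfaces(proj, th), spec)
  marg <- ac$cumulative[ac$cumulative$scenario_id == "X" &
                          ac$cumulative$level == "marginal", ]
  # cosine-latitude correction leaves a ~1e-5 imbalance between rows
  expect_equal(marg$pct_change_vs_baseline, -50, tolerance = 1e-4)
})

test_that("warming run: ratcheted cumulative areas never increase", {
  pb <- projection_bundle()
  cg <- reclassify_surfaces(pb$proj, pb$th, ratchet = TRUE)
  ac <- compute_area_change(cg, pb$spec)
  for (id in c("A1B", "A2A", "B2A")) {
    for (lv in c("optimal", "intermediate", "marginal")) {
      d <- ac$cumulative[ac$cumulative$scenario_id == id &
                           ac$cumulative$level == lv, ]
      d <- d[order(as.numeric(d$date)), ]
      expect_true(all(diff(d$cum_area_km2) <= 1e-9))
    }
  }
  # per-cell exhaustive: every future suitable cell is baseline-suitable
  base_codes <- cg$class_grid[[which(cg$scenario_id == "baseline")]]
  for (i in which(cg$scenario_id != "baseline")) {
    g <- cg$class_grid[[i]]
    expect_true(all(base_codes[!is.na(g) & g > 0] > 0))
  }
})

test_that("cell areas shrink with latitude via the cosine correction", {
  spec <- grid_spec(10, 5, cell_size = 0.5, origin_lon = 0,
                    origin_lat = 60)
  a <- cell_area_km2(spec)
  expect_equal(length(a), 10)
  expect_true(all(diff(a) > 0))   # southward rows (toward equator) larger
  # closed form at the first row center
  lat1 <- 60 - 0.25
  expect_equal(a[1], 111.320 * cos(lat1 * pi / 180) * 0.5 * 110.574 * 0.5)
})
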