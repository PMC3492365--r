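# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

tiny_spec <- function(n = 20, cell = 0.05) {
  grid_spec(n, n, cell_size = cell, origin_lon = 35, origin_lat = 9)
}

# a baseline + specialist-niche bundle reused across modules
niche_landscape <- function(n = 50, cell = 0.02, seed = 42) {
  spec <- grid_spec(n, n, cell_size = cell, origin_lon = 35,
                    origin_lat = 9)
  base <- generate_baseline(spec, seed = seed)
  niche <- default_niche()
  list(spec = spec, base = base, niche = niche,
       truth = true_suitability(base, niche))
}

# fitted model on the standard landscape, cached per session
fitted_bundle <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    land <- niche_landscape(n = 60, seed = 42)
    recs <- sample_occurrences(land$truth, land$spec, 250,
                               clustering = 1, frac_bad = 0,
                               frac_duplicate = 0, seed = 43)
    pres <- extract_at(recs[c("lon", "lat")], land$base)
    bg <- background_sample(land$base, 1500, seed = 44)
    vars <- names(land$base$layers)
    model <- fit_maxent(pres[vars], bg[vars], beta = 1)
    cache <<- c(land, list(recs = recs, pres = pres, bg = bg,
                           vars = vars, model = model))
    cache
  }
})

# shared projection fixture: fitted model + stacks for all scenarios
projection_bundle <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bun <- fitted_bundle()
    scenarios <- default_scenarios()
    stacks <- list()
    for (i in seq_len(nrow(scenarios))) {
      sc <- scenarios[i, ]
      stacks[[paste0(sc$scenario_id, "_", sc$date)]] <-
        generate_future(bun$base, sc)
    }
    proj <- project_scenarios(bun$model, stacks)
    prep <- prepare_occurrences(bun$recs, bun$spec)
    loc_env <- extract_at(prep$localities[c("lon", "lat")], bun$base)
    loc_scores <- predict(bun$model, loc_env[bun$vars])
    th <- derive_thresholds(loc_scores)
    cache <<- c(bun, list(stacks = stacks, proj = proj,
                          localities = prep$localities,
                          loc_scores = loc_scores, th = th))
    cache
  }
})

# brute-force Moran's I with rook adjacency (independent oracle)
morans_i_brute <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xbar <- mean(m)
  num <- 0; w_sum <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (i < nr) { num <- num + (m[i, j] - xbar) * (m[i + 1, j] - xbar) * 2
                    w_sum <- w_sum + 2 }
      if (j < nc) { num <- num + (m[i, j] - xbar) * (m[i, j + 1] - xbar) * 2
                    w_sum <- w_sum + 2 }
    }
  }
  n <- nr * nc
  (n / w_sum) * num / sum((m - xbar)^2)
}

# independent winding-number point-in-polygon (oracle for the even-odd
# implementation; identical for simple polygons)
winding_inside <- function(x, y, ring) {
  px <- ring$lon; py <- ring$lat
  n <- length(px)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (py[i] <= y) {
      if (py[j] > y &&
          (px[j] - px[i]) * (y - py[i]) - (x - px[i]) * (py[j] - py[i]) > 0)
        wn <- wn + 1
    } else {
      if (py[j] <= y &&
          (px[j] - px[i]) * (y - py[i]) - (x - px[i]) * (py[j] - py[i]) < 0)
        wn <- wn - 1
    }
  }
  wn != 0
}
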