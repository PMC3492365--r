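#' Build a run configuration
#'
#' Collects everything one end-to-end run needs: the synthetic landscape
#' (or paths to an occurrence CSV and ASCII-grid stacks), model settings,
#' threshold levels, scenarios, seeds and the output directory. The
#' configuration is validated up front and serialised into the output
#' directory so a run is reproducible from its own artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param grid A [grid_spec()] (synthetic runs).
#' @param scenarios Scenario tibble ([default_scenarios()] by default).
#' @param niche A [true_niche()] or `NULL` for the packaged default.
#' @param n_records Raw records to simulate.
#' @param occurrences_csv Optional path to an existing occurrence CSV
#'   (skips simulation of records).
#' @param n_background Background sample size for the fit.
#' @param beta Regularisation multiplier.
#' @param levels Threshold quantile levels.
#' @param core_fraction Core-locality fraction.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, grid = grid_spec(50, 50, 0.02),
                       scenarios = default_scenarios(), niche = NULL,
                       n_records = 600, occurrences_csv = NULL,
                       n_background = 2000, beta = 1,
                       levels = c(0.68, 0.95, 1.00),
                       core_fraction = 0.1, seed = 1) {
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec",
                                         call. = FALSE)
  need <- c("scenario_id", "date", "temp_delta", "precip_factor",
            "seasonality_delta")
  if (!all(need %in% names(scenarios))) {
    stop("validation error: scenarios table missing columns",
         call. = FALSE)
  }
  if (!"baseline" %in% scenarios$scenario_id) {
    stop("validation error: scenarios must include a baseline row",
         call. = FALSE)
  }
  if (!is.null(occurrences_csv) && !file.exists(occurrences_csv)) {
    stop("validation error: occurrences_csv not found", call. = FALSE)
  }
  structure(list(
    out_dir = out_dir, grid = grid, scenarios = scenarios,
    niche = niche, n_records = n_records,
    occurrences_csv = occurrences_csv,
    n_background = n_background, beta = beta, levels = levels,
    core_fraction = core_fraction, seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Key-value file mirroring the [run_config()] arguments; `grid` is a
#' mapping with `n_rows`, `n_cols`, `cell_size`, `origin_lon`,
#' `origin_lat`.
#'
#' @param path YAML file path.
#' @param out_dir Override for the output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  g <- y$grid
  args <- list(
    out_dir = out_dir %||% y$out_dir,
    grid = grid_spec(g$n_rows, g$n_cols, g$cell_size %||% 0.02,
                     g$origin_lon %||% 34, g$origin_lat %||% 10)
  )
  for (k in c("n_records", "n_background", "beta", "core_fraction",
              "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$levels)) args$levels <- as.numeric(y$levels)
  if (!is.null(y$occurrences_csv)) args$occurrences_csv <- y$occurrences_csv
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default synthetic niche: a montane specialist
#'
#' The packaged ground-truth niche is a narrow specialist — optimum at
#' the cool, climatically stable, moderately moist end of the synthetic
#' landscape, with tolerances of roughly half a layer standard deviation.
#' On the default landscape it occupies only a small fraction of the
#' region (mean true suitability about 0.03, about 1% of cells above
#' 0.5), matching the narrow-endemic character of a montane forest
#' understorey species rather than a widespread generalist.
#'
#' @return A [true_niche()].
#' @export
default_niche <- function() {
  true_niche(
    optimum = c(temp_seasonality = 50, warm_quarter_temp = 20.5,
                dry_month_precip = 32, wet_quarter_temp = 18),
    tolerance = c(temp_seasonality = 7, warm_quarter_temp = 1.1,
                  dry_month_precip = 7, wet_quarter_temp = 1.0),
    max_suitability = 1
  )
}

#' Run the full pipeline
#'
#' Stages: `simulate` (landscape + scenario stacks + records, skipped for
#' real occurrence input) -> `prep` (filter, deduplicate, one-per-cell)
#' -> `fit` (maxent on the samples) -> `thresholds` -> `localities`
#' (projection + classification) -> `areas` -> `core`. Every tabular
#' artifact is written as CSV, the model as JSON, surfaces as ESRI ASCII
#' grids; a manifest records each artifact with its MD5 checksum, stage
#' timings, and — on failure — the failing stage. With `resume = TRUE`
#' stages whose outputs already exist in `out_dir` are skipped.
#'
#' @param config A [run_config()].
#' @param resume Skip stages whose artifacts already exist.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = config$seed, stages = list(),
                   artifacts = list(), status = "running")
  path_of <- function(f) file.path(config$out_dir, f)
  register <- function(files) {
    for (f in files) {
      p <- path_of(f)
      if (dir.exists(p)) {
        inner <- list.files(p, recursive = TRUE)
        for (g in inner) {
          manifest$artifacts[[file.path(f, g)]] <<-
            unname(tools::md5sum(file.path(p, g)))
        }
      } else {
        manifest$artifacts[[f]] <<- unname(tools::md5sum(p))
      }
    }
  }
  save_manifest <- function() {
    jsonlite::write_json(manifest, path_of("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, outputs, fun) {
    if (resume && all(file.exists(path_of(outputs)))) {
      manifest$stages[[name]] <<- list(status = "skipped")
      register(outputs)
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$status <<- paste0("failed:", name)
      save_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, "secs")), 2))
    register(outputs)
    invisible(NULL)
  }

  env <- new.env()
  # yaml-serialisable copy of the config for reproducibility
  yaml::write_yaml(list(
    grid = config$grid[c("n_rows", "n_cols", "cell_size", "origin_lon",
                         "origin_lat")],
    n_records = config$n_records, n_background = config$n_background,
    beta = config$beta, levels = config$levels,
    core_fraction = config$core_fraction, seed = config$seed
  ), path_of("run_config.yaml"))

  run_stage("simulate", c("occurrences_raw.csv", "stack_baseline_2000",
                          "true_suitability.asc"), function() {
    env$baseline <- generate_baseline(config$grid, seed = config$seed)
    env$niche <- config$niche %||% default_niche()
    env$truth <- true_suitability(env$baseline, env$niche)
    write_ascii_grid(env$truth, config$grid, path_of("true_suitability.asc"))
    env$stacks <- list()
    for (i in seq_len(nrow(config$scenarios))) {
      sc <- config$scenarios[i, ]
      nm <- paste0(sc$scenario_id, "_", sc$date)
      env$stacks[[nm]] <- generate_future(env$baseline, sc)
      dir.create(path_of(paste0("stack_", nm)), showWarnings = FALSE)
      for (ly in names(env$stacks[[nm]]$layers)) {
        write_ascii_grid(env$stacks[[nm]]$layers[[ly]], config$grid,
                         path_of(file.path(paste0("stack_", nm),
                                           paste0(ly, ".asc"))))
      }
    }
    env$records <- if (is.null(config$occurrences_csv)) {
      sample_occurrences(env$truth, config$grid, config$n_records,
                         seed = config$seed + 1)
    } else read_occurrences(config$occurrences_csv)
    write_occurrences(env$records, path_of("occurrences_raw.csv"))
  })

  run_stage("prep", c("localities.csv", "samples.csv", "rejected.csv"),
            function() {
    prep <- prepare_occurrences(env$records, config$grid)
    env$localities <- prep$localities
    env$samples <- prep$samples
    utils::write.csv(
      dplyr::select(prep$localities, -"member_record_ids"),
      path_of("localities.csv"), row.names = FALSE)
    utils::write.csv(dplyr::select(prep$samples, -"member_record_ids"),
                     path_of("samples.csv"), row.names = FALSE)
    utils::write.csv(prep$rejected[c("record_id", "reason")],
                     path_of("rejected.csv"), row.names = FALSE)
  })

  run_stage("fit", "model.json", function() {
    baseline <- env$stacks[["baseline_2000"]]
    pres_env <- extract_at(env$samples[c("lon", "lat")], baseline)
    env$bg <- background_sample(baseline, config$n_background,
                                seed = config$seed + 2)
    vars <- names(baseline$layers)
    env$model <- fit_maxent(pres_env[vars], env$bg[vars],
                            beta = config$beta)
    write_model(env$model, path_of("model.json"))
  })

  run_stage("thresholds", "thresholds.json", function() {
    baseline <- env$stacks[["baseline_2000"]]
    loc_env <- extract_at(env$localities[c("lon", "lat")], baseline)
    env$loc_scores <- predict(env$model,
                              loc_env[names(baseline$layers)])
    env$thresholds <- derive_thresholds(env$loc_scores, config$levels)
    jsonlite::write_json(unclass(env$thresholds),
                         path_of("thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  run_stage("localities", c("locality_classes.csv",
                            "classification_table.csv"), function() {
    env$projections <- project_scenarios(env$model, env$stacks)
    tab <- tabulate_localities(env$localities, env$projections,
                               env$thresholds, config$grid)
    env$trajectories <- tab$trajectories
    env$class_table <- tab$table
    utils::write.csv(tab$trajectories, path_of("locality_classes.csv"),
                     row.names = FALSE)
    utils::write.csv(tab$table, path_of("classification_table.csv"),
                     row.names = FALSE)
  })

  run_stage("areas", c("area_change.csv", "class_grids"), function() {
    cg <- reclassify_surfaces(env$projections, env$thresholds)
    env$area <- compute_area_change(cg, config$grid)
    utils::write.csv(env$area$cumulative, path_of("area_change.csv"),
                     row.names = FALSE)
    dir.create(path_of("class_grids"), showWarnings = FALSE)
    for (i in seq_len(nrow(cg))) {
      g <- cg$class_grid[[i]]
      write_ascii_grid(g, config$grid,
                       path_of(file.path("class_grids",
                                         sprintf("%s_%s.asc",
                                                 cg$scenario_id[i],
                                                 cg$date[i]))))
    }
  })

  run_stage("core", "core_localities.csv", function() {
    core <- score_core(env$trajectories, config$core_fraction)
    utils::write.csv(core, path_of("core_localities.csv"),
                     row.names = FALSE)
  })

  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  save_manifest()
  invisible(manifest)
}

#' Seeded uniform background sample from a stack
#'
#' Uniform random non-nodata cells (with replacement when the request
#' exceeds the cell count), the standard background for
#' presence-background fitting.
#'
#' @param stack A [clim_stack()].
#' @param n Number of background points.
#' @param seed Integer seed.
#' @return A tibble of cell-center environments (`lon`, `lat`, layers).
#' @export
background_sample <- function(stack, n = 10000, seed = 1) {
  env <- as_tibble.clim_stack(stack)
  ok <- stats::complete.cases(env[names(stack$layers)])
  env <- env[ok, ]
  withr_seed(seed)
  env[sample.int(nrow(env), min(n, nrow(env))), ]
}
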