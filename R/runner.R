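run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "latsecr-run",
    stages = c("simulate", "prepare", "fit", "exposure", "posthoc"),
    min_days = 5L,
    grid = list(lat_origin = 44.33, bin_width = 0.01, n_bins = 55),
    scenario = list(),
    model = list(n_chains = 3L, n_iter = 400000L, burn_in = 50000L,
                 thin = 100L, priors = list(), absent_center_deg = 52,
                 absent_sigma2 = 0.001, effort_scale_factor = 10),
    paths = list(sightings = NULL, effort = NULL, layers = NULL, labels = NULL)
  )
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Build or load a validated pipeline configuration
#'
#' `run_config()` fills defaults and validates; `load_config()` reads a YAML
#' file and passes it through `run_config()`; `write_config()` writes a
#' config back to YAML so that write/read round-trips are exact. Unknown
#' keys at any level are rejected by name.
#'
#' @param ... Configuration entries overriding the defaults: `seed`,
#'   `out_dir`, `stages`, `min_days`, and the nested lists `grid`,
#'   `scenario` (passed to [sim_scenario()]), `model` (passed to
#'   [model_config()], with `priors` passed to [prior_spec()]) and `paths`
#'   (`sightings`, `effort`, `layers`, `labels` inputs used when the
#'   simulate stage is skipped).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  defs <- run_config_defaults()
  check_keys(user, names(defs), "the top level")
  cfg <- utils::modifyList(defs, user, keep.null = TRUE)
  check_keys(cfg$grid, c("lat_origin", "bin_width", "n_bins"), "grid")
  check_keys(cfg$scenario,
             setdiff(names(formals(sim_scenario)), "seed"), "scenario")
  check_keys(cfg$model,
             c("n_chains", "n_iter", "burn_in", "thin", "priors",
               "absent_center_deg", "absent_sigma2", "effort_scale_factor"),
             "model")
  check_keys(cfg$model$priors, names(formals(prior_spec)), "model$priors")
  check_keys(cfg$paths, c("sightings", "effort", "layers", "labels"), "paths")
  bad_stage <- setdiff(cfg$stages, run_config_defaults()$stages)
  if (length(bad_stage)) {
    stop(sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")),
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_days <- as.integer(cfg$min_days)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path A YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_grid <- function(config) {
  lat_grid(config$grid$lat_origin, config$grid$bin_width, config$grid$n_bins)
}

pipeline_scenario <- function(config) {
  do.call(sim_scenario, c(
    config$scenario,
    list(seed = config$seed,
         lat_origin = config$grid$lat_origin,
         bin_width_deg = config$grid$bin_width,
         n_bins = config$grid$n_bins)
  ))
}

#' Run the simulate-prepare-fit-exposure-posthoc pipeline
#'
#' Executes the requested stages in order under one seed, writing each
#' stage's outputs as delimited text under `out_dir` and finishing with a
#' JSON manifest listing every output file with its MD5 checksum, the seed
#' and the configuration echo. Re-running with the same configuration and
#' seed reproduces all outputs byte for byte. When the simulate stage is
#' skipped, input tables are read from `paths$sightings`, `paths$effort`
#' and, for the exposure stage, the layer files in `paths$layers`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages (default FALSE).
#' @return The manifest, invisibly (a list; also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- pipeline_grid(config)
  stages <- config$stages
  run_stage <- function(stage, expr) {
    say("stage %s ...", stage)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sightings <- effort <- layers <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", {
      ds <- simulate_dataset(pipeline_scenario(config))
      sightings <- ds$sightings; effort <- ds$effort; layers <- ds$stressors
      dir.create(file.path(config$out_dir, "data"), showWarnings = FALSE)
      write_sightings(ds$sightings, file.path(config$out_dir, "data", "sightings.csv"))
      write_effort(ds$effort, file.path(config$out_dir, "data", "effort.csv"))
      write_truth(ds$truth, file.path(config$out_dir, "data", "truth.csv"))
      for (ly in ds$stressors) {
        write_layer(ly, file.path(config$out_dir, "data",
                                  paste0("layer_", layer_name(ly), ".csv")))
      }
    })
  } else {
    if (!is.null(config$paths$sightings)) sightings <- read_sightings(config$paths$sightings)
    if (!is.null(config$paths$effort)) effort <- read_effort(config$paths$effort)
    if (!is.null(config$paths$layers)) {
      layers <- lapply(list.files(config$paths$layers, "\\.csv$",
                                  full.names = TRUE), read_layer)
    }
  }

  data <- fit <- NULL
  if ("prepare" %in% stages) {
    run_stage("prepare", {
      if (is.null(sightings) || is.null(effort)) {
        stop("prepare needs sightings and effort (simulate them or set paths)")
      }
      binned <- assign_latitude_bins(sightings, grid)
      data <- build_encounter_array(binned, effort, grid, config$min_days)
      write_encounters(data, file.path(config$out_dir, "encounters"))
    })
  }

  if ("fit" %in% stages) {
    run_stage("fit", {
      if (is.null(data)) stop("fit needs the prepare stage")
      mc <- config$model
      mcfg <- model_config(
        n_chains = mc$n_chains, n_iter = mc$n_iter, burn_in = mc$burn_in,
        thin = mc$thin, seed = config$seed,
        priors = do.call(prior_spec, mc$priors),
        absent_center_deg = mc$absent_center_deg,
        absent_sigma2 = mc$absent_sigma2,
        effort_scale_factor = mc$effort_scale_factor
      )
      fit <- secr_fit(data, mcfg)
      write_posterior(fit, file.path(config$out_dir, "posterior.csv"))
      diag <- dplyr::left_join(gelman_rubin(fit),
                               effective_sample_size(fit),
                               by = "parameter")
      readr::write_csv(diag, file.path(config$out_dir, "diagnostics.csv"))
    })
  }

  if ("exposure" %in% stages) {
    run_stage("exposure", {
      if (is.null(fit)) stop("exposure needs the fit stage")
      su <- space_use_distribution(fit)
      readr::write_csv(tibble::as_tibble(su),
                       file.path(config$out_dir, "space_use.csv"))
      if (!is.null(layers)) {
        exp_tbl <- purrr::map(layers, function(ly) {
          tibble::as_tibble(exposure_distribution(fit, scale_layer(ly)))
        }) |> dplyr::bind_rows()
        readr::write_csv(exp_tbl, file.path(config$out_dir, "exposure.csv"))
      }
    })
  }

  if ("posthoc" %in% stages) {
    run_stage("posthoc", {
      if (is.null(fit)) stop("posthoc needs the fit stage")
      readr::write_csv(range_summaries(fit),
                       file.path(config$out_dir, "ranges.csv"))
      if (!is.null(config$paths$labels)) {
        labels <- readr::read_csv(config$paths$labels,
                                  col_types = readr::cols())
        ct <- group_center_contrast(fit, labels)
        readr::write_csv(ct$summary, file.path(config$out_dir, "contrast.csv"))
      }
    })
  }

  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    outputs = lapply(files, function(f) {
      list(path = f,
           md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %d output files", length(files))
  invisible(manifest)
}
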