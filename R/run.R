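bmc_log <- function(..., level = "info") {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  cur <- getOption("boldmc.log_level", "info")
  if (levels[[level]] <= levels[[cur]] && cur != "quiet")
    message("[boldmc] ", ...)
  invisible(NULL)
}

#' Read and validate a run configuration
#'
#' Configurations are YAML files (or equivalent lists) declaring the input
#' paths and the two candidate models of a comparison run:
#'
#' ```yaml
#' events: events.tsv        # BIDS-style event table
#' series: series.tsv        # TSV time series; or volume: + mask: (NIfTI)
#' trial_type: feedback      # which trial type carries the reward column
#' models:
#'   A: {name: RO,  source: modulation}
#'   B: {name: RPE, source: rw, alpha: 0.5, v0: 0}
#' dt: 1.0
#' tie_tolerance: 1.0e-6
#' seed: 1
#' ```
#'
#' A model with `source: modulation` uses the trial type's modulation column
#' directly; `source: rw` treats that column as reward receipts and derives
#' per-trial Rescorla-Wagner prediction errors with the given `alpha` and
#' `v0`. Relative paths are resolved against the config file's directory.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return validated config list.
#' @export
read_config <- function(config) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$models) || length(config$models) != 2L)
    stop("config must declare exactly two candidate models", call. = FALSE)
  if (is.null(names(config$models)))
    names(config$models) <- c("A", "B")
  nms <- vapply(config$models, function(m) m$name %||% "", "")
  if (any(!nzchar(nms)) || nms[1] == nms[2])
    stop("each model needs a distinct 'name'", call. = FALSE)
  for (field in c("events", "series", "volume", "mask"))
    if (!is.null(config[[field]]) && !grepl("^(/|~)", config[[field]]))
      config[[field]] <- file.path(base, config[[field]])
  config$trial_type <- config$trial_type %||% NULL
  config$dt <- config$dt %||% 1
  config$tie_tolerance <- as.numeric(config$tie_tolerance %||% 1e-6)
  config$use_abs <- isTRUE(config$use_abs)
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build one candidate's standardized regressor from the shared event table.
build_model_regressor <- function(ev, model, total_duration, dt) {
  source <- model$source %||% "modulation"
  mods <- switch(source,
    modulation = ev$modulations,
    rw = rw_trace(ev$modulations, alpha = model$alpha %||% 0.5,
                  v0 = model$v0 %||% 0)$deltas,
    stop("unknown model source '", source, "' (use 'modulation' or 'rw')",
         call. = FALSE)
  )
  ev2 <- event_spec(ev$onsets, ev$durations, mods, label = model$name)
  zscore(build_regressor(ev2, total_duration, dt = dt))
}

# Events + config -> the standardized candidate pair (A, B).
config_regressors <- function(config, total_duration) {
  evs <- read_events(config$events)
  tt <- config$trial_type %||% names(evs)[1]
  if (is.null(evs[[tt]]))
    stop("trial type '", tt, "' not present in ", config$events,
         call. = FALSE)
  ev <- evs[[tt]]
  list(A = build_model_regressor(ev, config$models[[1]], total_duration,
                                 config$dt),
       B = build_model_regressor(ev, config$models[[2]], total_duration,
                                 config$dt))
}

#' Run a full comparison from a configuration
#'
#' Builds both candidate regressors from the event table, z-standardizes
#' them, runs all three comparison approaches on every series column, and
#' writes `report.json` (keys sorted; no timestamp, so reruns are
#' byte-identical) and a flat `report.tsv` (one row per region x approach)
#' to `out_dir`. Partial outputs are removed if any step fails.
#'
#' @param config path to a YAML config or a config list (see
#'   [read_config()]).
#' @param out_dir output directory.
#' @return named list of `comparison_report`s, invisibly.
#' @export
run_compare <- function(config, out_dir) {
  config <- read_config(config)
  if (is.null(config$events) || is.null(config$series))
    stop("compare run needs 'events' and 'series' paths in the config",
         call. = FALSE)
  series <- read_series(config$series)
  n <- length(series[[1]])
  total_duration <- config$total_duration %||% (n * config$dt)
  regs <- config_regressors(config, total_duration)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "report.json")
  tsv_path <- file.path(out_dir, "report.tsv")
  ok <- FALSE
  on.exit(if (!ok) unlink(c(json_path, tsv_path)), add = TRUE)

  reports <- lapply(names(series), function(nm)
    run_report(series[[nm]], regs$A, regs$B,
               tie_tolerance = config$tie_tolerance,
               use_abs = config$use_abs, region = nm))
  names(reports) <- names(series)

  bmc_log("compare: ", length(reports), " series, r = ",
          sprintf("%.3f", reports[[1]]$diagnostics$r),
          ", n = ", reports[[1]]$diagnostics$n,
          ", k = ", reports[[1]]$diagnostics$k,
          ", seed = ", config$seed)

  json <- lapply(reports, function(rep) sort_keys(list(
    model_A = rep$model_A, model_B = rep$model_B,
    agreement = rep$agreement, diagnostics = rep$diagnostics,
    approaches = lapply(rep$results, function(res) list(
      statistic_A = res$statistic_A, statistic_B = res$statistic_B,
      margin = res$margin,
      winner = c(A = res$model_A, B = res$model_B, tie = "tie")[[res$winner]]
    ))
  )))
  jsonlite::write_json(sort_keys(json), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  flat <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ok <- TRUE
  invisible(reports)
}

#' Simulate a dataset from a configuration
#'
#' Generates the two-region ground-truth dataset (see [two_region_fixture()]),
#' optionally overriding its parameters from the config, and writes
#' `events.tsv`, `series.tsv` and `provenance.json` to `out_dir`. With
#' `write_volume: true` in the config, additionally writes the tiled 4D
#' volume (`volume.nii.gz`), its mask and true block labels as NIfTI.
#'
#' @param config path to a YAML config or list; may be `NULL` for all
#'   defaults. Recognized keys: `seed`, `noise_sd`, `dt`, `total_duration`,
#'   `alpha`, `rewards`, `onsets`, `weights`, `write_volume`.
#' @param out_dir output directory.
#' @param seed overrides the config seed when non-NULL.
#' @return the `simulated_dataset`, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  if (!is.null(seed)) config$seed <- seed
  args <- config[intersect(names(config),
                           names(formals(two_region_fixture)))]
  ds <- do.call(two_region_fixture, args)
  write_dataset(ds, out_dir)
  if (isTRUE(config$write_volume)) {
    vol <- simulate_volume(ds, seed = ds$config$seed)
    RNifti::writeNifti(RNifti::asNifti(vol$volume),
                       file.path(out_dir, "volume.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol$mask),
                       file.path(out_dir, "mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol$labels),
                       file.path(out_dir, "labels.nii.gz"))
  }
  bmc_log("simulate: wrote ", out_dir, " (seed = ", ds$config$seed, ")")
  invisible(ds)
}

#' Voxelwise model comparison over a 4D volume
#'
#' Runs the three comparison approaches independently on every voxel inside
#' the mask and writes, per approach, an integer winner map (0 = tie,
#' 1 = model A, 2 = model B) and a real-valued margin map as NIfTI volumes
#' named `winner_<approach>.nii.gz` / `margin_<approach>.nii.gz`.
#'
#' @param config path to a YAML config or list with `events`, `volume`,
#'   `mask` and model declarations (see [read_config()]).
#' @param out_dir output directory.
#' @return named list of 3D winner arrays, invisibly.
#' @export
run_voxelwise <- function(config, out_dir) {
  config <- read_config(config)
  if (is.null(config$events) || is.null(config$volume) ||
      is.null(config$mask))
    stop("voxelwise run needs 'events', 'volume' and 'mask' in the config",
         call. = FALSE)
  vol <- RNifti::readNifti(config$volume)
  mask <- RNifti::readNifti(config$mask)
  vdim <- dim(vol)
  if (length(vdim) != 4L)
    stop("'volume' must be a 4D image", call. = FALSE)
  if (!identical(as.integer(dim(mask)), as.integer(vdim[1:3])))
    stop("'mask' grid does not match the volume grid", call. = FALSE)

  nt <- vdim[4]
  total_duration <- config$total_duration %||% (nt * config$dt)
  regs <- config_regressors(config, total_duration)

  approaches <- c("orthogonalized_betas", "nonorthogonalized_betas",
                  "residual_variance")
  winners <- lapply(approaches, function(a) array(0L, dim = vdim[1:3]))
  margins <- lapply(approaches, function(a) array(0, dim = vdim[1:3]))
  names(winners) <- names(margins) <- approaches

  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("mask selects no voxels; writing empty maps", call. = FALSE)
  } else {
    for (i in seq_len(nrow(idx))) {
      co <- idx[i, ]
      y <- vol[co[1], co[2], co[3], ]
      rep <- run_report(y, regs$A, regs$B,
                        tie_tolerance = config$tie_tolerance,
                        use_abs = config$use_abs)
      for (a in approaches) {
        res <- rep$results[[a]]
        winners[[a]][co[1], co[2], co[3]] <-
          c(A = 1L, B = 2L, tie = 0L)[[res$winner]]
        margins[[a]][co[1], co[2], co[3]] <- res$margin
      }
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (a in approaches) {
    RNifti::writeNifti(RNifti::asNifti(winners[[a]], reference = mask),
                       file.path(out_dir, paste0("winner_", a, ".nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(margins[[a]], reference = mask),
                       file.path(out_dir, paste0("margin_", a, ".nii.gz")))
  }
  bmc_log("voxelwise: ", nrow(idx), " voxels compared")
  invisible(winners)
}
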