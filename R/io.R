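CONFIG_SCALAR_KEYS <- c(
  "inhibitory_fraction", "reference_weight_nS", "overlap_fraction", "overlap_seed",
  "mechanism_mode", "weight_handling", "duration_ms", "timestep_ms",
  "n_runs", "seed", "redraw_connectivity_per_run"
)
CONFIG_TABLE_KEYS <- c("synapses", "populations", "ensembles", "projections")
CONFIG_KEYS <- c("neuron", CONFIG_TABLE_KEYS, CONFIG_SCALAR_KEYS,
                 "amplitude_projections")

#' Write a circuit configuration to YAML
#'
#' The file mirrors the configuration field-for-field; units are fixed
#' (ms, mV, nS, pA, pF, Hz) and encoded in the key names.
#'
#' @param config A `circuit_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  obj <- unclass(config)
  for (k in CONFIG_TABLE_KEYS) obj[[k]] <- as.data.frame(obj[[k]])
  if (!is.null(obj$amplitude_projections)) {
    obj$amplitude_projections <- as.data.frame(obj$amplitude_projections)
  }
  yaml::write_yaml(obj, path, column.major = FALSE)
  invisible(path)
}

#' Load a circuit configuration from YAML
#'
#' Missing fields are filled from [default_config()]; unknown keys and
#' out-of-range values are rejected with named errors. An empty file yields
#' the full default configuration.
#'
#' @param path Path to a YAML config file.
#' @return A validated `circuit_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  obj <- yaml::read_yaml(path)
  cfg <- default_config()
  if (is.null(obj)) return(cfg)
  unknown <- setdiff(names(obj), CONFIG_KEYS)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(obj$neuron)) {
    bad <- setdiff(names(obj$neuron), names(cfg$neuron))
    if (length(bad)) abort(sprintf("unknown neuron key(s): %s", paste(bad, collapse = ", ")))
    cfg$neuron[names(obj$neuron)] <- obj$neuron
  }
  for (k in CONFIG_TABLE_KEYS) {
    if (!is.null(obj[[k]])) {
      tbl <- dplyr::bind_rows(lapply(obj[[k]], as_tibble))
      template <- cfg[[k]]
      bad <- setdiff(names(tbl), names(template))
      if (length(bad)) {
        abort(sprintf("unknown column(s) in '%s': %s", k, paste(bad, collapse = ", ")))
      }
      for (col in names(template)) {
        if (!col %in% names(tbl)) {
          abort(sprintf("config table '%s' is missing column '%s'", k, col))
        }
      }
      tbl <- tbl[names(template)]
      for (col in names(template)) {
        mode(tbl[[col]]) <- mode(template[[col]])
        if (is.integer(template[[col]])) tbl[[col]] <- as.integer(tbl[[col]])
      }
      cfg[[k]] <- tbl
    }
  }
  for (k in CONFIG_SCALAR_KEYS) {
    if (!is.null(obj[[k]])) {
      val <- obj[[k]]
      if (is.integer(cfg[[k]]) && !is.null(val)) val <- as.integer(val)
      cfg[[k]] <- val
    }
  }
  if (!is.null(obj$amplitude_projections)) {
    cfg$amplitude_projections <- dplyr::bind_rows(
      lapply(obj$amplitude_projections, as_tibble))
  }
  validate_config(cfg)
  cfg
}

#' Hash of the canonical configuration serialisation
#' @param config A `circuit_config`.
#' @return A character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(jsonlite::toJSON(unclass(config), digits = NA, force = TRUE))
}

#' Write a spike raster to CSV
#'
#' Columns `neuron_id,population,time_ms`; times with fixed three-decimal
#' precision (the integration grid is coarser).
#'
#' @param sim A `vh_sim` (or its raster tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(sim, path) {
  raster <- if (inherits(sim, "vh_sim")) sim$raster else as_tibble(sim)
  raster$time_ms <- sprintf("%.3f", raster$time_ms)
  utils::write.csv(raster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-population totals to JSON
#' @param sim A `vh_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(sim, path) {
  totals <- stats::setNames(as.list(sim$summary$total_spikes),
                            sim$summary$population)
  jsonlite::write_json(totals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write recorded membrane traces to CSV
#'
#' Wide format: a `time_ms` column followed by one column per recorded
#' neuron id, values in mV with fixed three-decimal precision.
#'
#' @param sim A `vh_sim` simulated with `record_vm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vm <- function(sim, path) {
  if (is.null(sim$vm)) abort("simulation was run without record_vm")
  wide <- tidyr::pivot_wider(sim$vm, names_from = "neuron_id",
                             values_from = "vm_mV")
  wide[] <- lapply(wide, function(x) sprintf("%.3f", x))
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write sweep results to tidy CSV with a JSON sidecar
#'
#' CSV columns: `parameter,value,run,population,total_spikes`. The sidecar
#' (`<path>.json`) records the master seed, config hash, grid and package
#' version for provenance.
#'
#' @param sweep A `vh_sweep`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  tbl <- as_tibble(sweep)[, c("parameter", "value", "run", "population",
                              "total_spikes")]
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  cfg <- attr(sweep, "base_config")
  sidecar <- list(
    swept_parameter = attr(sweep, "swept_parameter"),
    master_seed = attr(sweep, "master_seed"),
    grid = sort(unique(tbl$value)),
    config_hash = if (!is.null(cfg)) config_hash(cfg) else NULL,
    package_version = as.character(utils::packageVersion("vhgate"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read sweep results written by [write_sweep()]
#' @param path CSV path.
#' @return A `vh_sweep` tibble (attributes restored from the sidecar when
#'   present).
#' @export
read_sweep <- function(path) {
  tbl <- as_tibble(utils::read.csv(path))
  sidecar <- paste0(path, ".json")
  ms <- NA_integer_
  sp <- "inhibitory_fraction"
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ms <- meta$master_seed %||% NA_integer_
    sp <- meta$swept_parameter %||% sp
  }
  new_sweep(tbl, ms, NULL, swept_parameter = sp)
}

#' Write a sweep trace (plus metadata sidecar) to CSV
#'
#' CSV columns `time_ms,value`; the JSON sidecar carries sampling rate,
#' onsets, polarity, windows, units and trial count, which [read_trace()]
#' validates on the way back in.
#'
#' @param trace A [sweep_trace()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sweep_trace"))
  utils::write.csv(trace$data, path, row.names = FALSE, quote = FALSE)
  meta <- trace[c("sampling_rate_Hz", "stimulus_onsets_ms", "polarity",
                  "baseline_window_ms", "response_window_ms", "units",
                  "n_trials")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sweep trace written by [write_trace()]
#' @param path CSV path (expects `<path>.json` sidecar).
#' @return A [sweep_trace()].
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort(sprintf("missing trace sidecar '%s'", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!meta$units %in% c("pA", "mV")) abort("trace sidecar has unknown units")
  tbl <- utils::read.csv(path)
  sweep_trace(tbl$value, meta$sampling_rate_Hz, meta$stimulus_onsets_ms,
              polarity = meta$polarity,
              baseline_window_ms = meta$baseline_window_ms,
              response_window_ms = meta$response_window_ms,
              units = meta$units, n_trials = meta$n_trials)
}

#' Write a trajectory (plus arena sidecar) to CSV
#' @param trajectory Tibble `time_s,x_cm,y_cm` with arena attributes.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as_tibble(trajectory)[, c("time_s", "x_cm", "y_cm")],
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(arena = attr(trajectory, "arena"),
               stim_side = attr(trajectory, "stim_side"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#' @param path CSV path.
#' @return Trajectory tibble with arena attributes restored.
#' @export
read_trajectory <- function(path) {
  tbl <- as_tibble(utils::read.csv(path))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(tbl, "arena") <- as.list(meta$arena)
    attr(tbl, "stim_side") <- meta$stim_side
  }
  tbl
}

#' Write a run manifest
#'
#' Records everything needed to regenerate an output set: subcommand,
#' master seed, config hash, package version, timestamps and output files.
#' Written atomically (temp file + rename).
#'
#' @param dir Output directory.
#' @param subcommand Character tag of the producing command.
#' @param master_seed Integer seed.
#' @param config A `circuit_config` or `NULL`.
#' @param outputs Character vector of produced file names.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, subcommand, master_seed, config, outputs) {
  manifest <- list(
    subcommand = subcommand,
    master_seed = master_seed,
    config_hash = if (!is.null(config)) config_hash(config) else NULL,
    package_version = as.character(utils::packageVersion("vhgate")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  path <- file.path(dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}
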