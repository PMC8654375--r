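#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation: the spike raster
#' @param x A `vh_sim`.
#' @param ... Unused.
#' @return The raster tibble (`neuron_id`, `population`, `time_ms`).
#' @export
tidy.vh_sim <- function(x, ...) x$raster

#' One-row simulation summary
#' @param x A `vh_sim`.
#' @param ... Unused.
#' @return One-row tibble with duration, timestep, seed and per-population
#'   totals in wide form.
#' @export
glance.vh_sim <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary[, c("population", "total_spikes")],
                             names_from = "population",
                             values_from = "total_spikes")
  dplyr::bind_cols(
    tibble(duration_ms = x$duration_ms, timestep_ms = x$timestep_ms,
           seed = x$seed, n_spikes = sum(x$summary$total_spikes)),
    wide
  )
}

#' Tidy sweep results
#' @param x A `vh_sweep`.
#' @param ... Unused.
#' @return A plain tibble of per-run per-population totals.
#' @export
tidy.vh_sweep <- function(x, ...) as_tibble(x)

#' One-row sweep summary with the peak of the vH-NAc minus vH-BA difference
#' @param x A `vh_sweep`.
#' @param ... Unused.
#' @return One-row tibble: grid size, runs, master seed, `peak_value`,
#'   `mean_difference`.
#' @export
glance.vh_sweep <- function(x, ...) {
  pk <- find_peak_difference(x)
  tibble(
    n_grid = length(unique(x$value)),
    n_runs = max(x$run),
    master_seed = attr(x, "master_seed"),
    peak_value = pk$peak_value,
    mean_difference = pk$mean_difference
  )
}

#' Tidy a silencing experiment
#' @param x A `vh_silencing`.
#' @param ... Unused.
#' @return A plain tibble of per-condition per-run totals.
#' @export
tidy.vh_silencing <- function(x, ...) as_tibble(x)

#' Condition contrast for a silencing experiment
#' @param x A `vh_silencing`.
#' @param ... Unused.
#' @return One row per population: mean totals in the intact and silenced
#'   conditions and their difference.
#' @export
glance.vh_silencing <- function(x, ...) {
  as_tibble(x) |>
    dplyr::group_by(.data$population, .data$condition) |>
    dplyr::summarise(mean_total = mean(.data$total_spikes), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_total") |>
    dplyr::mutate(difference = .data$silenced - .data$intact,
                  silenced_population = attr(x, "silenced"))
}

#' Tidy intrinsic properties: spike counts per step
#' @param x An `intrinsic_properties`.
#' @param ... Unused.
#' @return The `spikes_per_step` tibble.
#' @export
tidy.intrinsic_properties <- function(x, ...) x$spikes_per_step

#' One-row intrinsic-property summary
#' @param x An `intrinsic_properties`.
#' @param ... Unused.
#' @return One-row tibble: `resting_mV`, `input_resistance_MOhm`, `sag_mV`.
#' @export
glance.intrinsic_properties <- function(x, ...) {
  tibble(resting_mV = x$resting_mV,
         input_resistance_MOhm = x$input_resistance_MOhm,
         sag_mV = x$sag_mV)
}
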