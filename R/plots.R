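POPULATION_COLOURS <- c(
  "vH-BA" = "#2e7d32", "vH-NAc" = "#c62828", "vH-PFC" = "#757575",
  "interneuron" = "#ef6c00"
)

#' Raster plot of a simulation
#'
#' @param object A `vh_sim`.
#' @param ... Unused.
#' @return A ggplot: spike times by neuron, coloured by population.
#' @export
autoplot.vh_sim <- function(object, ...) {
  ggplot2::ggplot(object$raster,
                  ggplot2::aes(x = .data$time_ms, y = .data$neuron_id,
                               colour = .data$population)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::scale_colour_manual(values = POPULATION_COLOURS) +
    ggplot2::labs(x = "time (ms)", y = "neuron",
                  title = sprintf("spike raster, %g ms", object$duration_ms)) +
    ggplot2::theme_minimal()
}

#' Population totals across an inhibition sweep
#'
#' The summary figure of the in-silico experiment: run-averaged total
#' spikes per population against the inhibitory input proportion.
#'
#' @param object A `vh_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vh_sweep <- function(object, ...) {
  agg <- as_tibble(object) |>
    dplyr::group_by(.data$value, .data$population) |>
    dplyr::summarise(mean_total = mean(.data$total_spikes),
                     sem = stats::sd(.data$total_spikes) /
                       sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$value, y = .data$mean_total,
                                    colour = .data$population)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_total - .data$sem,
                                      ymax = .data$mean_total + .data$sem,
                                      fill = .data$population),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = POPULATION_COLOURS) +
    ggplot2::scale_fill_manual(values = POPULATION_COLOURS) +
    ggplot2::labs(x = attr(object, "swept_parameter") %||% "value",
                  y = "total spikes (mean ± SEM across runs)") +
    ggplot2::theme_minimal()
}

#' Plot a sweep trace with its analysis windows
#'
#' @param trace A [sweep_trace()].
#' @param call Optional result of [detect_connection()] to annotate.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, call = NULL) {
  stopifnot(inherits(trace, "sweep_trace"))
  onset <- trace$stimulus_onsets_ms[1]
  win <- onset + trace$response_window_ms
  p <- ggplot2::ggplot(trace$data,
                       ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::annotate("rect", xmin = trace$baseline_window_ms[1],
                      xmax = trace$baseline_window_ms[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "grey40") +
    ggplot2::annotate("rect", xmin = win[1], xmax = win[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "#1565c0") +
    ggplot2::geom_vline(xintercept = trace$stimulus_onsets_ms,
                        linetype = "dotted", colour = "#1565c0") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = trace$units) +
    ggplot2::theme_minimal()
  if (!is.null(call)) {
    p <- p + ggplot2::ggtitle(sprintf(
      "%s (amplitude %.1f %s, baseline SD %.2f)",
      if (call$connected) "connected" else "not connected",
      call$amplitude, trace$units, call$baseline_sd))
  }
  p
}

#' Plot a place-preference trajectory
#'
#' @param trajectory A trajectory tibble (see [make_trajectory()]).
#' @return A ggplot with the stimulation side shaded.
#' @export
plot_trajectory <- function(trajectory) {
  arena <- attr(trajectory, "arena") %||%
    list(width_cm = max(trajectory$x_cm), height_cm = max(trajectory$y_cm))
  stim_side <- attr(trajectory, "stim_side") %||% "right"
  mid <- arena$width_cm / 2
  xmin <- if (identical(stim_side, "right")) mid else 0
  ggplot2::ggplot(as_tibble(trajectory),
                  ggplot2::aes(x = .data$x_cm, y = .data$y_cm)) +
    ggplot2::annotate("rect", xmin = xmin, xmax = xmin + mid,
                      ymin = 0, ymax = arena$height_cm,
                      alpha = 0.15, fill = "#1565c0") +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.2) +
    ggplot2::coord_fixed(xlim = c(0, arena$width_cm),
                         ylim = c(0, arena$height_cm)) +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}
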