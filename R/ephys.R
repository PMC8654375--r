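#' Construct a sweep trace
#'
#' Container for one trial-averaged voltage-clamp or current-clamp record:
#' a regularly sampled series with stimulus annotations and the analysis
#' windows used by [detect_connection()] and [measure_amplitude()].
#'
#' Window defaults follow common practice for optogenetic circuit mapping:
#' the baseline is a 100 ms stretch ending 5 ms before the first stimulus,
#' and the response window spans 2-50 ms after stimulus onset (the first
#' 2 ms are excluded to avoid the stimulation artifact). Both are
#' configurable and are carried in every result.
#'
#' @param values Numeric samples (pA for voltage clamp, mV for current
#'   clamp), regularly sampled from time 0.
#' @param sampling_rate_Hz Sampling rate (Hz).
#' @param stimulus_onsets_ms Stimulus onset times (ms), at least one.
#' @param polarity Expected response polarity: `"inward"` (negative
#'   deflection, excitatory currents at -70 mV) or `"outward"` (positive,
#'   inhibitory currents at 0 mV).
#' @param baseline_window_ms Two-element `c(start, end)` in ms, or `NULL`
#'   for the default ending 5 ms before the first onset.
#' @param response_window_ms Two-element window in ms relative to each
#'   stimulus onset.
#' @param units `"pA"` or `"mV"`.
#' @param n_trials Number of trials averaged into `values`.
#' @return A `sweep_trace` object.
#' @export
sweep_trace <- function(values, sampling_rate_Hz, stimulus_onsets_ms,
                        polarity = c("inward", "outward"),
                        baseline_window_ms = NULL,
                        response_window_ms = c(2, 50),
                        units = c("pA", "mV"),
                        n_trials = 1L) {
  polarity <- match.arg(polarity)
  units <- match.arg(units)
  stopifnot(sampling_rate_Hz > 0, length(values) > 1)
  if (length(stimulus_onsets_ms) < 1) abort("at least one stimulus onset is required")
  duration_ms <- (length(values) - 1) * 1000 / sampling_rate_Hz
  onset <- min(stimulus_onsets_ms)
  if (is.null(baseline_window_ms)) {
    baseline_window_ms <- c(max(0, onset - 105), max(0, onset - 5))
  }
  if (baseline_window_ms[2] > onset) {
    abort("baseline window must precede the first stimulus onset")
  }
  if (baseline_window_ms[1] >= baseline_window_ms[2]) {
    abort("baseline window is empty")
  }
  structure(
    list(
      data = tibble(time_ms = (seq_along(values) - 1) * 1000 / sampling_rate_Hz,
                    value = as.numeric(values)),
      sampling_rate_Hz = sampling_rate_Hz,
      stimulus_onsets_ms = as.numeric(stimulus_onsets_ms),
      polarity = polarity,
      baseline_window_ms = as.numeric(baseline_window_ms),
      response_window_ms = as.numeric(response_window_ms),
      units = units,
      n_trials = as.integer(n_trials),
      duration_ms = duration_ms
    ),
    class = "sweep_trace"
  )
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf("<sweep_trace> %d samples @ %g kHz (%s, %s), %d onset(s), %d trial(s) averaged\n",
              nrow(x$data), x$sampling_rate_Hz / 1000, x$units, x$polarity,
              length(x$stimulus_onsets_ms), x$n_trials))
  invisible(x)
}

window_values <- function(trace, from_ms, to_ms) {
  t <- trace$data$time_ms
  trace$data$value[t >= from_ms & t <= to_ms]
}

baseline_stats <- function(trace) {
  v <- window_values(trace, trace$baseline_window_ms[1], trace$baseline_window_ms[2])
  list(mean = mean(v), sd = stats::sd(v))
}

signed_deflection <- function(x, baseline, polarity) {
  if (polarity == "inward") baseline - x else x - baseline
}

#' Detect a synaptic connection in a trial-averaged trace
#'
#' A cell is called connected when the average stimulus-evoked response
#' exceeds two standard deviations of the baseline: the mean of the trace
#' over the response window, taken in the expected polarity, must be
#' strictly greater than `2 * sd(baseline)` away from the baseline mean.
#' Deflections of exactly two standard deviations, and flat traces with a
#' degenerate zero baseline SD, are not connected.
#'
#' @param trace A [sweep_trace()] (trial-averaged).
#' @param sd_criterion Multiple of the baseline SD (default 2).
#' @return One-row tibble: `connected`, `response_mean`, `baseline_mean`,
#'   `baseline_sd`, `amplitude`, `peak_time_ms` (amplitude and peak from
#'   [measure_amplitude()], reported for connected and unconnected cells
#'   alike).
#' @export
detect_connection <- function(trace, sd_criterion = 2) {
  stopifnot(inherits(trace, "sweep_trace"))
  onset <- trace$stimulus_onsets_ms[1]
  win <- onset + trace$response_window_ms
  if (win[2] > trace$duration_ms + 1e-9) {
    abort("response window extends beyond the end of the record")
  }
  bl <- baseline_stats(trace)
  response_mean <- mean(window_values(trace, win[1], win[2]))
  defl <- signed_deflection(response_mean, bl$mean, trace$polarity)
  connected <- is.finite(defl) && bl$sd >= 0 &&
    defl > sd_criterion * bl$sd && defl > 0
  amp <- measure_amplitude(trace)
  tibble(
    connected = connected,
    response_mean = response_mean,
    baseline_mean = bl$mean,
    baseline_sd = bl$sd,
    amplitude = amp$amplitude,
    peak_time_ms = amp$peak_time_ms
  )
}

#' Measure response amplitude in a 2 ms peak window
#'
#' The peak is the extremum of the trace within the response window, in the
#' stated polarity; the amplitude is the absolute deviation from the
#' baseline mean of the trace averaged over a 2 ms window centred on the
#' peak. A peak close enough to the record edge that the window is
#' truncated is flagged.
#'
#' @param trace A [sweep_trace()].
#' @param peak_window_ms Full width of the averaging window (default 2 ms).
#' @return One-row tibble: `amplitude` (positive, trace units),
#'   `peak_time_ms`, `truncated`.
#' @export
measure_amplitude <- function(trace, peak_window_ms = 2) {
  stopifnot(inherits(trace, "sweep_trace"))
  onset <- trace$stimulus_onsets_ms[1]
  win <- onset + trace$response_window_ms
  if (win[2] > trace$duration_ms + 1e-9) {
    abort("response window extends beyond the end of the record")
  }
  t <- trace$data$time_ms
  sel <- which(t >= win[1] & t <= win[2])
  v <- trace$data$value[sel]
  bl <- baseline_stats(trace)
  extremum <- if (trace$polarity == "inward") min(v) else max(v)
  # flat peaks (e.g. square responses): centre the window on the plateau
  cands <- which(v == extremum)
  idx <- cands[ceiling(length(cands) / 2)]
  peak_time <- t[sel[idx]]
  half <- peak_window_ms / 2
  lo <- peak_time - half
  hi <- peak_time + half
  truncated <- lo < 0 || hi > trace$duration_ms
  avg <- mean(window_values(trace, max(0, lo), min(trace$duration_ms, hi)))
  tibble(
    amplitude = abs(avg - bl$mean),
    peak_time_ms = peak_time,
    truncated = truncated
  )
}

#' Paired-recording input ratio
#'
#' Ratio of light-evoked amplitudes recorded sequentially in two
#' neighbouring neurons under the same stimulus, the within-slice
#' normalisation used to compare input across projection populations.
#' Zero-denominator pairs are censored (ratio `NA`), not imputed.
#'
#' @param pair A tibble with columns `label` and `amplitude_pA` (two rows),
#'   e.g. from [make_paired_cells()].
#' @param numerator_label,denominator_label Projection labels selecting the
#'   two cells.
#' @return One-row tibble: `ratio`, `log10_ratio`, `censored`.
#' @export
pair_ratio <- function(pair, numerator_label, denominator_label) {
  pair <- as_tibble(pair)
  stopifnot(all(c("label", "amplitude_pA") %in% names(pair)))
  get_amp <- function(lbl) {
    i <- which(pair$label == lbl)
    if (length(i) != 1) abort(sprintf("pair must contain exactly one '%s' cell", lbl))
    pair$amplitude_pA[i]
  }
  num <- get_amp(numerator_label)
  den <- get_amp(denominator_label)
  if (den <= 0) {
    return(tibble(ratio = NA_real_, log10_ratio = NA_real_, censored = TRUE))
  }
  r <- num / den
  tibble(ratio = r, log10_ratio = log10(r), censored = FALSE)
}

#' Intrinsic membrane properties from current steps
#'
#' Standard current-clamp characterisation: resting potential as the mean
#' pre-step voltage across traces; input resistance from Ohm's law on the
#' smallest hyperpolarising step, using the steady-state deflection (mean of
#' the last 20 percent of the step); sag amplitude as the absolute
#' difference between the peak and steady-state deflection on that step;
#' spike counts per depolarising step by upward threshold crossings.
#'
#' @param step_traces List of [sweep_trace()] voltage records (`units =
#'   "mV"`), one per injected current, each annotated with the step onset as
#'   its single stimulus onset and the step duration as its response window
#'   `c(0, duration)`.
#' @param injected_currents_pA Numeric vector, one per trace (negative =
#'   hyperpolarising).
#' @param spike_threshold_mV Upward-crossing threshold for spike counting
#'   (default -20 mV).
#' @return A list of class `intrinsic_properties`: `resting_mV`,
#'   `input_resistance_MOhm`, `sag_mV`, and tibble `spikes_per_step`
#'   (`injected_pA`, `n_spikes`). Resistance and sag are `NA` (with a
#'   warning) when no hyperpolarising step is present.
#' @export
intrinsic_properties <- function(step_traces, injected_currents_pA,
                                 spike_threshold_mV = -20) {
  stopifnot(length(step_traces) == length(injected_currents_pA),
            length(step_traces) >= 1)
  for (tr in step_traces) {
    if (!inherits(tr, "sweep_trace") || tr$units != "mV") {
      abort("step_traces must be voltage (mV) sweep_trace objects")
    }
  }
  resting <- mean(vapply(step_traces, function(tr) baseline_stats(tr)$mean,
                         numeric(1)))
  hyp <- which(injected_currents_pA < 0)
  if (length(hyp) == 0) {
    warn("no hyperpolarising step: input resistance and sag unavailable")
    rin <- NA_real_
    sag <- NA_real_
  } else {
    i <- hyp[which.min(abs(injected_currents_pA[hyp]))]
    tr <- step_traces[[i]]
    onset <- tr$stimulus_onsets_ms[1]
    win <- onset + tr$response_window_ms
    t <- tr$data$time_ms
    in_step <- t >= win[1] & t <= win[2]
    v_step <- tr$data$value[in_step]
    steady_from <- win[1] + 0.8 * (win[2] - win[1])
    steady <- mean(tr$data$value[t >= steady_from & t <= win[2]])
    steady_defl <- steady - resting
    rin <- steady_defl / (injected_currents_pA[i] / 1000)  # mV / nA = MOhm
    peak_defl <- min(v_step) - resting
    sag <- abs(peak_defl - steady_defl)
  }
  spikes <- vapply(seq_along(step_traces), function(j) {
    tr <- step_traces[[j]]
    onset <- tr$stimulus_onsets_ms[1]
    win <- onset + tr$response_window_ms
    t <- tr$data$time_ms
    v <- tr$data$value[t >= win[1] & t <= win[2]]
    sum(diff(v >= spike_threshold_mV) == 1)
  }, numeric(1))
  structure(
    list(
      resting_mV = resting,
      input_resistance_MOhm = rin,
      sag_mV = sag,
      spikes_per_step = tibble(injected_pA = injected_currents_pA,
                               n_spikes = as.integer(spikes))
    ),
    class = "intrinsic_properties"
  )
}

#' @export
print.intrinsic_properties <- function(x, ...) {
  cat(sprintf("<intrinsic_properties> rest %.1f mV, Rin %.1f MOhm, sag %.2f mV\n",
              x$resting_mV, x$input_resistance_MOhm, x$sag_mV))
  print(x$spikes_per_step)
  invisible(x)
}

#' Place-preference occupancy metrics
#'
#' Time-weighted occupancy of the stimulation-paired side of the arena and
#' total distance travelled, scored from a tracked 2-D trajectory. Each
#' sample's dwell time is the gap to the next sample (the final sample
#' contributes none), so the two sides' fractions sum to one.
#'
#' @param trajectory A tibble with columns `time_s`, `x_cm`, `y_cm`
#'   (strictly increasing times), e.g. from [make_trajectory()]. Arena
#'   metadata may be carried as attributes `arena` (list with `width_cm`,
#'   `height_cm`) and `stim_side`.
#' @param arena_width_cm Arena extent along x; defaults to the `arena`
#'   attribute, else the data range.
#' @param stim_side `"right"` (x above the midline) or `"left"`; defaults to
#'   the `stim_side` attribute, else `"right"`.
#' @return One-row tibble: `stim_fraction`, `control_fraction`,
#'   `distance_cm`, `duration_s`.
#' @export
occupancy_metrics <- function(trajectory, arena_width_cm = NULL,
                              stim_side = NULL) {
  tr <- as_tibble(trajectory)
  stopifnot(all(c("time_s", "x_cm", "y_cm") %in% names(tr)))
  if (nrow(tr) < 2) abort("trajectory needs at least two samples")
  if (any(diff(tr$time_s) <= 0)) abort("trajectory times must be strictly increasing")
  arena <- attr(trajectory, "arena")
  arena_width_cm <- arena_width_cm %||% arena$width_cm %||%
    (max(tr$x_cm) + min(tr$x_cm))
  stim_side <- stim_side %||% attr(trajectory, "stim_side") %||% "right"
  mid <- arena_width_cm / 2
  on_stim <- if (identical(stim_side, "right")) tr$x_cm >= mid else tr$x_cm < mid
  dwell <- c(diff(tr$time_s), 0)
  total <- sum(dwell)
  stim_frac <- sum(dwell[on_stim]) / total
  dist <- sum(sqrt(diff(tr$x_cm)^2 + diff(tr$y_cm)^2))
  tibble(
    stim_fraction = stim_frac,
    control_fraction = 1 - stim_frac,
    distance_cm = dist,
    duration_s = total
  )
}
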