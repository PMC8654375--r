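#' Difference-of-exponentials synaptic kernel
#'
#' `k(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / k_max`, normalised
#' analytically so its maximum is exactly 1: the peak occurs at
#' `t* = tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param t_ms Times since onset (ms); values before 0 give 0.
#' @param rise_tau_ms,decay_tau_ms Time constants, `decay > rise > 0`.
#' @return Kernel values with unit peak.
#' @export
psc_kernel <- function(t_ms, rise_tau_ms, decay_tau_ms) {
  stopifnot(decay_tau_ms > rise_tau_ms, rise_tau_ms > 0)
  tpk <- rise_tau_ms * decay_tau_ms / (decay_tau_ms - rise_tau_ms) *
    log(decay_tau_ms / rise_tau_ms)
  norm <- exp(-tpk / decay_tau_ms) - exp(-tpk / rise_tau_ms)
  out <- ifelse(t_ms >= 0,
                (exp(-t_ms / decay_tau_ms) - exp(-t_ms / rise_tau_ms)) / norm,
                0)
  out
}

#' Synthesise a trial-averaged postsynaptic-current trace
#'
#' Emulates a light-evoked postsynaptic current: a difference-of-exponentials
#' response of known peak amplitude at each stimulus onset, with optional
#' per-trial latency jitter, additive Gaussian noise per trial, and trial
#' averaging before analysis (matching per-cell averaged responses).
#'
#' @param peak_amplitude_pA True response amplitude (>= 0; 0 gives an
#'   unconnected null trace).
#' @param rise_tau_ms,decay_tau_ms Kernel time constants.
#' @param latency_ms Onset-to-response latency.
#' @param noise_sd_pA Per-trial Gaussian noise SD.
#' @param n_trials Trials averaged.
#' @param trial_jitter_sd_ms Per-trial latency jitter SD.
#' @param baseline_offset_pA Constant holding-current offset.
#' @param stimulus_onsets_ms Stimulus onsets (ms).
#' @param duration_ms,sampling_rate_Hz Record geometry.
#' @param polarity `"inward"` or `"outward"`.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A list with `trace` (a [sweep_trace()]) and `truth` (one-row
#'   tibble: `connected`, `amplitude_pA`, `window_amplitude_pA` — the 2 ms
#'   peak-window mean of the noiseless averaged response — `latency_ms`,
#'   `peak_time_ms`).
#' @export
make_psc_trace <- function(peak_amplitude_pA,
                           rise_tau_ms = 1, decay_tau_ms = 10,
                           latency_ms = 3,
                           noise_sd_pA = 5, n_trials = 10L,
                           trial_jitter_sd_ms = 0,
                           baseline_offset_pA = 0,
                           stimulus_onsets_ms = 150,
                           duration_ms = 400, sampling_rate_Hz = 10000,
                           polarity = c("inward", "outward"),
                           seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(peak_amplitude_pA >= 0, noise_sd_pA >= 0, n_trials >= 1)
  sgn <- if (polarity == "inward") -1 else 1
  n <- round(duration_ms * sampling_rate_Hz / 1000) + 1
  t <- (seq_len(n) - 1) * 1000 / sampling_rate_Hz

  local_seed(seed, {
    clean_sum <- numeric(n)
    noisy_sum <- numeric(n)
    for (trial in seq_len(n_trials)) {
      jit <- if (trial_jitter_sd_ms > 0) stats::rnorm(1, 0, trial_jitter_sd_ms) else 0
      resp <- numeric(n)
      for (on in stimulus_onsets_ms) {
        resp <- resp + sgn * peak_amplitude_pA *
          psc_kernel(t - on - latency_ms - jit, rise_tau_ms, decay_tau_ms)
      }
      clean_sum <- clean_sum + resp
      noisy_sum <- noisy_sum + resp + stats::rnorm(n, 0, noise_sd_pA)
    }
    clean <- clean_sum / n_trials + baseline_offset_pA
    avg <- noisy_sum / n_trials + baseline_offset_pA

    trace <- sweep_trace(avg, sampling_rate_Hz, stimulus_onsets_ms,
                         polarity = polarity, units = "pA",
                         n_trials = n_trials)
    # ground truth: 2 ms window mean around the peak of the noiseless average
    clean_trace <- sweep_trace(clean, sampling_rate_Hz, stimulus_onsets_ms,
                               polarity = polarity, units = "pA",
                               n_trials = n_trials)
    amp <- measure_amplitude(clean_trace)
    list(
      trace = trace,
      truth = tibble(
        connected = peak_amplitude_pA > 0,
        amplitude_pA = peak_amplitude_pA,
        window_amplitude_pA = amp$amplitude,
        latency_ms = latency_ms,
        peak_time_ms = amp$peak_time_ms
      )
    )
  })
}

#' Synthesise a paired recording
#'
#' Two neighbouring cells recorded under the same stimulus with true
#' amplitudes `base_amplitude_pA` and `base_amplitude_pA * ratio`, analysed
#' with [detect_connection()]/[measure_amplitude()] to produce the measured
#' amplitudes used by [pair_ratio()].
#'
#' @param ratio True amplitude ratio (cell b / cell a), >= 0.
#' @param base_amplitude_pA True amplitude of cell a.
#' @param labels Projection labels for cells a and b.
#' @param noise_sd_pA,n_trials Noise model per cell.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [make_psc_trace()].
#' @return A list with `pair` (tibble `label`, `amplitude_pA`, `pair_id`),
#'   `traces` (the two sweep traces) and `truth` (tibble with the true
#'   amplitudes and ratio).
#' @export
make_paired_cells <- function(ratio, base_amplitude_pA = 40,
                              labels = c("vH-BA", "vH-NAc"),
                              noise_sd_pA = 3, n_trials = 10L, seed = 1L, ...) {
  stopifnot(ratio >= 0, base_amplitude_pA >= 0, length(labels) == 2,
            labels[1] != labels[2])
  amps <- c(base_amplitude_pA, base_amplitude_pA * ratio)
  cells <- lapply(1:2, function(i) {
    make_psc_trace(amps[i], noise_sd_pA = noise_sd_pA, n_trials = n_trials,
                   seed = child_seed(seed, i), ...)
  })
  measured <- vapply(cells, function(cl) measure_amplitude(cl$trace)$amplitude,
                     numeric(1))
  list(
    pair = tibble(label = labels, amplitude_pA = measured,
                  pair_id = sprintf("pair-%d", seed)),
    traces = lapply(cells, `[[`, "trace"),
    truth = tibble(label = labels, true_amplitude_pA = amps,
                   true_ratio = ratio)
  )
}

#' Synthesise current-step traces
#'
#' Leaky integrate-and-fire-like responses to a family of current steps with
#' known resting potential, input resistance, sag and membrane time
#' constant: exponential charging toward `rest + I * R`, an additive
#' alpha-shaped sag component on hyperpolarising steps, stereotyped spikes
#' on suprathreshold depolarising steps, and optional Gaussian noise.
#'
#' @param resting_mV,input_resistance_MOhm,membrane_tau_ms Membrane model.
#' @param sag_mV Extra transient hyperpolarisation at the step onset of
#'   hyperpolarising steps (0 for none).
#' @param steps_pA Injected currents, one trace each.
#' @param threshold_mV,refractory_ms Spiking model for depolarising steps.
#' @param step_onset_ms,step_duration_ms,post_ms Step geometry.
#' @param sampling_rate_Hz Sampling rate.
#' @param noise_sd_mV Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list with `traces` (list of [sweep_trace()], `units = "mV"`),
#'   `injected_currents_pA`, and `truth` (tibble with the generating
#'   parameters and per-step spike counts).
#' @export
make_current_step_traces <- function(resting_mV = -70,
                                     input_resistance_MOhm = 150,
                                     sag_mV = 0,
                                     membrane_tau_ms = 20,
                                     steps_pA = c(-40, 160),
                                     threshold_mV = -35,
                                     refractory_ms = 5,
                                     step_onset_ms = 100,
                                     step_duration_ms = 500,
                                     post_ms = 100,
                                     sampling_rate_Hz = 10000,
                                     noise_sd_mV = 0,
                                     seed = 1L) {
  stopifnot(input_resistance_MOhm > 0, sag_mV >= 0, membrane_tau_ms > 0)
  dt <- 1000 / sampling_rate_Hz
  duration <- step_onset_ms + step_duration_ms + post_ms
  n <- round(duration / dt) + 1
  t <- (seq_len(n) - 1) * dt
  tau_sag <- 3 * membrane_tau_ms

  local_seed(seed, {
    out <- lapply(steps_pA, function(I) {
      dV_ss <- I / 1000 * input_resistance_MOhm  # nA * MOhm = mV
      v <- rep(resting_mV, n)
      n_spikes <- 0L
      in_step <- t >= step_onset_ms & t < step_onset_ms + step_duration_ms
      ts <- t[in_step] - step_onset_ms
      if (I < 0 || resting_mV + dV_ss < threshold_mV) {
        vs <- resting_mV + dV_ss * (1 - exp(-ts / membrane_tau_ms))
        if (I < 0 && sag_mV > 0) {
          vs <- vs - sag_mV * (ts / tau_sag) * exp(1 - ts / tau_sag)
        }
        v[in_step] <- vs
        # relaxation after step end
        after <- t >= step_onset_ms + step_duration_ms
        v_end <- vs[length(vs)]
        v[after] <- resting_mV + (v_end - resting_mV) *
          exp(-(t[after] - (step_onset_ms + step_duration_ms)) / membrane_tau_ms)
      } else {
        # suprathreshold: integrate-and-fire render with spike markers
        vv <- resting_mV
        refr <- 0
        vs <- numeric(sum(in_step))
        for (k in seq_along(ts)) {
          if (refr > 0) {
            refr <- refr - dt
            vv <- resting_mV
            vs[k] <- vv
            next
          }
          vv <- vv + dt * ((resting_mV - vv) + dV_ss) / membrane_tau_ms
          if (vv >= threshold_mV) {
            vs[k] <- 20  # rendered spike peak
            vv <- resting_mV
            refr <- refractory_ms
            n_spikes <- n_spikes + 1L
          } else {
            vs[k] <- vv
          }
        }
        v[in_step] <- vs
      }
      if (noise_sd_mV > 0) v <- v + stats::rnorm(n, 0, noise_sd_mV)
      trace <- sweep_trace(v, sampling_rate_Hz, step_onset_ms,
                           polarity = "inward", units = "mV",
                           baseline_window_ms = c(0, step_onset_ms - 5),
                           response_window_ms = c(0, step_duration_ms))
      list(trace = trace, n_spikes = n_spikes)
    })
    list(
      traces = lapply(out, `[[`, "trace"),
      injected_currents_pA = steps_pA,
      truth = tibble(
        resting_mV = resting_mV,
        input_resistance_MOhm = input_resistance_MOhm,
        sag_mV = sag_mV,
        membrane_tau_ms = membrane_tau_ms,
        injected_pA = list(steps_pA),
        n_spikes = list(vapply(out, `[[`, integer(1), "n_spikes"))
      )
    )
  })
}

#' Synthesise a place-preference trajectory
#'
#' Reflected random walk in a rectangular arena whose side occupancy is
#' governed by a two-state bout process: at each sample the animal remains
#' on its current side or switches with probabilities tuned so the
#' stationary probability of the stimulation side equals `stim_bias`.
#' Within the current side, the position performs a reflected Gaussian walk.
#' The realised stimulation-side dwell fraction (computed exactly as
#' [occupancy_metrics()] computes it) is recorded as ground truth.
#'
#' @param duration_s Session length (default 900 s, a 15 min session).
#' @param rate_Hz Sampling rate of the tracker.
#' @param stim_bias Stationary probability of the stimulation side, in
#'   `[0, 1]`.
#' @param arena_width_cm,arena_height_cm Arena size (default 24 x 16 cm).
#' @param stim_side `"right"` or `"left"`.
#' @param switch_rate Per-sample propensity to re-draw the side (smaller =
#'   longer bouts).
#' @param step_sd_cm Within-side walk step SD per sample.
#' @param seed Integer seed.
#' @return A list with `trajectory` (tibble `time_s`, `x_cm`, `y_cm` with
#'   `arena` and `stim_side` attributes) and `truth` (one-row tibble:
#'   `stim_bias`, `realised_stim_fraction`, `distance_cm`).
#' @export
make_trajectory <- function(duration_s = 900, rate_Hz = 10, stim_bias = 0.5,
                            arena_width_cm = 24, arena_height_cm = 16,
                            stim_side = "right", switch_rate = 0.2,
                            step_sd_cm = 1.5, seed = 1L) {
  stim_bias <- check_fraction(stim_bias, "stim_bias")
  n <- floor(duration_s * rate_Hz)
  if (n < 2) abort("trajectory must contain at least two samples")
  mid <- arena_width_cm / 2
  local_seed(seed, {
    on_stim <- logical(n)
    on_stim[1] <- stats::runif(1) < stim_bias
    switch_draw <- stats::runif(n) < switch_rate
    side_draw <- stats::runif(n) < stim_bias
    for (k in 2:n) {
      on_stim[k] <- if (switch_draw[k]) side_draw[k] else on_stim[k - 1]
    }
    stim_right <- identical(stim_side, "right")
    x <- numeric(n)
    y <- numeric(n)
    reflect <- function(p, lo, hi) {
      width <- hi - lo
      p <- (p - lo) %% (2 * width)
      lo + ifelse(p > width, 2 * width - p, p)
    }
    xr <- function(stim) {
      if (xor(stim, stim_right)) c(0, mid) else c(mid, arena_width_cm)
    }
    r0 <- xr(on_stim[1])
    x[1] <- stats::runif(1, r0[1], r0[2])
    y[1] <- stats::runif(1, 0, arena_height_cm)
    dx <- stats::rnorm(n, 0, step_sd_cm)
    dy <- stats::rnorm(n, 0, step_sd_cm)
    for (k in 2:n) {
      r <- xr(on_stim[k])
      x[k] <- reflect(x[k - 1] + dx[k], r[1], r[2])
      y[k] <- reflect(y[k - 1] + dy[k], 0, arena_height_cm)
    }
    traj <- tibble(time_s = (seq_len(n) - 1) / rate_Hz, x_cm = x, y_cm = y)
    attr(traj, "arena") <- list(width_cm = arena_width_cm,
                                height_cm = arena_height_cm)
    attr(traj, "stim_side") <- stim_side
    occ <- occupancy_metrics(traj)
    list(
      trajectory = traj,
      truth = tibble(
        stim_bias = stim_bias,
        realised_stim_fraction = occ$stim_fraction,
        distance_cm = occ$distance_cm
      )
    )
  })
}
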