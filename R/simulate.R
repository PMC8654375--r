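#' Generate homogeneous Poisson spike trains
#'
#' Independent homogeneous Poisson processes, one per source, realised
#' either by per-timestep Bernoulli thinning (`method = "thinning"`, the
#' discretisation the network engine uses) or by exact exponential-gap
#' sampling (`method = "exact"`).
#'
#' @param n_sources Number of independent sources.
#' @param rate_Hz Firing rate of each source (Hz, non-negative).
#' @param duration_ms Train duration (ms).
#' @param seed Integer seed.
#' @param method `"thinning"` or `"exact"`.
#' @param timestep_ms Discretisation for the thinning method.
#' @return A tibble with columns `source` and `time_ms`, sorted by time
#'   within source; sources with no spikes are absent.
#' @export
generate_poisson_trains <- function(n_sources, rate_Hz, duration_ms, seed,
                                    method = c("thinning", "exact"),
                                    timestep_ms = 0.1) {
  method <- match.arg(method)
  stopifnot(n_sources >= 1, duration_ms > 0, timestep_ms > 0)
  if (rate_Hz < 0) abort("rate must be non-negative")
  if (rate_Hz == 0) {
    return(tibble(source = integer(), time_ms = numeric()))
  }
  local_seed(seed, {
    if (method == "thinning") {
      n_steps <- round(duration_ms / timestep_ms)
      p <- rate_Hz * timestep_ms / 1000
      if (p > 1) abort("timestep too large for this rate")
      # per-step count of spiking sources, then distinct source ids
      counts <- stats::rbinom(n_steps, n_sources, p)
      src <- unlist(lapply(counts, function(k) {
        if (k == 0) integer() else sample.int(n_sources, k)
      }), use.names = FALSE)
      out <- tibble(
        source = src,
        time_ms = rep((seq_len(n_steps) - 1) * timestep_ms, counts)
      )
    } else {
      n_exp <- stats::rpois(n_sources, rate_Hz * duration_ms / 1000)
      src <- rep(seq_len(n_sources), n_exp)
      out <- tibble(
        source = src,
        time_ms = sort_within(stats::runif(length(src), 0, duration_ms), src)
      )
    }
    dplyr::arrange(out, .data$source, .data$time_ms)
  })
}

sort_within <- function(x, group) {
  unlist(lapply(split(x, group), sort), use.names = FALSE)
}

# CSR (by source) representation of a connection list.
as_csr <- function(src, tgt, w, n_sources, extra = NULL) {
  o <- order(src)
  counts <- tabulate(src, nbins = n_sources)
  out <- list(
    ptr = c(0L, cumsum(counts)),
    tgt = as.integer(tgt[o]),
    w = as.numeric(w[o])
  )
  if (!is.null(extra)) out$extra <- as.integer(extra[o])
  out
}

#' Simulate a realised circuit
#'
#' Integrates the conductance-based leaky integrate-and-fire dynamics
#' `C dV/dt = gL (Erest - V) + gAMPA (EAMPA - V) + gGABA (EGABA - V)`,
#' with exponentially decaying synaptic conductances that jump by the
#' connection weight on each presynaptic spike. A neuron crossing threshold
#' spikes, is reset and held for the refractory period. Silenced populations
#' are clamped at rest and emit nothing.
#'
#' @param circuit A `circuit_instance` from [build_circuit()].
#' @param duration_ms,timestep_ms Override the config values if given.
#' @param seed Integer seed for the input spike trains.
#' @param record_vm Optional integer vector of neuron ids whose membrane
#'   potential is sampled.
#' @param record_every_ms Sampling interval for `record_vm` (default 1 ms).
#' @param i_inj_pA Optional per-neuron constant injected current (pA);
#'   recycled to the number of neurons.
#' @param init Initial membrane potential: `"uniform"` (default) draws each
#'   neuron's starting potential uniformly between the resting potential and
#'   5 mV below threshold, which desynchronises the onset without
#'   initialising any cell into an immediate spike; `"rest"` starts every
#'   neuron at the resting potential (and produces one artefactual
#'   synchronous population spike at onset).
#' @return A `vh_sim` object: list with `raster` (tibble `neuron_id`,
#'   `population`, `time_ms`), `summary` (tibble `population`, `n_neurons`,
#'   `total_spikes`), `counts` (per-neuron spike counts), and optionally
#'   `vm` (long tibble `time_ms`, `neuron_id`, `vm_mV`).
#' @export
simulate_circuit <- function(circuit, duration_ms = NULL, timestep_ms = NULL,
                             seed = 1L, record_vm = NULL,
                             record_every_ms = 1, i_inj_pA = 0,
                             init = c("uniform", "rest")) {
  stopifnot(inherits(circuit, "circuit_instance"))
  init <- match.arg(init)
  cfg <- circuit$config
  duration_ms <- duration_ms %||% cfg$duration_ms
  timestep_ms <- timestep_ms %||% cfg$timestep_ms
  n_neurons <- sum(cfg$populations$size)
  rng <- circuit$index_ranges

  rec <- as_csr(circuit$recurrent$src, circuit$recurrent$tgt,
                circuit$recurrent$w, n_neurons, extra = circuit$recurrent$syn)
  ens <- lapply(circuit$ensembles, function(e) {
    csr <- as_csr(e$src, e$tgt, e$w, e$n_sources)
    list(n_sources = e$n_sources, rate_Hz = e$rate_Hz, synapse = e$synapse,
         ptr = csr$ptr, tgt = csr$tgt, w = csr$w)
  })

  silenced_pops <- cfg$populations$name[cfg$populations$silenced]
  silenced <- population_labels(rng) %in% silenced_pops

  i_inj <- rep_len(as.numeric(i_inj_pA), n_neurons)
  record_ids <- as.integer(record_vm %||% integer())
  record_every <- max(1L, as.integer(round(record_every_ms / timestep_ms)))

  res <- local_seed(seed, {
    v0 <- if (init == "uniform") {
      stats::runif(n_neurons, cfg$neuron$resting_mV,
                   max(cfg$neuron$resting_mV, cfg$neuron$threshold_mV - 5))
    } else {
      rep(cfg$neuron$resting_mV, n_neurons)
    }
    lif_engine(
      n_neurons = n_neurons,
      neuron = c(cfg$neuron, list(v0 = v0)),
      syn_tau_ms = cfg$synapses$tau_ms,
      syn_reversal_mV = cfg$synapses$reversal_mV,
      rec_ptr = rec$ptr, rec_tgt = rec$tgt, rec_w = rec$w, rec_syn = rec$extra,
      ensembles = unname(ens),
      silenced = silenced,
      i_inj_pA = i_inj,
      duration_ms = duration_ms,
      dt_ms = timestep_ms,
      record_ids = record_ids,
      record_every = record_every
    )
  })

  labels <- population_labels(rng)
  raster <- tibble(
    neuron_id = res$spike_id,
    population = labels[res$spike_id],
    time_ms = res$spike_time_ms
  ) |> dplyr::arrange(.data$time_ms, .data$neuron_id)

  out <- list(
    raster = raster,
    counts = res$counts,
    summary = summarise_counts(res$counts, circuit),
    duration_ms = duration_ms,
    timestep_ms = timestep_ms,
    seed = as.integer(seed)
  )
  if (length(record_ids)) {
    vm <- as.data.frame(res$vm)
    names(vm) <- as.character(record_ids)
    vm$time_ms <- res$vm_time_ms
    out$vm <- tidyr::pivot_longer(as_tibble(vm), -"time_ms",
                                  names_to = "neuron_id", values_to = "vm_mV") |>
      dplyr::mutate(neuron_id = as.integer(.data$neuron_id))
  }
  structure(out, class = "vh_sim")
}

summarise_counts <- function(counts, circuit) {
  members <- circuit$members
  tibble(
    population = names(members),
    n_neurons = unname(lengths(members)),
    total_spikes = unname(vapply(members, function(ids) sum(counts[ids]),
                                 numeric(1)))
  )
}

#' Count spikes per population
#'
#' Exact per-population totals from a spike raster. Under population overlap
#' dual-identity neurons are credited to each of their identities.
#'
#' @param raster A tibble with columns `neuron_id`, `time_ms` (a `vh_sim`
#'   raster works directly).
#' @param circuit The `circuit_instance` the raster came from.
#' @return A tibble `population`, `n_neurons`, `total_spikes`.
#' @export
count_spikes <- function(raster, circuit) {
  stopifnot(inherits(circuit, "circuit_instance"))
  n_neurons <- sum(circuit$config$populations$size)
  if (nrow(raster) && (any(raster$neuron_id < 1) || any(raster$neuron_id > n_neurons))) {
    abort("raster contains neuron ids outside the circuit")
  }
  counts <- tabulate(raster$neuron_id, nbins = n_neurons)
  summarise_counts(counts, circuit)
}

#' @export
print.vh_sim <- function(x, ...) {
  cat(sprintf("<vh_sim> %g ms, dt %g ms, seed %d\n",
              x$duration_ms, x$timestep_ms, x$seed))
  print(x$summary)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
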