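#' Circuit populations
#'
#' The model contains three pyramidal projection populations, named for their
#' downstream target (basal amygdala, nucleus accumbens, prefrontal cortex),
#' interspersed with local GABAergic interneurons.
#' @keywords internal
PYRAMIDAL_POPULATIONS <- c("vH-BA", "vH-NAc", "vH-PFC")

#' Default circuit configuration
#'
#' Returns the reference parameterisation of the ventral-hippocampal output
#' circuit: 1000 neurons in each of the three projection populations
#' (`vH-BA`, `vH-NAc`, `vH-PFC`) interspersed with 80 local interneurons.
#' All neurons share leaky integrate-and-fire parameters (200 pF capacitance,
#' 5.5 nS leak, -70 mV rest, -35 mV threshold). Local AMPA connections are
#' 1 nS with a 5 ms decay; local GABA connections are 3 nS with a 10 ms
#' decay. Each pyramidal population feeds back onto interneurons with
#' probability 0.1; interneurons inhibit pyramidal neurons with probability
#' 0.8 (`vH-NAc`) or 0.4 (`vH-BA`, `vH-PFC`). Excitatory and inhibitory
#' amygdalar drive each arrive from 50,000 independent 10 Hz Poisson sources
#' connected with probability 0.1 (the inhibitory probability is scaled by
#' [scale_inhibitory_input()]), with per-connection synaptic weights drawn
#' from normal distributions whose means differ by target population: strong
#' 0.3 nS excitatory drive to `vH-BA` and `vH-NAc`, weak 0.03 nS
#' background-level drive to `vH-PFC`; strong 0.3 nS inhibitory drive to
#' `vH-BA` and interneurons, weak 0.08 nS to `vH-NAc` and 0.03 nS to
#' `vH-PFC`. Direct excitatory drive onto interneurons uses the weak
#' background mean (0.03 nS): the slice experiments could not quantify
#' interneuron input strength, and the circuit's described operating regime
#' (interneuron activity dominated by pyramidal feedback, so that
#' inactivating `vH-BA` releases `vH-NAc`) requires it to be far below the
#' pyramidal drive. See the methods vignette for this choice.
#'
#' @param reduced If `TRUE`, return the reduced-scale configuration used for
#'   fast exploration: 200 neurons per pyramidal population, 16 interneurons
#'   and 10,000 input sources, with synaptic weights scaled up fivefold so
#'   the expected synaptic drive per neuron is unchanged.
#' @return A `circuit_config` object (a named list with tibble components
#'   `populations`, `synapses`, `ensembles` and `projections`).
#' @seealso [scale_inhibitory_input()], [apply_overlap()],
#'   [set_mechanism_mode()], [silence_population()], [build_circuit()]
#' @export
#' @examples
#' cfg <- default_config()
#' sum(cfg$populations$size)
default_config <- function(reduced = FALSE) {
  cfg <- list(
    neuron = list(
      capacitance_pF = 200,
      leak_nS = 5.5,
      resting_mV = -70,
      threshold_mV = -35,
      reset_mV = -70,
      refractory_ms = 2
    ),
    synapses = tibble(
      kind = c("AMPA", "GABA"),
      reversal_mV = c(0, -75),
      tau_ms = c(5, 10)
    ),
    populations = tibble(
      name = c(PYRAMIDAL_POPULATIONS, "interneuron"),
      size = c(1000L, 1000L, 1000L, 80L),
      kind = c(rep("pyramidal", 3), "interneuron"),
      silenced = FALSE
    ),
    ensembles = tibble(
      name = c("BA-exc", "BA-inh"),
      n_sources = c(50000L, 50000L),
      rate_Hz = c(10, 10),
      synapse = c("AMPA", "GABA")
    ),
    projections = tibble(
      source = c(
        rep("BA-exc", 4), rep("BA-inh", 4),
        PYRAMIDAL_POPULATIONS, rep("interneuron", 3)
      ),
      target = c(
        PYRAMIDAL_POPULATIONS, "interneuron",
        PYRAMIDAL_POPULATIONS, "interneuron",
        rep("interneuron", 3), PYRAMIDAL_POPULATIONS
      ),
      probability = c(
        rep(0.1, 4),          # excitatory drive, all targets
        rep(0, 4),            # inhibitory drive; set by scale_inhibitory_input()
        rep(0.1, 3),          # pyramidal -> interneuron feedback
        0.4, 0.8, 0.4         # interneuron -> vH-BA / vH-NAc / vH-PFC
      ),
      weight_mean_nS = c(
        0.3, 0.3, 0.03, 0.03,
        0.3, 0.08, 0.03, 0.3,
        1, 1, 1,
        3, 3, 3
      ),
      weight_sd_nS = c(rep(0.2, 8), rep(0, 6)),
      synapse = c(rep("AMPA", 4), rep("GABA", 4), rep("AMPA", 3), rep("GABA", 3)),
      # full-strength probability of each amygdalar ensemble row; the
      # mixture/additive ops scale it by the inhibitory proportion, and the
      # probability-mechanism transform rescales it with the weights
      base_probability = c(rep(0.1, 8), rep(0.1, 3), 0.4, 0.8, 0.4)
    ),
    inhibitory_fraction = 0,
    reference_weight_nS = 0.3,
    overlap_fraction = 0,
    overlap_seed = NA_integer_,
    mechanism_mode = "amplitude",
    weight_handling = "signed",
    duration_ms = 500,
    timestep_ms = 0.1,
    n_runs = 5L,
    seed = 1L,
    redraw_connectivity_per_run = TRUE
  )
  class(cfg) <- "circuit_config"
  if (reduced) cfg <- scale_circuit(cfg, 0.2)
  validate_config(cfg)
  cfg
}

#' Validate a circuit configuration
#'
#' Checks ranges, units and internal consistency; returns the config
#' invisibly unchanged so it can be used in a pipe.
#'
#' @param config A `circuit_config`.
#' @return The validated config (invisibly its input).
#' @export
validate_config <- function(config) {
  if (!inherits(config, "circuit_config")) abort("not a `circuit_config` object")
  n <- config$neuron
  if (n$capacitance_pF <= 0) abort("membrane capacitance must be positive")
  if (n$leak_nS <= 0) abort("leak conductance must be positive")
  if (n$resting_mV >= n$threshold_mV) {
    abort("resting potential must lie below the spike threshold")
  }
  if (n$reset_mV > n$threshold_mV) abort("reset potential must not exceed threshold")
  if (n$refractory_ms < 0) abort("refractory period must be non-negative")
  if (any(config$synapses$tau_ms <= 0)) abort("synaptic decay tau must be positive")
  rev <- stats::setNames(config$synapses$reversal_mV, config$synapses$kind)
  if (rev[["AMPA"]] <= rev[["GABA"]]) {
    abort("AMPA reversal potential must exceed the GABA reversal potential")
  }
  p <- config$populations
  if (any(p$size <= 0)) abort("population sizes must be positive")
  if (anyDuplicated(p$name)) abort("population names must be unique")
  if (!all(p$kind %in% c("pyramidal", "interneuron"))) {
    abort("population kind must be 'pyramidal' or 'interneuron'")
  }
  e <- config$ensembles
  if (any(e$n_sources <= 0)) abort("ensemble n_sources must be positive")
  if (any(e$rate_Hz < 0)) abort("ensemble rates must be non-negative")
  pr <- config$projections
  if (any(pr$probability < 0 | pr$probability > 1)) {
    abort("connection probabilities must lie in [0, 1]")
  }
  if (any(pr$base_probability < 0 | pr$base_probability > 1)) {
    abort("base connection probabilities must lie in [0, 1]")
  }
  if (any(pr$weight_mean_nS < 0)) abort("mean synaptic weights must be non-negative")
  if (any(pr$weight_sd_nS < 0)) abort("weight standard deviations must be non-negative")
  known <- c(p$name, e$name)
  if (!all(pr$source %in% known) || !all(pr$target %in% p$name)) {
    abort("projection sources/targets must name known populations or ensembles")
  }
  if (!all(pr$synapse %in% config$synapses$kind)) abort("unknown synapse kind in projections")
  check_fraction(config$inhibitory_fraction, "inhibitory_fraction")
  check_fraction(config$overlap_fraction, "overlap_fraction")
  if (!config$mechanism_mode %in% c("amplitude", "probability")) {
    abort("mechanism_mode must be 'amplitude' or 'probability'")
  }
  if (!config$weight_handling %in% c("signed", "clip", "resample")) {
    abort("weight_handling must be 'signed', 'clip' or 'resample'")
  }
  if (config$duration_ms <= 0) abort("duration must be positive")
  if (config$timestep_ms <= 0 || config$timestep_ms > 1) {
    abort("timestep must be positive and at most 1 ms")
  }
  if (config$n_runs < 1) abort("n_runs must be at least 1")
  invisible(config)
}

#' @export
print.circuit_config <- function(x, ...) {
  cat("<circuit_config>\n")
  cat(sprintf("  %d neurons in %d populations (%s)\n",
              sum(x$populations$size), nrow(x$populations),
              paste(x$populations$name, collapse = ", ")))
  sil <- x$populations$name[x$populations$silenced]
  if (length(sil)) cat("  silenced:", paste(sil, collapse = ", "), "\n")
  cat(sprintf("  inhibitory fraction %.2f, overlap %.2f, mechanism '%s', weights '%s'\n",
              x$inhibitory_fraction, x$overlap_fraction, x$mechanism_mode,
              x$weight_handling))
  cat(sprintf("  %g ms at dt = %g ms, %d run(s)\n",
              x$duration_ms, x$timestep_ms, x$n_runs))
  invisible(x)
}

ensemble_rows <- function(config) config$projections$source %in% config$ensembles$name

inhibitory_ensemble_rows <- function(config) {
  gaba <- config$ensembles$name[config$ensembles$synapse == "GABA"]
  config$projections$source %in% gaba
}

excitatory_ensemble_rows <- function(config) {
  ampa <- config$ensembles$name[config$ensembles$synapse == "AMPA"]
  config$projections$source %in% ampa
}

#' Scale long-range inhibitory input
#'
#' Sets the connection probability of the inhibitory amygdalar ensemble to a
#' fraction of the excitatory ensemble's probability onto the same target
#' population. A fraction of 0.4 with the default excitatory probability of
#' 0.1 therefore yields an inhibitory connection probability of 0.04.
#'
#' @param config A `circuit_config`.
#' @param fraction Inhibitory-to-excitatory input proportion in `[0, 1]`.
#' @return The modified config.
#' @export
scale_inhibitory_input <- function(config, fraction) {
  validate_config(config)
  fraction <- check_fraction(fraction, "fraction")
  pr <- config$projections
  inh <- inhibitory_ensemble_rows(config)
  exc <- excitatory_ensemble_rows(config)
  pr$probability[inh] <- fraction * pr$base_probability[inh]
  pr$probability[exc] <- pr$base_probability[exc]
  config$projections <- pr
  config$inhibitory_fraction <- fraction
  validate_config(config)
  config
}

#' Set the excitatory/inhibitory mixture of amygdalar input
#'
#' Treats the long-range amygdalar projection as a mixed bundle of
#' excitatory and inhibitory axons whose total connection probability is
#' fixed at the excitatory reference value: at mixture proportion `f` the
#' excitatory ensemble connects with probability `(1 - f) * p_ref` and the
#' inhibitory ensemble with `f * p_ref` (reference `p_ref = 0.1` per target
#' by default). This is the default axis of the inhibition sweep; see
#' [scale_inhibitory_input()] for the additive variant in which the
#' excitatory probability is held fixed.
#'
#' @param config A `circuit_config`.
#' @param fraction Inhibitory proportion of the amygdalar input in `[0, 1]`.
#' @return The modified config.
#' @export
set_input_mixture <- function(config, fraction) {
  validate_config(config)
  fraction <- check_fraction(fraction, "fraction")
  pr <- config$projections
  exc <- excitatory_ensemble_rows(config)
  inh <- inhibitory_ensemble_rows(config)
  pr$probability[exc] <- (1 - fraction) * pr$base_probability[exc]
  pr$probability[inh] <- fraction * pr$base_probability[inh]
  config$projections <- pr
  config$inhibitory_fraction <- fraction
  validate_config(config)
  config
}

#' Designate overlapping projection populations
#'
#' Marks a seeded random subset of each pyramidal population, of the given
#' fraction, as dual-identity: for every ordered pair of distinct pyramidal
#' populations (A, B), `round(fraction * size(A))` neurons of A additionally
#' acquire identity B. Dual-identity neurons receive the union of their
#' identities' ensemble input rules (independent weight draws per identity,
#' summed), are inhibited by local interneurons at the maximum of their
#' identities' connection probabilities, and are credited to every identity
#' when spikes are counted. At `fraction = 1` all pyramidal neurons carry all
#' three identities, so per-population spike totals coincide exactly.
#'
#' @param config A `circuit_config`.
#' @param overlap_fraction Proportion in `[0, 1]` of each population that is
#'   shared with each other population.
#' @param rng_seed Integer seed fixing the selected subsets (realised in
#'   [build_circuit()]).
#' @return The modified config.
#' @export
apply_overlap <- function(config, overlap_fraction, rng_seed = 1L) {
  validate_config(config)
  overlap_fraction <- check_fraction(overlap_fraction, "overlap_fraction")
  config$overlap_fraction <- overlap_fraction
  config$overlap_seed <- if (overlap_fraction > 0) as.integer(rng_seed) else NA_integer_
  config
}

#' Choose the postsynaptic mechanism implementing input differences
#'
#' In `"amplitude"` mode (the default parameterisation), all targets share
#' the ensemble connection probability and differ in their mean synaptic
#' weight. In `"probability"` mode every ensemble weight is fixed at the
#' reference mean of 0.3 nS and each target's connection probability is
#' rescaled by (mean weight / 0.3), preserving the expected total synaptic
#' conductance per neuron.
#'
#' @param config A `circuit_config`.
#' @param mode `"amplitude"` or `"probability"`.
#' @param reference_weight_nS Reference mean weight; defaults to the config's
#'   `reference_weight_nS` (0.3 nS at full scale, rescaled with the circuit).
#' @return The modified config.
#' @export
set_mechanism_mode <- function(config, mode = c("amplitude", "probability"),
                               reference_weight_nS = NULL) {
  validate_config(config)
  reference_weight_nS <- reference_weight_nS %||%
    config$reference_weight_nS %||% 0.3
  mode <- match.arg(mode)
  if (mode == config$mechanism_mode) return(config)
  pr <- config$projections
  ens <- ensemble_rows(config)
  if (mode == "probability") {
    config$amplitude_projections <- pr[ens, ]
    scale <- pr$weight_mean_nS[ens] / reference_weight_nS
    pr$probability[ens] <- pmin(1, pr$probability[ens] * scale)
    pr$base_probability[ens] <- pmin(1, pr$base_probability[ens] * scale)
    pr$weight_mean_nS[ens] <- reference_weight_nS
    pr$weight_sd_nS[ens] <- 0
  } else {
    if (is.null(config$amplitude_projections)) {
      abort("cannot restore amplitude mode: no stored amplitude parameterisation")
    }
    pr[ens, ] <- config$amplitude_projections
    config$amplitude_projections <- NULL
  }
  config$projections <- pr
  config$mechanism_mode <- mode
  validate_config(config)
  config
}

#' Silence a population
#'
#' A silenced population is clamped at resting potential during simulation:
#' its neurons emit no spikes and deliver no synaptic output, emulating
#' pharmacogenetic inactivation.
#'
#' @param config A `circuit_config`.
#' @param name Population name to silence.
#' @return The modified config.
#' @export
silence_population <- function(config, name) {
  validate_config(config)
  if (!name %in% config$populations$name) {
    abort(sprintf("unknown population '%s' (known: %s)", name,
                  paste(config$populations$name, collapse = ", ")))
  }
  config$populations$silenced[config$populations$name == name] <- TRUE
  config
}

#' Rescale the circuit size, preserving per-neuron synaptic drive
#'
#' Multiplies every population size and ensemble source count by `factor`
#' (rounded) and divides all synaptic weights by `factor`, so that the
#' expected total synaptic conductance impinging on each neuron is unchanged.
#' Used for fast reduced-scale runs; fluctuations around the expectation are
#' larger at smaller scale.
#'
#' @param config A `circuit_config`.
#' @param factor Positive scale factor (1 = full scale).
#' @return The modified config.
#' @export
scale_circuit <- function(config, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  config$populations$size <- pmax(1L, as.integer(round(config$populations$size * factor)))
  config$ensembles$n_sources <- pmax(1L, as.integer(round(config$ensembles$n_sources * factor)))
  config$projections$weight_mean_nS <- config$projections$weight_mean_nS / factor
  config$projections$weight_sd_nS <- config$projections$weight_sd_nS / factor
  config$reference_weight_nS <- (config$reference_weight_nS %||% 0.3) / factor
  config
}
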