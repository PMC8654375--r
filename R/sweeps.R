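run_seeded <- function(config, master_seed, counter) {
  build_seed <- child_seed(master_seed, 2L * counter - 1L)
  sim_seed <- child_seed(master_seed, 2L * counter)
  circuit <- build_circuit(config, seed = build_seed)
  simulate_circuit(circuit, seed = sim_seed)
}

# One grid point of a sweep: n_runs seeded runs, tidy totals.
run_grid_point <- function(config, master_seed, counter0) {
  runs <- lapply(seq_len(config$n_runs), function(r) {
    sim <- run_seeded(config, master_seed, counter0 + r)
    dplyr::mutate(sim$summary, run = r, .before = 1)
  })
  dplyr::bind_rows(runs)
}

#' Sweep the proportion of long-range inhibitory input
#'
#' The central in-silico experiment: for each inhibitory proportion the
#' circuit is realised and simulated `n_runs` times (500 ms each by
#' default), and total spikes per population are recorded. With increasing
#' inhibitory input, activity switches from `vH-BA` to `vH-NAc` neurons.
#'
#' Connectivity and input trains are redrawn for every run from seeds
#' derived from `master_seed` by counter position (see [child_seed()]),
#' unless `config$redraw_connectivity_per_run` is `FALSE`, in which case one
#' circuit realisation per grid point is reused across runs.
#'
#' @param config Base `circuit_config` (inhibitory fraction is overridden by
#'   the grid).
#' @param fractions Ordered vector of inhibitory proportions in `[0, 1]`.
#' @param master_seed Integer master seed.
#' @param mixture If `TRUE` (default) the proportion is interpreted as the
#'   inhibitory share of a fixed-size amygdalar input bundle
#'   ([set_input_mixture()]); if `FALSE` inhibition is added on top of a
#'   fixed excitatory probability ([scale_inhibitory_input()]).
#' @return A `vh_sweep` object: tibble with columns `parameter`, `value`,
#'   `run`, `population`, `n_neurons`, `total_spikes` and attributes
#'   `master_seed`, `config`.
#' @export
run_inhibition_sweep <- function(config, fractions = seq(0, 1, by = 0.1),
                                 master_seed = 1L, mixture = TRUE) {
  if (length(fractions) == 0) abort("`fractions` must be non-empty")
  for (f in fractions) check_fraction(f, "fractions")
  apply_fraction <- if (mixture) set_input_mixture else scale_inhibitory_input
  out <- lapply(seq_along(fractions), function(i) {
    cfg <- apply_fraction(config, fractions[i])
    if (!config$redraw_connectivity_per_run) {
      circuit <- build_circuit(cfg, seed = child_seed(master_seed, 1000L + i))
      runs <- lapply(seq_len(cfg$n_runs), function(r) {
        sim <- simulate_circuit(circuit,
                                seed = child_seed(master_seed, 2L * ((i - 1L) * cfg$n_runs + r)))
        dplyr::mutate(sim$summary, run = r, .before = 1)
      })
      pt <- dplyr::bind_rows(runs)
    } else {
      pt <- run_grid_point(cfg, master_seed, (i - 1L) * cfg$n_runs)
    }
    dplyr::mutate(pt,
                  parameter = "inhibitory_fraction",
                  value = fractions[i], .before = 1)
  })
  new_sweep(dplyr::bind_rows(out), master_seed, config,
            swept_parameter = "inhibitory_fraction", mixture = mixture)
}

new_sweep <- function(tbl, master_seed, config, swept_parameter, ...) {
  structure(tbl,
            class = c("vh_sweep", class(tibble())),
            master_seed = as.integer(master_seed),
            swept_parameter = swept_parameter,
            base_config = config,
            extra = list(...))
}

#' Locate the grid value maximising a population difference
#'
#' Averages total spikes per population across runs at each grid value and
#' returns the value maximising `mean(total_a) - mean(total_b)`. Exact ties
#' are broken toward the smaller grid value.
#'
#' @param sweep A `vh_sweep` (or any tibble with columns `value`, `run`,
#'   `population`, `total_spikes`).
#' @param population_a,population_b Population names; the difference is
#'   a minus b.
#' @return One-row tibble: `peak_value`, `mean_difference`.
#' @export
find_peak_difference <- function(sweep, population_a = "vH-NAc",
                                 population_b = "vH-BA") {
  pops <- unique(sweep$population)
  for (p in c(population_a, population_b)) {
    if (!p %in% pops) abort(sprintf("population '%s' not present in sweep", p))
  }
  diffs <- sweep |>
    dplyr::filter(.data$population %in% c(population_a, population_b)) |>
    dplyr::group_by(.data$value, .data$population) |>
    dplyr::summarise(mean_total = mean(.data$total_spikes), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "population", values_from = "mean_total") |>
    dplyr::mutate(difference = .data[[population_a]] - .data[[population_b]]) |>
    dplyr::arrange(.data$value)
  best <- which(diffs$difference == max(diffs$difference))[1]
  tibble(peak_value = diffs$value[best], mean_difference = diffs$difference[best])
}

#' Robustness sweep over local connectivity probabilities
#'
#' Reruns the inhibition sweep over a grid of local circuit connectivities:
#' the pyramidal-to-interneuron feedback probability and the pair of
#' interneuron-to-pyramidal probabilities (onto `vH-NAc` versus onto the
#' other pyramidal populations).
#'
#' @param config Base `circuit_config`.
#' @param feedback_probabilities Values for the pyramidal-to-interneuron
#'   feedback probability.
#' @param interneuron_probability_pairs List of two-element vectors
#'   `c(p_nac, p_other)` for interneuron-to-pyramidal connectivity.
#' @param fractions Inhibitory proportions swept in each cell.
#' @param master_seed Integer master seed.
#' @param mixture Passed to [run_inhibition_sweep()].
#' @return A tibble with columns `feedback_p`, `in_p_nac`, `in_p_other` plus
#'   the sweep columns.
#' @export
run_connectivity_sweep <- function(config,
                                   feedback_probabilities = c(0.05, 0.1, 0.2),
                                   interneuron_probability_pairs =
                                     list(c(0.8, 0.4), c(0.6, 0.4)),
                                   fractions = seq(0, 1, by = 0.1),
                                   master_seed = 1L, mixture = TRUE) {
  for (p in feedback_probabilities) check_fraction(p, "feedback_probabilities")
  for (pp in interneuron_probability_pairs) {
    check_fraction(pp[1], "interneuron probability (vH-NAc)")
    check_fraction(pp[2], "interneuron probability (other)")
  }
  grid <- tidyr::expand_grid(
    feedback_p = feedback_probabilities,
    pair = interneuron_probability_pairs
  )
  out <- lapply(seq_len(nrow(grid)), function(i) {
    fb <- grid$feedback_p[i]
    pp <- grid$pair[[i]]
    cfg <- config
    pr <- cfg$projections
    fb_rows <- pr$target == "interneuron" & pr$source %in% cfg$populations$name
    pr$probability[fb_rows] <- fb
    in_rows <- pr$source == "interneuron"
    pr$probability[in_rows & pr$target == "vH-NAc"] <- pp[1]
    pr$probability[in_rows & pr$target != "vH-NAc"] <- pp[2]
    cfg$projections <- pr
    sw <- run_inhibition_sweep(cfg, fractions,
                               master_seed = child_seed(master_seed, 9000L + i),
                               mixture = mixture)
    dplyr::mutate(as_tibble(sw), feedback_p = fb, in_p_nac = pp[1],
                  in_p_other = pp[2], .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Robustness sweep over projection-population overlap
#'
#' @param config Base `circuit_config`.
#' @param overlap_fractions Overlap proportions in `[0, 1]`.
#' @param inhibitory_fractions Inhibitory proportions swept at each overlap.
#' @param master_seed Integer master seed.
#' @param mixture Passed to [run_inhibition_sweep()].
#' @return A tibble with an `overlap` column plus the sweep columns.
#' @export
run_overlap_sweep <- function(config, overlap_fractions = c(0, 0.1, 0.3),
                              inhibitory_fractions = seq(0, 1, by = 0.1),
                              master_seed = 1L, mixture = TRUE) {
  out <- lapply(seq_along(overlap_fractions), function(i) {
    ov <- check_fraction(overlap_fractions[i], "overlap_fractions")
    cfg <- apply_overlap(config, ov, rng_seed = child_seed(master_seed, 5000L + i))
    sw <- run_inhibition_sweep(cfg, inhibitory_fractions,
                               master_seed = master_seed, mixture = mixture)
    dplyr::mutate(as_tibble(sw), overlap = ov, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Compare postsynaptic mechanisms
#'
#' Runs the inhibition sweep in `"amplitude"` mode (population-specific mean
#' weights, shared connection probability) and in `"probability"` mode
#' (shared weight, rescaled probabilities preserving expected conductance),
#' with identical seeds.
#'
#' @inheritParams run_inhibition_sweep
#' @return A tibble with a `mechanism` column plus the sweep columns.
#' @export
run_mechanism_comparison <- function(config, fractions = seq(0, 1, by = 0.1),
                                     master_seed = 1L, mixture = TRUE) {
  out <- lapply(c("amplitude", "probability"), function(mode) {
    cfg <- set_mechanism_mode(config, mode)
    sw <- run_inhibition_sweep(cfg, fractions, master_seed = master_seed,
                               mixture = mixture)
    dplyr::mutate(as_tibble(sw), mechanism = mode, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Population silencing experiment
#'
#' Paired intact/silenced runs with common seeds: the same master seed
#' drives connectivity and input realisation in both conditions, so the only
#' difference is the clamp on the silenced population.
#'
#' @param config Base `circuit_config`.
#' @param silenced Name of the population to silence.
#' @param fraction Inhibitory proportion for both conditions.
#' @param master_seed Integer master seed.
#' @param mixture Interpretation of `fraction`, see [run_inhibition_sweep()].
#' @return A `vh_silencing` tibble: `condition`, `run`, `population`,
#'   `n_neurons`, `total_spikes`.
#' @export
run_silencing_experiment <- function(config, silenced = "vH-BA", fraction = 0,
                                     master_seed = 1L, mixture = TRUE) {
  if (!silenced %in% config$populations$name) {
    abort(sprintf("unknown population '%s'", silenced))
  }
  fraction <- check_fraction(fraction, "fraction")
  apply_fraction <- if (mixture) set_input_mixture else scale_inhibitory_input
  base <- apply_fraction(config, fraction)
  out <- lapply(c("intact", "silenced"), function(cond) {
    cfg <- if (cond == "silenced") silence_population(base, silenced) else base
    run_grid_point(cfg, master_seed, 0L) |>
      dplyr::mutate(condition = cond, .before = 1)
  })
  structure(dplyr::bind_rows(out),
            class = c("vh_silencing", class(tibble())),
            master_seed = as.integer(master_seed),
            silenced = silenced, fraction = fraction)
}
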