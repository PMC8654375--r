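#' Population index ranges
#'
#' Neurons are numbered contiguously in the order the populations appear in
#' the configuration.
#' @param config A `circuit_config`.
#' @return A tibble with columns `population`, `start`, `end` (1-based,
#'   inclusive).
#' @export
index_ranges <- function(config) {
  sizes <- config$populations$size
  ends <- cumsum(sizes)
  tibble(
    population = config$populations$name,
    start = ends - sizes + 1L,
    end = as.integer(ends)
  )
}

# Identity membership under overlap: a list mapping population name to the
# sorted neuron ids credited to it. Without overlap this is just the index
# ranges; with overlap, seeded subsets of each pyramidal population gain the
# other pyramidal identities.
identity_members <- function(config) {
  rng <- index_ranges(config)
  ids <- Map(seq.int, rng$start, rng$end)
  names(ids) <- rng$population
  members <- ids
  frac <- config$overlap_fraction
  if (frac > 0) {
    pyr <- config$populations$name[config$populations$kind == "pyramidal"]
    extra <- local_seed(config$overlap_seed, {
      out <- stats::setNames(vector("list", length(pyr)), pyr)
      for (a in pyr) {
        for (b in setdiff(pyr, a)) {
          k <- round(frac * length(ids[[a]]))
          chosen <- if (k >= length(ids[[a]])) ids[[a]] else sort(sample(ids[[a]], k))
          out[[b]] <- c(out[[b]], chosen)
        }
      }
      out
    })
    for (b in pyr) members[[b]] <- sort(unique(c(members[[b]], extra[[b]])))
  }
  members
}

draw_weights <- function(n, mean, sd, handling) {
  w <- stats::rnorm(n, mean, sd)
  if (handling == "clip") {
    w <- pmax(w, 0)
  } else if (handling == "resample") {
    bad <- which(w < 0)
    while (length(bad)) {
      w[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[w[bad] < 0]
    }
  }
  w
}

# Bernoulli realisation of one projection onto a set of target ids: per
# target, in-degree ~ Binomial(n_sources, p), sources sampled without
# replacement, one weight draw per connection.
realise_projection <- function(targets, n_sources, probability, mean, sd, handling) {
  if (probability <= 0 || length(targets) == 0) {
    return(list(src = integer(), tgt = integer(), w = numeric()))
  }
  k <- stats::rbinom(length(targets), n_sources, probability)
  total <- sum(k)
  src <- integer(total)
  pos <- 1L
  for (i in seq_along(targets)) {
    if (k[i] > 0) {
      src[pos:(pos + k[i] - 1L)] <- sample.int(n_sources, k[i])
      pos <- pos + k[i]
    }
  }
  list(
    src = src,
    tgt = rep(as.integer(targets), k),
    w = draw_weights(total, mean, sd, handling)
  )
}

#' Realise a circuit instance
#'
#' Draws every connection of every projection by independent Bernoulli trials
#' and per-connection normal weight draws. The realisation is a pure function
#' of `(config, seed)`.
#'
#' Negative weight draws are handled according to `config$weight_handling`:
#' `"signed"` keeps them (they subtract from the summed synaptic conductance,
#' preserving the mean of the fitted distribution), `"clip"` sets them to
#' zero, `"resample"` redraws until non-negative.
#'
#' @param config A `circuit_config`.
#' @param seed Integer seed.
#' @return A `circuit_instance` list with elements `config`, `index_ranges`,
#'   `members`, `recurrent` (source/target/weight/synapse vectors over
#'   neurons) and `ensembles` (per ensemble, source/target/weight vectors plus
#'   the Poisson parameters).
#' @export
build_circuit <- function(config, seed = config$seed) {
  validate_config(config)
  rng <- index_ranges(config)
  members <- identity_members(config)
  n_neurons <- sum(config$populations$size)
  handling <- config$weight_handling
  syn_index <- stats::setNames(seq_len(nrow(config$synapses)), config$synapses$kind)

  pop_rows <- stats::setNames(seq_len(nrow(rng)), rng$population)
  inst <- local_seed(seed, {
    pr <- config$projections
    # interneuron -> pyramidal probability per neuron is the max over the
    # neuron's identities; precompute per-target-population neuron sets that
    # account for overlap (a dual vH-NAc neuron keeps the 0.8 probability).
    rec <- list(src = integer(), tgt = integer(), w = numeric(), syn = integer())
    ens <- lapply(seq_len(nrow(config$ensembles)), function(i) {
      list(
        name = config$ensembles$name[i],
        n_sources = config$ensembles$n_sources[i],
        rate_Hz = config$ensembles$rate_Hz[i],
        synapse = syn_index[[config$ensembles$synapse[i]]],
        src = integer(), tgt = integer(), w = numeric()
      )
    })
    names(ens) <- config$ensembles$name

    inhib_rows <- which(pr$source == "interneuron")
    if (length(inhib_rows)) {
      # per-neuron inhibition probability = max over identities
      p_in <- numeric(n_neurons)
      for (i in inhib_rows) {
        tgt_ids <- members[[pr$target[i]]]
        p_in[tgt_ids] <- pmax(p_in[tgt_ids], pr$probability[i])
      }
      in_row <- pop_rows[["interneuron"]]
      n_int <- rng$end[in_row] - rng$start[in_row] + 1L
      offset <- rng$start[in_row] - 1L
      w_row <- pr[inhib_rows[1], ]
      tgt_all <- which(p_in > 0)
      srcs <- vector("list", length(tgt_all))
      for (j in seq_along(tgt_all)) {
        srcs[[j]] <- which(stats::runif(n_int) < p_in[tgt_all[j]]) + offset
      }
      counts <- lengths(srcs)
      total <- sum(counts)
      rec$src <- unlist(srcs, use.names = FALSE)
      rec$tgt <- rep(tgt_all, counts)
      rec$w <- draw_weights(total, w_row$weight_mean_nS, w_row$weight_sd_nS, handling)
      rec$syn <- rep(syn_index[[w_row$synapse]], total)
    }

    for (i in seq_len(nrow(pr))) {
      if (pr$source[i] == "interneuron") next
      if (pr$source[i] %in% config$ensembles$name) {
        tgt_ids <- members[[pr$target[i]]]
        e <- pr$source[i]
        con <- realise_projection(tgt_ids, ens[[e]]$n_sources, pr$probability[i],
                                  pr$weight_mean_nS[i], pr$weight_sd_nS[i], handling)
        ens[[e]]$src <- c(ens[[e]]$src, con$src)
        ens[[e]]$tgt <- c(ens[[e]]$tgt, con$tgt)
        ens[[e]]$w <- c(ens[[e]]$w, con$w)
      } else {
        # pyramidal -> interneuron feedback: one rule per source population
        # (identities share it, so dual neurons are not drawn twice)
        src_row <- pop_rows[[pr$source[i]]]
        src_ids <- seq.int(rng$start[src_row], rng$end[src_row])
        tgt_row <- pop_rows[[pr$target[i]]]
        tgt_ids <- seq.int(rng$start[tgt_row], rng$end[tgt_row])
        con <- realise_projection(tgt_ids, length(src_ids), pr$probability[i],
                                  pr$weight_mean_nS[i], pr$weight_sd_nS[i], handling)
        rec$src <- c(rec$src, src_ids[con$src])
        rec$tgt <- c(rec$tgt, con$tgt)
        rec$w <- c(rec$w, con$w)
        rec$syn <- c(rec$syn, rep(syn_index[[pr$synapse[i]]], length(con$src)))
      }
    }
    list(recurrent = rec, ensembles = ens)
  })

  structure(
    list(
      config = config,
      index_ranges = rng,
      members = members,
      recurrent = inst$recurrent,
      ensembles = inst$ensembles,
      seed = as.integer(seed)
    ),
    class = "circuit_instance"
  )
}

#' @export
print.circuit_instance <- function(x, ...) {
  cat("<circuit_instance>\n")
  cat(sprintf("  %d neurons, %d recurrent connections\n",
              sum(x$config$populations$size), length(x$recurrent$src)))
  for (e in x$ensembles) {
    cat(sprintf("  ensemble %s: %d sources @ %g Hz, %d connections\n",
                e$name, e$n_sources, e$rate_Hz, length(e$src)))
  }
  invisible(x)
}

#' Per-neuron population labels
#' @param instance A `circuit_instance` (or the result of [index_ranges()]).
#' @return Character vector of length `n_neurons`, primary identity only.
#' @keywords internal
population_labels <- function(rng) {
  rep(rng$population, rng$end - rng$start + 1L)
}
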