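# Tiny circuit for fast unit tests: 20 neurons per pyramidal population,
# 2 interneurons, 1000 input sources; scale_circuit() preserves the
# expected per-neuron synaptic drive.
tiny_config <- function(...) {
  cfg <- scale_circuit(default_config(), 0.02)
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  validate_config(cfg)
  cfg
}

# Single isolated neuron with no synaptic input: a bare LIF.
isolated_config <- function() {
  cfg <- default_config()
  cfg$populations <- cfg$populations[1, ]
  cfg$populations$size <- 1L
  cfg$ensembles <- cfg$ensembles[0, ]
  cfg$projections <- cfg$projections[0, ]
  cfg
}

# Closed-form LIF inter-spike interval for constant injected current.
lif_isi_ms <- function(i_pA, neuron = default_config()$neuron) {
  v_ss <- neuron$resting_mV + i_pA / neuron$leak_nS
  if (v_ss <= neuron$threshold_mV) return(Inf)
  tau <- neuron$capacitance_pF / neuron$leak_nS
  neuron$refractory_ms +
    tau * log((v_ss - neuron$reset_mV) / (v_ss - neuron$threshold_mV))
}
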