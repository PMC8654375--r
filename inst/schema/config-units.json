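{
  "description": "Units and semantics of circuit_config YAML files. All keys are fixed-unit; unknown keys are rejected.",
  "neuron": {
    "capacitance_pF": "picofarads",
    "leak_nS": "nanosiemens",
    "resting_mV": "millivolts",
    "threshold_mV": "millivolts",
    "reset_mV": "millivolts",
    "refractory_ms": "milliseconds"
  },
  "synapses": {"reversal_mV": "millivolts", "tau_ms": "milliseconds"},
  "ensembles": {"n_sources": "count", "rate_Hz": "hertz"},
  "projections": {
    "probability": "probability in [0,1]",
    "base_probability": "full-strength probability in [0,1]",
    "weight_mean_nS": "nanosiemens",
    "weight_sd_nS": "nanosiemens"
  },
  "scalars": {
    "inhibitory_fraction": "proportion in [0,1]",
    "reference_weight_nS": "nanosiemens",
    "overlap_fraction": "proportion in [0,1]",
    "duration_ms": "milliseconds",
    "timestep_ms": "milliseconds (must be <= 1)",
    "n_runs": "count",
    "seed": "integer"
  },
  "file_formats": {
    "raster_csv": "neuron_id,population,time_ms (times to 3 decimals)",
    "sweep_csv": "parameter,value,run,population,total_spikes",
    "trace_csv": "time_ms,value with JSON sidecar (sampling_rate_Hz, stimulus_onsets_ms, polarity, windows, units, n_trials)",
    "trajectory_csv": "time_s,x_cm,y_cm with JSON arena sidecar"
  }
}
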