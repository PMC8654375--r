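Package: vhgate
Title: Amygdalar Control of Parallel Ventral Hippocampal Output Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire network model of the
    ventral hippocampal (vH) output circuit and its control by co-activated
    excitatory and long-range inhibitory input from the basal amygdala (BA).
    Implements the three parallel projection populations (vH-BA, vH-NAc,
    vH-PFC) with local feedforward and feedback inhibition, Poisson synaptic
    drive with heterogeneous weights, and parameter sweeps over the
    inhibitory-to-excitatory input ratio that reproduce the switch of circuit
    output from BA-projecting to NAc-projecting neurons. Also provides the
    accompanying electrophysiology quantification rules (optogenetic
    circuit-mapping response detection by a two-standard-deviation criterion,
    peak-window amplitude measurement, paired-recording input ratios,
    current-step intrinsic properties) and real-time place-preference
    occupancy metrics, together with seeded synthetic-data generators for all
    of these analysis stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
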