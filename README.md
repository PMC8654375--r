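# vhgate

Amygdalar control of parallel ventral-hippocampal output pathways: a
conductance-based spiking circuit model with the accompanying
electrophysiology and behaviour quantification rules.

## The problem

Pyramidal neurons at the ventral hippocampus (vH) CA1/subiculum border form
parallel projection populations — to the basal amygdala (vH-BA), the
nucleus accumbens (vH-NAc) and the prefrontal cortex (vH-PFC). The basal
amygdala (BA) sends vH a *mixed* projection: a large excitatory component
that targets vH-BA and vH-NAc neurons but avoids vH-PFC, and a smaller
long-range GABAergic component that targets mainly vH-BA. Local
interneurons, driven largely by pyramidal feedback, inhibit vH-NAc about
twice as strongly as the other populations. `vhgate` asks what this wiring
implies for the routing of vH output, for users who study hippocampal—
amygdalar circuits or who need a compact, fully seeded reference
implementation of the model and its analysis conventions.

## The model

A leaky integrate-and-fire network (3 × 1000 pyramidal neurons + 80
interneurons) with conductance-based exponential synapses,

```
C dV/dt = gL (Erest − V) + gAMPA (EAMPA − V) + gGABA (EGABA − V)
```

(C = 200 pF, gL = 5.5 nS, Erest = −70 mV, threshold −35 mV; τAMPA = 5 ms,
τGABA = 10 ms). Long-range input is two ensembles of 50,000 Poisson
sources at 10 Hz (excitatory and inhibitory), connected with probability
0.1 and per-connection weights drawn from the normal distributions fitted
to paired recordings (0.3 ± 0.2 nS onto the strongly targeted populations,
0.08 ± 0.2 nS inhibitory onto vH-NAc, 0.03 ± 0.2 nS "background" onto
vH-PFC). The swept quantity is the inhibitory share *f* of the input
bundle: excitation connects at 0.1 (1 − f), inhibition at 0.1 f. Model
output is total spikes per population over 500 ms, five seeded runs per
level. See the methods vignette (`vignettes/circuit-model.Rmd`) for every
default and the reasoning behind the choices the published description
leaves open.

The package also implements the study's quantification rules: synaptic
connection detection (response > 2 baseline SDs), 2 ms peak-window
amplitudes, paired-recording input ratios, current-step intrinsic
properties (resting potential, input resistance, sag, spike counts) and
real-time place-preference occupancy — plus seeded synthetic-data
generators with ground truth for all of them.

## Worked example

A reduced-scale sweep (200 neurons per population, 10,000 sources,
drive-preserving weights — about 30 s) shows the full phenomenology:

```r
library(vhgate)
cfg <- default_config(reduced = TRUE)
sweep <- run_inhibition_sweep(cfg, seq(0, 1, by = 0.1), master_seed = 1)
glance(sweep)
#> # A tibble: 1 × 5
#>   n_grid n_runs master_seed peak_value mean_difference
#>    <int>  <int>       <int>      <dbl>           <dbl>
#> 1     11      5           1        0.5           8832.
autoplot(sweep)   # population totals vs inhibitory proportion
```

With no inhibitory input vH-BA dominates (vH-NAc fires ~3% as much);
around f = 0.4–0.5 the output switches — vH-BA is effectively silent,
vH-NAc fires robustly — and the vH-NAc − vH-BA difference peaks; vH-PFC
stays silent, and interneuron firing declines monotonically with f. The
in-silico inactivation prediction is reproduced by

```r
res <- run_silencing_experiment(cfg, "vH-BA", fraction = 0, master_seed = 1)
glance(res)
#> # A tibble: 4 × 5
#>   population  intact silenced difference silenced_population
#>   <chr>        <dbl>    <dbl>      <dbl> <chr>
#> 1 interneuron   825.    443       -382.  vH-BA
#> 2 vH-BA        2968.      0      -2968.  vH-BA
#> 3 vH-NAc         93     852.       759.  vH-BA
#> 4 vH-PFC          0       5.2        5.2 vH-BA
```

— clamping vH-BA removes the bulk of the feedback drive onto local
interneurons and releases vH-NAc roughly tenfold.

Full-scale simulations use `default_config()` (a 500 ms run takes a few
seconds; the full sweep several minutes). The analysis side:

```r
psc <- make_psc_trace(40, noise_sd_pA = 5, n_trials = 10, seed = 3)
detect_connection(psc$trace)
#> # A tibble: 1 × 6
#>   connected response_mean baseline_mean baseline_sd amplitude peak_time_ms
#>   <lgl>             <dbl>         <dbl>       <dbl>     <dbl>        <dbl>
#> 1 TRUE              -10.7        0.0123        1.56      39.3         156.
```

A thin command-line interface (`exec/vhgate`, or `vhgate::main()`) exposes
`simulate`, `sweep`, `silence`, `overlap`, `mechanism`, `connectivity`,
`analyze-traces`, `occupancy` and `synth`, writing tidy CSV outputs with
JSON provenance sidecars and a `manifest.json` per output directory.

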