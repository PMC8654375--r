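---
title: "The vH output-gating circuit model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vH output-gating circuit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vhgate)
```

## The scientific question

The ventral hippocampus (vH) routes its output through parallel populations
of pyramidal neurons at the CA1/subiculum border, each projecting to a
single downstream structure: the basal amygdala (vH-BA), the nucleus
accumbens (vH-NAc), or the prefrontal cortex (vH-PFC). The basal amygdala
returns a mixed projection to vH that contains both excitatory axons and a
smaller contingent of long-range GABAergic axons. Slice mapping shows a very
specific wiring diagram:

* excitatory BA input targets vH-BA and vH-NAc neurons about equally and
  avoids vH-PFC neurons;
* long-range inhibitory BA input targets vH-BA neurons strongly, vH-NAc
  neurons weakly, and vH-PFC neurons not at all;
* local interneurons inhibit vH-NAc neurons about twice as strongly as the
  other pyramidal populations, and are themselves driven by pyramidal
  feedback.

`vhgate` implements a conductance-based leaky integrate-and-fire (LIF)
network that asks what this wiring does to the *routing* of vH output as
the inhibitory share of the amygdalar input grows. The headline result the
package reproduces: with no long-range inhibition the circuit output is a
reciprocal projection back to BA, and as the inhibitory share grows the
output switches to the accumbens pathway, with the difference between the
two populations peaking when roughly 40% of the input is inhibitory.

## The model

Every neuron follows

$$C_m \frac{dV}{dt} = g_L (E_{rest} - V) + g_{AMPA}(t)(E_{AMPA} - V) +
  g_{GABA}(t)(E_{GABA} - V)$$

with $C_m = 200$ pF, $g_L = 5.5$ nS, $E_{rest} = -70$ mV and a spike
threshold of $-35$ mV. Each synapse class is a single exponentially
decaying conductance per neuron ($\tau_{AMPA} = 5$ ms, $\tau_{GABA} =
10$ ms) that jumps by the connection weight whenever a presynaptic spike
arrives. The network holds 1000 neurons in each projection population and
80 interneurons. Local wiring: each pyramidal population contacts
interneurons with probability 0.1 at 1 nS (AMPA); interneurons contact
vH-NAc neurons with probability 0.8 and the other pyramidal populations
with probability 0.4, at 3 nS (GABA). Long-range input is modelled as two
ensembles of 50,000 independent 10 Hz Poisson sources (one excitatory, one
inhibitory), connected with probability 0.1 and per-connection weights
drawn from normal distributions fitted to the paired-recording amplitudes:
0.3 ± 0.2 nS onto vH-BA and vH-NAc (excitatory) and onto vH-BA
(inhibitory), 0.08 ± 0.2 nS inhibitory onto vH-NAc, and 0.03 ± 0.2 nS —
the "background" level — onto vH-PFC from both ensembles.

### Paper gaps filled by explicit defaults

The published description leaves several standard LIF parameters open. The
package fixes them as configurable defaults: reset potential equal to rest
($-70$ mV), a 2 ms refractory period, and reversal potentials
$E_{AMPA} = 0$ mV, $E_{GABA} = -75$ mV — all conventional values for
conductance-based cortical models.

### The direct drive onto interneurons

The slice experiments could quantify input ratios only between pairs of
simultaneously recorded *pyramidal* neurons; input strength onto
interneurons was observed qualitatively (connections exist, roughly half of
tested cells) but could not be calibrated. The circuit's documented
operating regime constrains it instead: local interneurons must be driven
predominantly by pyramidal *feedback*, because (a) vH-BA firing, via
feedback inhibition biased onto vH-NAc, is what silences the accumbens
pathway when inhibition is absent, and (b) inactivating vH-BA alone must
release vH-NAc. If interneurons received the same 0.3 nS-scale direct
ensemble drive as the strongly targeted pyramidal populations, they would
fire tonically near 260 Hz regardless of pyramidal activity, silencing
every pyramidal population at all inhibitory levels and breaking both
properties. The default therefore assigns the direct ensemble drive onto
interneurons the background weight class (0.03 ± 0.2 nS); the stronger
value is one config edit away (`projections` table), and
`run_connectivity_sweep()` exposes the local-connectivity robustness of the
result.

### The sweep axis: an input mixture

The swept quantity is the *proportion of the amygdalar input bundle that
is inhibitory*. The BA projection is anatomically a mixed bundle (a few
percent of retrogradely labelled BA neurons are GABAergic), so the natural
model of "x% inhibitory input" holds the total input budget fixed:
at proportion $f$ the excitatory ensemble connects with probability
$0.1(1-f)$ and the inhibitory ensemble with probability $0.1 f$
(`set_input_mixture()`). An additive variant that keeps excitation fixed
and only adds inhibition ($p_{inh} = 0.1 f$) is available via
`scale_inhibitory_input()` and `run_inhibition_sweep(..., mixture =
FALSE)`. Only the mixture reading produces an interior peak of the
vH-NAc − vH-BA difference with vH-BA effectively silent at the peak; under
the additive reading vH-NAc activity keeps growing until $f$ approaches 1
because its direct inhibition (0.08 nS weights) never catches up with its
fixed 0.3 nS excitation.

### Weight handling

Weight distributions such as $\mathcal{N}(0.03, 0.2)$ put substantial mass
below zero. The default (`weight_handling = "signed"`) keeps draws as
drawn: negative draws subtract from the summed conductance, preserving the
fitted population means exactly. Clipping at zero (`"clip"`) raises the
realised mean of the background class from 0.03 to ~0.096 nS (a factor
3.2) and of the weak inhibitory class from 0.08 to ~0.126 nS, materially
changing the balance the model is built on; it is provided as an option,
as is rejection resampling (`"resample"`, a truncated normal). One
consequence of the signed default: a neuron's summed synaptic conductance
can transiently be negative, so membrane potentials are not strictly
confined to the reversal-potential interval (they are under `"clip"`).

### Numerics

Integration uses exponential-Euler decay for the conductances and forward
Euler for the voltage at a default timestep of 0.1 ms; spikes are detected
on the grid, network spikes take effect on the following step, and external
ensemble spikes on the step they occur. Ensemble trains are realised by
per-step Bernoulli thinning (a binomial draw of the number of active
sources, then distinct ids); an exact exponential-gap sampler is available
in `generate_poisson_trains()`. Halving the timestep changes the totals of
the populations carrying the activity by well under 5% (the near-silent
populations, a few hundred spikes against tens of thousands, are dominated
by sampling noise and are not a meaningful convergence probe). Initial
membrane potentials are drawn uniformly between rest and 5 mV below
threshold: starting all neurons at rest produces one artefactual
synchronous population spike at ~2 ms, while initialising cells within a
fraction of a millivolt of threshold lets a handful fire before any
inhibition can build up; the 5 mV margin removes both artefacts. Silenced
populations are clamped at rest. Per-run child seeds derive from the master
seed by counter position (`child_seed()`), so grids can be extended without
reshuffling completed runs; by default every run redraws both connectivity
and input trains (`redraw_connectivity_per_run`).

### Overlap semantics

Real projection populations overlap: some neurons collateralise to two
targets. `apply_overlap(config, f, seed)` gives a seeded random fraction
$f$ of each population a second identity in each other population.
Dual-identity neurons receive the union of their identities' ensemble
input rules (independent draws summed), are inhibited at the maximum of
their identities' local-inhibition probabilities, and are credited to every
identity in the spike totals. At $f = 1$ all pyramidal neurons carry all
identities and the per-population totals coincide exactly.

### Mechanism modes

Because slice mapping cannot distinguish whether a weaker input reflects
smaller synaptic amplitudes or fewer connections, `set_mechanism_mode()`
re-expresses every ensemble projection in either convention:
`"amplitude"` (shared probability, population-specific mean weights — the
default) or `"probability"` (all weights at the 0.3 nS reference, each
probability rescaled by its weight ratio). Both preserve the expected
total conductance per neuron, and the switch and its peak location are
preserved across the two modes.

## What the simulations show

At full scale (3080 neurons, 100,000 sources), a 500 ms run takes a few
seconds; the default sweep (11 levels × 5 runs) takes several minutes on
one CPU. The reduced scale used by the test suite (200 neurons per
pyramidal population, 16 interneurons, 10,000 sources, weights scaled
fivefold to preserve per-neuron drive) runs the same sweep in about half a
minute with the same qualitative behaviour, at the price of larger
finite-size fluctuations.

```{r, eval = FALSE}
library(vhgate)
sweep <- run_inhibition_sweep(default_config(), seq(0, 1, 0.1), master_seed = 1)
autoplot(sweep)
find_peak_difference(sweep, "vH-NAc", "vH-BA")
```

With no inhibitory input, vH-BA fires vigorously (gamma-like bursts paced
by the feedback loop with the interneurons), vH-NAc is held at a few
percent of vH-BA's rate by the biased local inhibition, and vH-PFC is
silent. As the inhibitory proportion grows, direct inhibition suppresses
interneurons and vH-BA in parallel, releasing vH-NAc; past the peak the
declining excitatory share extinguishes all firing. The difference between
vH-NAc and vH-BA totals peaks at 0.4–0.5 across master seeds.
`run_silencing_experiment()` reproduces the in-silico inactivation
prediction: clamping vH-BA with no inhibitory input present increases
vH-NAc output roughly tenfold, because the dominant source of feedback
drive onto the interneurons disappears.

Two deviations of the faithful implementation from an idealised reading
are worth naming. First, at reduced scale a handful of vH-PFC neurons fire
(a few hundred spikes against tens of thousands): with fivefold-scaled
weight variance and only 16 interneurons, a few cells land in the
suprathreshold tail while drawing no local inhibitory connection — a
finite-size effect absent at full scale, where vH-PFC totals are exactly
zero at every grid level. Second, the peak of the difference lands at 0.4
or 0.5 depending on the seed; the two levels differ by a few percent of
the peak difference, within run-to-run noise.

## The analysis stages

The quantification rules mirror common practice for optogenetic circuit
mapping and are exercised against seeded synthetic data with known ground
truth:

* `detect_connection()`: a cell is connected when the trial-averaged
  response deflects, in the expected polarity, strictly more than 2
  baseline standard deviations from the baseline mean. Windows default to
  a 100 ms baseline ending 5 ms before the first stimulus and a 2–50 ms
  response window (the first 2 ms excluded as stimulus artifact); both are
  parameters carried in every result.
* `measure_amplitude()`: the mean over a 2 ms window centred on the
  response-window extremum, baseline-subtracted and reported positive;
  flat plateaus centre the window on the plateau; truncation at record
  edges is flagged.
* `pair_ratio()`: amplitude ratios of sequentially recorded neighbouring
  cells, with log10 transform for plotting; zero denominators are censored,
  never imputed.
* `intrinsic_properties()`: resting potential (pre-step mean), input
  resistance (Ohm's law on the smallest hyperpolarising step, steady state
  = last 20% of the step), sag (peak minus steady-state deflection), and
  spike counts by upward crossings of −20 mV.
* `occupancy_metrics()`: time-weighted side occupancy (each sample dwells
  until the next) and path length for real-time place-preference sessions
  in the 24 × 16 cm arena.

The generators (`make_psc_trace()`, `make_paired_cells()`,
`make_current_step_traces()`, `make_trajectory()`) are pure functions of
their seeds and record ground truth sufficient to predict every analysis
output. They emulate trial-averaged difference-of-exponentials currents
(kernel normalised analytically so its maximum equals the requested
amplitude), LIF-like current-step voltage responses with an alpha-shaped
sag component, and bout-structured reflected random walks whose realised
side occupancy is recorded exactly as the scorer computes it. They do not
model series resistance, space clamp, photostimulation artifacts, or
tracking noise — so passing recovery tests demonstrates correctness of the
quantification rules, not robustness to every pathology of real
recordings.

## Known limitations

* The network has no geometry, conduction delays, short-term plasticity or
  synaptic saturation; interneurons are a single homogeneous class with no
  mutual inhibition.
* Population totals over 500 ms are the only summary the experiments use;
  no attempt is made to reproduce spike-for-spike timing, and the
  integrator's one-step synaptic delay makes exact replication across
  timesteps impossible by design.
* The mixture interpretation of the inhibitory-proportion axis and the
  background-level interneuron drive are modelling choices defended above;
  both are single config edits for anyone wishing to explore the
  alternatives.
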