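---
title: "Methods: model, manipulations, and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, manipulations, and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(swimcpg)
```

This vignette documents how the pieces of `swimcpg` fit together: the
artificial-synapse kinetics, the hybrid integrate-and-fire circuit, the
experimental manipulations, the rule engines that analyze recordings, and the
population model that ties single-circuit mechanisms to cohort statistics.

## 1. Artificial synapse kinetics

The C2-to-VSI synapse is modeled as a sum of first-order activation
components. Each component `i` has weight `w_i` and time constant `tau_i`;
its activation `S_i` relaxes toward a sigmoid function of the presynaptic
voltage,

```
dS_i/dt = (S_inf(V_pre) - S_i) / tau_i,
S_inf(V) = 1 / (1 + exp(-(V - v_thresh) / v_slope)),
```

and the synaptic current is `I = g_syn * sum(w_i * S_i) * (V_post - v_syn)`.
With the postsynaptic cell at rest below the reversal potential the current
is outward (hyperpolarizing); depolarizing the cell above `v_syn` flips the
sign. The default kinetics use two slow components (700 ms and 1300 ms, equal
weights), matching the artificial synapse injected by the dynamic clamp.

```{r}
kin <- synapse_kinetics(g_syn = 1000)          # nS; v_syn = -80 mV
st  <- step_activation(kin, state = NULL, v_pre = 0, dt = 1)  # dt in ms
synaptic_current(kin, st, v_post = -50)        # pA, outward at rest
```

`clamp_trace()` integrates these equations along a recorded presynaptic
voltage trace and returns the current the clamp would inject; it is the exact
discrete-time reference that the compiled circuit core reproduces.

Subthreshold, each component decays as `S_0 * exp(-t / tau_i)`, and because
the system is linear in the components, a two-component response equals the
sum of the two single-component responses — both properties are enforced in
the acceptance tests.

## 2. The circuit model

`build_circuit(animal)` assembles a four-unit adaptive integrate-and-fire
network: DSI, C2, a VSI somatic compartment, and a VSI distal
spike-initiation zone. Key structural features:

- **Two VSI spike-initiation zones.** The distal zone sits beyond the nerve
  and is driven directly by C2; its spikes travel antidromically back to the
  soma through a conduction delay (`pdn6_delay`, 25 ms). Somatic spikes
  travel the other way. The recorded nerve channel places the electrode a
  fraction `pdn6_electrode_frac` of the way along the path, so nerve impulse
  times lead or lag soma events by only that share of the full delay.
- **Composite C2-to-VSI soma synapse.** The somatic compartment receives a
  fast depolarizing and a slow hyperpolarizing component whose amplitudes are
  calibrated per animal (`calibrate_direct_synapse`) so that, under synaptic
  isolation, the measured PSP reproduces the animal's phenotype `(d, h)` in
  millivolts.
- **Noise.** Each unit receives independent Gaussian current noise. The
  integration core draws exactly one normal variate per noisy unit per time
  step, *including refractory steps*, so that two simulations with the same
  seed but different switch settings (lesion, clamp, Hi-Di) see literally the
  same noise stream. This is what makes seed-matched paired comparisons exact
  rather than merely statistical.

Per-animal phenotype enters only through `virtual_animal()`: `h` and `d` (mV)
set the hidden synapse, `distal_gain` scales the C2 drive to the distal zone,
and `drive` scales the episode drive.

## 3. Manipulations

```{r}
circ <- build_circuit(virtual_animal(h = 2.9, d = 0.8))

apply_lesion(circ)                      # cut the nerve: no distal input,
                                        # no conduction, empty nerve channel
set_hi_di(circ)                         # high-divalent saline: raised spike
                                        # thresholds silence polysynaptic
                                        # pathways; direct PSPs remain
attach_dynamic_clamp(circ,              # artificial synapse at the soma
                     synapse_kinetics(g_syn = 1000),
                     mode = "add")      # or "subtract", "off"
```

In the intact circuit the distal zone dominates VSI output, so somatic
conductance injection does not change the burst count at all; after the
lesion the soma is the only initiation zone and the same injection abolishes
(`add`) or rescues (`subtract`) the rhythm. `simulate_episode()` runs a
stimulus protocol (`stim_swim()`, `stim_c2()`, `stim_none()`) and returns an
`episode_recording` with voltage channels, spike times, nerve impulse times,
and EPSP event annotations.

## 4. Rule engines

All analyses work from times and traces, never from simulator internals, so
they apply equally to synthetic fixtures:

- `detect_spikes()` — threshold crossing with refractory lockout, reporting
  peak times.
- `detect_bursts()` — partitions a spike train wherever the inter-spike
  interval exceeds `max_isi` (1 s default), drops groups below `min_spikes`,
  and can exclude a stimulus window. Verified against a brute-force
  gap-partition oracle on random trains.
- `match_and_classify()` — greedily pairs soma events with nerve impulses by
  smallest absolute lag inside a matching window; negative lag (nerve first)
  is antidromic, positive is orthodromic, near-zero lags within the ambiguity
  band are unmatched. Episode-level labels (`antidromic-only`, `mixed`,
  `orthodromic-only`) summarize the matched spikes.
- `classify_impulse_waveform()` — triphasic vs biphasic template shape of a
  nerve impulse, used to cross-check the lag-based classification.
- `measure_psp()` — baseline-referenced depolarizing peak and the
  hyperpolarizing trough that follows it, within a search window.

## 5. Statistics kit

`coef_variation`, `levene_median_test` (Brown–Forsythe, median-centered),
`linear_regression`, `percent_change`, `paired_t_test`, and `one_way_anova`
(with Holm–Šidák pairwise step-down). These are deliberately thin,
textbook-formula implementations validated against independent oracles to
1e-10 and, by simulation, shown to hold their nominal 5% level.

## 6. Population model and calibration

`generate_cohort(cohort_config(), seed)` draws virtual animals with truncated
normal `h` (2.9 ± 1.3 mV) and `d` (0.8 ± 0.36 mV) and assigns propagation
categories from the phenotype. Lesion outcomes at the cohort level come from
a count-level generator whose susceptibility mapping
`lesion_loss(h, n_max, coef)` has three coefficients, frozen in
`lesion_mapping_defaults()`. `calibrate_population_model()` re-derives those
coefficients from the population targets (`population_targets()`: intact and
lesioned CoV of motor and flexion counts, mean percent change) by a
deterministic grid search over seed-averaged replicates; failure to meet the
targets is reported in the returned object (`converged = FALSE`), never
thrown.

## 7. Experiments and reproduction

The five `run_*` experiments compose the above into the study designs
described in the README. Every experiment is a pure function of its
`experiment_spec` (configuration plus seed). The `analysis/` drivers
regenerate all results from scratch:

```{r}
# Rscript analysis/01_behavior_lesion.R
# ...
# Rscript analysis/07_hidden_phenotype_grid.R
```

and `scripts/acceptance.R` re-runs the full verification battery end to end:

```{r}
# Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
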