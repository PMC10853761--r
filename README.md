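# dynsort

Spike sorting of electrically evoked neural activity on dense
multi-electrode arrays (MEAs), despite the stimulation artifact.

Bi-directional neural interfaces — epiretinal prostheses above all — need
to know *which neurons fired* in the first millisecond after each current
pulse. The stimulation artifact is larger than any spike, occupies the same
frequency band, and outlasts the typical evoked-spike latency, so
conventional sorters fail exactly where calibration matters. `dynsort` is
for electrophysiologists and neural-interface engineers who have per-neuron
electrical images (EIs) from spontaneous activity and trial-structured
post-stimulation recordings, and want activation curves and stimulation
thresholds per neuron–electrode pair without manual curation.

## The method

Every source is a linear state-space system whose states are the voltages
on a subset of electrodes (`C` is a selection map):

    x_n^{t+1} = A_n x_n^t + B_n u_n^t,   y_n^t = C_n x_n^t        (EI of neuron n)
    x_a^{t+1} = A_a x_a^t + B_a u_a^t,   y_a^t = C_a x_a^t        (artifact)

Each EI model is driven by a fixed two-pulse input template `r_n` (the
pulses trigger the falling and rising phases of the spike); the artifact
model by a three-pulse template scaled by the stimulus current,
`u_a^t = q r_a^t`, with the stimulating electrode structurally excluded.
The models compose block-diagonally into an aggregate system whose output
is the superposition `y^t = Σ_n y_n^t + y_a^t + w^t`.

Sorting is inversion: a receding-horizon regularised least-squares input
estimator reconstructs, from an `L`-sample forward window with corrupted
electrodes removed and the known artifact input compensated, which EI
templates produced the measurement. Estimated input blocks are scored
against their templates (shift-maximised, amplitude-gated similarity); a
spike is called above a threshold. Calls aggregate into activation curves;
a logistic fit in log-amplitude yields the 50% stimulation threshold, with
K-fold artifact validation and threshold-set comparison by R².

A synthetic-data module generates the full study conditions — grid MEA,
axonally propagating biphasic EIs, radially decaying amplitude-scaled
artifact transients, Bernoulli activation with logistic thresholds,
Gaussian noise, and the standard protocol (39 log-spaced amplitudes
0.1–4.1 µA, 25 repeats, triphasic 2:−3:1 pulses) — so every stage is
testable against known ground truth.

## Worked example

Build a synthetic preparation (12×12 array, 5 neurons, fitted EI and
artifact models), invert one noisy trial in which neurons 0 and 2 fire at
latency 10 samples under a 2 µA artifact, and then recover activation
thresholds end to end:

```r
library(dynsort)

fx <- demo_models(seed = 1, rows = 12, cols = 12, n_neurons = 5)
fx$agg
#> <aggregate_model> 5 EI models + artifact: 124 states, 144 electrodes

r <- recovery_experiment(fx, firing_ids = c(0, 2), latency = 10, q = 2,
                         noise_std = 1, lambda = 1e-2, seed = 8)
r$calls
#>   neuron_id detected latency_samples      score
#> 1         0     TRUE              10 0.97521161
#> 2         1    FALSE              NA 0.01165778
#> 3         2     TRUE              10 0.99955702
#> 4         3    FALSE              NA 0.01441779
#> 5         4    FALSE              NA 0.13292429
```

The two firing neurons are recovered at the true latency with scores near
1; the silent neurons score near 0. The end-to-end study simulates the
full protocol (975 trials per stimulating electrode), fits the artifact
from low-amplitude trial averages, sorts every trial, and compares fitted
50% thresholds with the generating truth:

```r
ts <- threshold_recovery_study(seed = 1, n_stim = 1, kfold_K = 0)
ts$pairs[, c("neuron_id", "q50_true", "q50_est")]
#>   neuron_id  q50_true   q50_est
#> 1         0 0.3000000 0.2935664
#> 2         1 0.5097133 0.5054557
#> 3         2 0.8660254 0.8874567
#> 4         3 1.4714155 1.5220379
#> 5         4 2.5000000 2.4725500
sprintf("R^2 = %.3f, median relative error = %.1f%%", ts$r2, 100 * ts$median_rel_err)
#> [1] "R^2 = 0.999, median relative error = 2.1%"
```

`q50_true` is each neuron's generating 50% threshold in µA; `q50_est` is
what the pipeline recovers from the sorted spikes alone.

A thin command-line wrapper over the same functions lives at
`inst/cli/dynsort.R` (subcommands `run`, `simulate`, `fit-ei`,
`fit-artifact`, `sort`, `activation`, `compare`), and `run_pipeline()`
drives the whole chain from a YAML config.

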