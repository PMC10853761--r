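---
title: "Spike sorting of electrically evoked activity with linear dynamical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike sorting of electrically evoked activity with linear dynamical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynsort)
```

## The problem

Electrical stimulation through a multi-electrode array (MEA) evokes spikes
from nearby neurons, but the stimulation artifact — the voltage transient of
the electrode–electrolyte interface — is orders of magnitude larger than a
spike, overlaps it in time and frequency, and lasts longer (about 2 ms) than
the typical evoked-spike latency (0.4–0.6 ms). Conventional spike sorting
fails in this regime. `dynsort` separates evoked spikes from the artifact by
exploiting what a dense array measures and an isolated electrode cannot:
spikes and artifacts *propagate differently across space and time*.

## Models

Every signal source is modeled as a discrete-time linear state-space system
whose states are the voltages on a subset of electrodes (so `C` is a
selection map and the states are directly observed):

* **EI model** (one per neuron `n`): the electrical image (EI) is the
  neuron's mean spatiotemporal spike footprint, an `E x T` voltage template.
  The model `x^{t+1} = A_n x^t + B_n u_n^t`, `y_n^t = C_n x_n^t` lives on
  the electrodes where the EI is strong (by default, peak amplitude at
  least 10% of the neuron's global peak) and is driven by a fixed
  *input template* `r_n`: two unit-magnitude pulses that trigger the
  falling (depolarisation) and rising (repolarisation) phases of the
  spike. Output rows off the subset are identically zero.
* **Artifact model**: same structure on the electrodes around the
  stimulating electrode, driven by a three-pulse template at the first
  post-stimulus samples, scaled by the stimulus current:
  `u_a^t = q r_a^t`. The artifact is linear in `q`. The stimulating
  electrode itself behaves discontinuously with amplitude and is
  structurally excluded: never a state, never an output, never part of any
  error metric.
* **Aggregate model**: block-diagonal composition of all EI models plus the
  artifact model; by superposition the measured trace is the sum of the
  sub-model outputs plus i.i.d. Gaussian measurement noise at the output
  (no process noise).

**Input estimation.** Spike sorting is inversion: given a measured
post-stimulus window, which input templates were injected? Over a forward
window of `L` samples the aggregate output stacks into
`y^{t:t+L} = Phi x^t + G u^{t:t+L-1} + H u_a^{t:t+L-1}`. At each step the
state is propagated open loop with the inputs already estimated, the known
artifact input is compensated (stimulation timing and amplitude are known),
rows of corrupted electrodes are deleted, and the EI inputs over the whole
window are solved by ridge least squares — only the current step of the
window solution is retained (receding horizon). Solving the *whole* window
jointly matters: a variant that assumes future window inputs are zero is
biased whenever a pulse lies ahead inside the window and cannot reproduce
the exact noiseless recovery that the full method achieves. With
`lambda = 0` and a full-column-rank window map the inversion is exact to
round-off; the default `lambda = 1e-2` makes the solution unique and tames
noise at a negligible (~1%) shrinkage bias.

**Detection.** Each neuron's estimated 2-channel input block is compared to
its template. The default similarity pushes the block through the neuron's
own model and takes the cosine between that response and the response to
the template shifted over the candidate latencies, multiplied by an
amplitude gate `min(1, mag_ratio / 0.5)` where `mag_ratio` is the response
energy relative to the template response. The three ingredients each solve
a concrete failure mode observed on synthetic data:

* the window least squares smears a pulse across adjacent time steps whose
  response columns are nearly collinear, so the raw input-space cosine
  (available as `similarity()` and `method = "input"`) under-scores true
  spikes;
* a response-space cosine alone is shape-only and is fooled by leakage of
  *other* neurons' model residuals on shared electrodes — any concentrated
  input through a model produces a template-shaped response;
* a genuine spike carries the template's stereotyped amplitude
  (`mag_ratio` near 1), leakage does not.

Estimates with input norm below a tenth of a unit pulse score 0, extending
the all-zero convention to numerically negligible blocks (the cosine is
scale invariant, so round-off could otherwise score arbitrarily). A spike
is called when the score reaches `threshold` (default 0.5); at most one
spike per neuron per trial, since the 2.75 ms analysis window is shorter
than an inter-spike interval.

**Activation analysis.** Calls are aggregated per amplitude into an
activation curve; a logistic in *log*-amplitude (the grid is log-spaced)
is fit to the Bernoulli counts by maximum likelihood and the stimulation
threshold is the 50% point `q50`. Quasi-separated curves (e.g. a perfect
step) stop at the IRLS iteration cap with finite coefficients whose ratio
is still a well-defined threshold, so usability is judged on the
coefficients; all-0/all-1 curves are flagged, not errors. K-fold validation
(`K = 5`) refits the artifact model on K−1 trial folds and sorts the
held-out fold, so every probability comes from data unseen by the artifact
model that processed it. Threshold sets are compared by squared Pearson
correlation (default) with the identity-line R² also reported.

## Identification: why a modal realization

With observed states, the textbook estimator is a one-step least-squares
regression of `x^{t+1}` on `(x^t, u^t)`. On smooth spike trajectories it is
a trap: each transition fits to ~0.1%, but the open-loop rollout — the
only thing that matters for a template model — amplifies the residuals
through non-normal transients and collapses or explodes (normalised errors
around 1.0). `dynsort` instead builds a stable low-order *modal*
realization:

1. eigenvalues of the dynamics from a rank-truncated one-step map on the
   free-decay samples (after the rising pulse for EIs, after the
   three-sample onset for the artifact), clamped to magnitude ≤ 0.995
   (transients are stable by physics);
2. a variable-projection polish of those mode frequencies, minimising the
   reconstruction error directly (a small error in a slow mode otherwise
   accumulates along the tail), with mode columns equilibrated to unit
   norm in every least-squares solve;
3. spatial mode profiles by least squares, segment-wise for EIs (the fall
   and rise segments share modes, so one transition matrix propagates
   both);
4. the transition matrix as the minimum-norm reduced one-step map of the
   modal reconstruction — consistent with it by construction and, unlike
   an eigenvector-inverse modal form, numerically tame, so the operator
   powers used by the estimator stay accurate;
5. input columns of `B` launching each phase exactly at the template's
   pulse times.

When the data are exactly realizable by the model class the reduced
one-step map already reproduces every free transition at machine precision
and is used directly; round trips on model-generated data come back with
normalised errors near 1e-15, and the whole construction needs no
regularisation (`ridge` remains available as damping for ill-conditioned
mode bases). Template pulses are anchored at the *onset* of the falling
phase (the last sample before the dominant-electrode trace exceeds 2% of
its peak) and at the trough where the rise begins: the model's output is
identically zero before the first pulse, so a pulse placed mid-fall would
irrevocably discard the leading ~17% of spike energy.

The artifact fit first pools the per-amplitude trial averages into one
least-squares estimate of the *unit-amplitude* trajectory (the artifact is
linear in `q`), then realises that. Fitting amplitudes should be chosen
where trial averages are artifact-only: evoked spikes in the averages are
absorbed into the model and extrapolate with `q`, so the default studies
fit on the bottom quarter of the grid — below the lowest activation
threshold in the simulated preparations — with a 0.25 trimmed mean as a
second line of defence.

## The synthetic preparation

No recordings ship with the package; every analysis runs on synthetic data
whose ground truth is known.

* **Geometry**: rectangular grid, default 60 µm pitch (the demo studies use
  16×16 or 12×12 arrays; the full-scale system would be 16×32 = 512).
* **EIs**: a biphasic difference-of-Gaussians waveform (dominant negative
  lobe, smaller overshoot) whose onset latency grows with arc-length along
  a straight axon path (conduction 50 µm/sample = 1 m/s at 20 kHz) and
  whose amplitude decays as `exp(-d / 40 µm)` from the path; peak 60–120 µV.
  Deterministic given the placement seed.
* **Artifact**: sum of a fast (≈5 samples) and a slow (≈40 samples ≈ 2 ms)
  exponential transient, each spreading radially from the stimulating
  electrode with its own spatial constant (100 µm and 1.5× that — the
  slow, Faradaic-like component reaches farther than the fast capacitive
  one). Distinct spatial profiles make the truth exactly representable by
  the states-are-electrodes model class; a shared profile would force a
  structural misfit the method is not meant to model. The first
  post-stimulus sample is baseline zero, matching a model that starts from
  rest. Amplitude scaling is exactly linear.
* **Trials**: per amplitude × repeat, each neuron fires a Bernoulli draw of
  a logistic in log-amplitude (default slope 0.1, i.e. the 10–90% rise
  spans ~1.6× in current); firing neurons are inserted at a latency drawn
  uniformly from 8–12 samples (0.4–0.6 ms); i.i.d. Gaussian noise, default
  1 µV, is added. The default protocol is 39 log-spaced amplitudes from
  0.1 to 4.1 µA, 25 repeats, charge-balanced triphasic pulses with phase
  ratios 2:−3:1 at 50 µs per phase.

What the generator deliberately does **not** emulate: electrode saturation
and amplifier nonlinearity, amplitude discontinuities of the stimulating
electrode (it is excluded anyway), axon-bundle activation, spontaneous
background spikes (available as an option, off by default in the studies),
correlated or non-Gaussian noise, and EI non-stationarity. Passing the
validation suite therefore demonstrates correctness of the machinery and
robustness to measurement noise and model-vs-data mismatch of the fitted
kind — not robustness to every pathology of ex vivo data.

## Study designs and problem sizes

The validation studies (also recomputed by `scripts/acceptance.R`) use
sizes chosen to exercise the method well inside a laptop budget:

* exact inversion and exclusion checks: 16×16 array, 8 neurons, artifact
  at the centre electrode, windows of 55 samples;
* detector-vs-oracle agreement: 36 electrodes, 4 neurons, 200 noisy trials
  at 1 µV plus noiseless trials (the exhaustive oracle enumerates every
  neuron subset × latency combination, with a per-spike residual penalty
  of `15 noise_std^2` — pure residual minimisation provably overfits noise,
  absorbing a ~6σ² projection per spurious spike, while a real spike
  removes its full signal energy);
* noise sensitivity: common random numbers across conditions with
  antithetic noise pairs. The estimator is linear, so the noise-induced
  input error is identical in distribution however many neurons fire; the
  antithetic design cancels the noise-bias cross term exactly and exposes
  the genuine (ridge-bias) ordering between the 3-neuron and 1-neuron
  conditions, with the most spatially overlapping neuron groups firing;
* threshold recovery: 12×12 array, 5 neurons with true thresholds
  log-spaced over 0.3–2.5 µA, 2 stimulating electrodes (10 neuron–electrode
  pairs), the full 39 × 25 protocol per electrode, plus 5-fold artifact
  validation on the first dataset. The artifact state subset covers every
  electrode except the stimulating one: on a 660 µm-wide array the
  artifact's slow spatial tail is far above the noise floor everywhere,
  and a truncated subset leaves tens of µV unmodeled at the highest
  amplitudes, exactly where high-threshold neurons must be detected. On a
  physically larger array a finite radius is the economical choice.

## Numerical choices

Double precision throughout; voltages in µV, currents in µA, time in
samples at 20 kHz. Mode count capped at 12 with singular values kept above
1e-7 of the leading one; eigenvalue magnitudes clamped at 0.995; the
variable-projection polish never accepts a point worse than its start and
is skipped when the start is already at machine precision. The window
solver uses the ridge normal equations (`lambda = 1e-2` default); with
`lambda = 0` a rank-deficient window map is a hard error naming the
unidentifiable neurons, never a silent pseudo-inverse. Trial averages use
R's trimmed-mean convention. K-fold splits are stratified by amplitude.
Degenerate inputs (all-zero EIs, zero-signal artifacts, monotone traces
without a trough, empty electrode selections) raise errors at the point of
first contact.

## Limitations

The method inherits the superposition and linearity assumptions of its
models: nonlinear artifact behaviour (as on the stimulating electrode) must
be handled by exclusion, not modeling. Detection thresholds were chosen on
synthetic receiver characteristics, not against human-curated labels; the
defaults (`threshold = 0.5`, amplitude gate 0.5, `L = 10`) are exposed for
recalibration on real preparations. Only single-channel stimulation is
composed; multi-artifact aggregates and streaming operation are out of
scope.
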