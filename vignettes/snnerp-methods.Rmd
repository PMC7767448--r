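---
title: "Spiking-network modelling of ERP data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking-network modelling of ERP data: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnerp)
```

This vignette is the package's account of its science: what each stage of
the pipeline computes, which parameters matter and why their defaults are
what they are, what the synthetic cohort generator does and does not
emulate, and where the genuinely open design choices were decided.

## 1. The modelling chain

An averaged ERP epoch — a 62-channel × 1300-sample matrix in microvolts at
1 kHz — passes through four stages.

**Threshold-based spike encoding.** Each channel is reduced to a ternary
event train: `+1` when the one-step increase exceeds a threshold θ, `-1`
when the decrease does, `0` otherwise (strict inequalities, so a change
exactly at θ produces no spike; the first sample has no predecessor and is
always 0). Three threshold policies exist:

* `sd_scaled_global` (default): θ = α × SD of the first differences pooled
  over *all* channels of the sample. A whole-recording gain factor
  (amplifier scaling) cancels, but a channel whose signal changes more than
  its neighbours' produces more spikes — the scalp topography of signal
  change is preserved. This is the policy the regional weight analyses
  require: a per-channel threshold would erase exactly the topographic
  amplitude structure they measure.
* `sd_scaled`: θ resolved per channel. Fully scale-invariant per channel,
  retaining only each channel's temporal structure; kept because it is a
  common convention and useful when channel gains are not comparable.
* `absolute`: θ in signal units, used by the exact unit tests.

The default α = 2 yields sparse trains (roughly 5% of time steps) marking
statistically salient changes. The conventional α = 0.5 is available but
produces ~60%-dense trains; at that density every input neuron drives the
network at its refractory ceiling and the reservoir's activity stops
depending on the stimulus amplitude at all — sparseness is what keeps the
model input-driven.

**The 3D reservoir.** Neurons sit on the packaged 1471-site, 1-cm lattice
(`load_fixture("grid1471")`) spanning a brain-shaped ellipsoid in a
Talairach-like millimetre frame; the grid is a synthetic lattice with the
canonical site count, not the atlas itself, and is labelled accordingly.
Each montage channel claims its nearest free grid neuron (montage order
breaks ties), so scalp neighbourhood relations survive inside the model.
Wiring is small-world: a directed edge i→j is created with probability
`base_prob · exp(−d²/radius²)` for d up to the hard radius and never
beyond, giving a connection probability that decreases monotonically with
distance. Initial weights are uniform on (0, 1]; 20% of neurons are
inhibitory (all outgoing weights negated). When no radius is supplied it
resolves to 2.5 × the median nearest-neighbour spacing — 25 mm on the full
grid — so reduced grids built with `subsample_grid()` (deterministic
farthest-point thinning) keep a comparable connectivity density.

**Dynamics and plasticity.** Input neurons are spike *sources*: they emit
their channel's encoded events directly, with polarity, and a negative
event delivers `−w` along each outgoing edge (the single-matrix ternary
convention; an explicit two-channel dialect could be added, but the signed
delivery keeps the bookkeeping in one matrix). All other neurons are leaky
integrate-and-fire units: `u ← u·leak + Σ w·s` with a one-step axonal
delay, firing when `u >` the threshold, then resetting and ignoring input
for the refractory period. Treating input neurons as integrate-and-fire
units instead would let the refractory period swallow consecutive spikes
of a rising edge and let negative spikes merely hyperpolarise — in
practice that caps every channel's contribution at a few events per
deflection regardless of its amplitude, severing the link between signal
strength and network activity that the downstream statistics rely on.

Weights adapt by nearest-spike STDP with one pairing per spike per role:
when a neuron spikes, each incoming connection whose presynaptic neuron
spiked Δt steps before is potentiated by `a₊·exp(−Δt/τ)`, and each
outgoing connection whose postsynaptic neuron spiked Δt before is
depressed by `a₋·exp(−Δt/τ)` — but only counterpart spikes newer than the
neuron's *own* previous spike are eligible, so a single postsynaptic spike
cannot be re-depressed against an entire train of later presynaptic
spikes. Without that restriction a high-rate source accumulates unbounded
depression on its outgoing edges and the learned weights *decrease* with
input strength. Excitatory weights are clipped to `[0, w_max]`; inhibitory
weights mirror the rule on their magnitude.

**deSNN output layer.** One output neuron per training sample, fully
connected to the reservoir; synapse r is initialised `mod^order(r)` by the
rank of r's first spike (0 = earliest; silent neurons get 0) and
incremented by `drift` on each later spike. Test samples are encoded the
same way and labelled by the majority class among the k nearest trained
output neurons (Euclidean distance on weight vectors; majority ties break
by smaller mean distance, then class order). Leave-one-out
cross-validation re-initialises the reservoir for every fold, seeded by
the held-out sample's identity, trains STDP on the remaining samples in a
canonical order, then propagates all samples once with plasticity off to
build the output layer — so results are invariant to sample ordering.

## 2. Parameters, defaults, and why

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `tbr_thr` (α) | 2 | SD of pooled diffs | sparse, salient-change encoding; keeps the network input-driven |
| `base_prob` | 0.15 | – | small-world convention; ~6 edges/neuron on the full grid |
| `radius_mm` | 2.5 grid units | mm | compact support for the distance kernel |
| `inhibitory_fraction` | 0.2 | – | common cortical reservoir convention |
| `fire_threshold` | 1.2 | potential | unit-magnitude events and mean initial weight 0.5 make internal neurons coincidence detectors; at 0.5 single events trigger self-sustaining cascades and the reservoir decouples from its input |
| `leak` | 0.9 | per step | ~10-step membrane memory at 1 kHz |
| `refractory_steps` | 5 | steps | 5 ms, physiological order |
| `a_plus`, `a_minus` | 0.02, 0.01 | weight | potentiation-dominant 2:1: up/down spike pairs produced by every waveform deflection otherwise cancel, and weights are meant to grow with the causal spike traffic a connection carries |
| `tau_ms` | 10 | ms | STDP pairing window |
| `w_max` | 2 | weight | bounds runaway potentiation |
| `mod`, `drift`, `k` | 0.9, 0.25, 1 | – | standard deSNN rank-order settings |

All of these are recorded in every experiment's `config.json`.

One seed policy covers the pipeline: every random draw is keyed by
`seed_for(base_seed, stage, identifier...)`, a stable 31-bit hash, so runs
are byte-reproducible and independent stages draw from independent
streams. Unsupervised per-sample models share one wiring draw per stimulus
(`seed_for(base, "wiring", stimulus)`): initial wiring is nuisance for the
group/time/participant contrasts, and sharing it turns those contrasts
into paired comparisons; leave-one-out folds, by contrast, deliberately
re-draw the wiring per fold as part of the evaluation protocol.

## 3. The synthetic cohort generator

The generator emulates the *design* of a two-group mindfulness-style
oddball study, not raw EEG. Each sample is an averaged ERP built from
three Gaussian-in-time components summed through band-wise topography
gains: a 100-ms, −4 µV negativity (SD 30 ms) and a 200-ms, −3 µV
negativity (SD 40 ms), both frontocentral-maximal, plus a +6 µV late
positivity (SD 60 ms) that peaks occipitoparietally at 340 ms for targets
and frontally at 320 ms for distractors — making the anteriorisation of
the distractor response a plantable, recoverable property.

Two effects are planted on top:

* **Training effect:** frontal-channel component gains of
  experimental-group samples at post-training time points are multiplied
  by `1 + frontal_gain_delta`; the default 1 (a doubling) is in line with
  the magnitude of reported post-training frontal connection-weight
  increases and is the "large effect" the recovery analyses assume.
* **Trait coupling:** each participant carries a latent right-frontal gain
  factor (`latent_gain_sd` = 0.15 around 1) multiplying the right-frontal
  component gains at all time points. FFMQ correlates with this latent at
  `psychometric_coupling` (default 0.6); BDI and the DASS subscales couple
  with the opposite sign through the same latent.

Noise is additive Gaussian, independent across channels, with marginal SD
`noise_sd_uv` (default 1 µV — the residual of averaging a few dozen
band-limited single trials) and temporal smoothness set by a Gaussian
autocorrelation kernel of SD `noise_smooth_ms` (default 12 ms). The
smoothness default matters and was chosen on signal-processing grounds:
the residual background of an averaged, 0.1–30 Hz-filtered ERP is
dominated by alpha-band and slower activity, and a 12-ms kernel reproduces
that sub-15 Hz concentration. White noise at 1 kHz (available via
`noise_smooth_ms = 0`) is not a realistic model of an averaged ERP — it
puts essentially all first-difference variance into the noise, where no
derivative-based encoder can see the waveform.

What the generator does **not** emulate: single trials, ocular or muscle
artefacts, volume-conduction correlations between channels, reaction
times, or any nonstationarity across the epoch. Passing the recovery
suites therefore shows that the pipeline detects the planted structure
under idealised averaged-ERP conditions; it does not certify performance
on raw recordings.

## 4. Statistics

Trained models are summarised by their activation level (mean |w| over all
connections; the absolute value stops inhibitory edges cancelling
excitatory ones — signed means are available via a flag) and by 5-site ×
2-hemisphere regional means: each reservoir neuron belongs to the region
of its nearest input channel (Voronoi over input-neuron coordinates) and a
connection to its *presynaptic* neuron's region (postsynaptic and midpoint
attribution available). Midline-cluster connections count toward model
totals but no hemispheric cell; cells with no member connections are
reported `NA` and flagged, never silently zero.

`rm_anova_gg()` runs univariate repeated-measures ANOVA (type-III sums of
squares via `car::Anova` on a multivariate linear model) with
Greenhouse–Geisser correction for every within effect with more than one
numerator df; two-level factors have ε = 1 by construction, and ε is
bounded below by 1/(levels−1). Effect size is partial η² =
SS_effect/(SS_effect + SS_error). The correction is guaranteed
conservative (corrected p ≥ uncorrected p) whenever F ≥ 1; for F < 1
shrinking both dfs can lower the p value, which is immaterial since such
effects are far from significance either way. `kendall_tau_matrix()`
computes tie-corrected Kendall τ-b with two-sided p values; constant
variables are flagged undefined rather than reported as zero. No
multiple-testing correction is applied by default (a Benjamini–Hochberg
flag exists), matching common practice for these designs.

## 5. Numerical and degenerate-input choices

* Discrete 1-ms time steps (matching 1 kHz sampling) with a one-step
  axonal delay on every edge; unsupervised learning makes one pass per
  sample by default (`passes` configurable).
* Simultaneous spikes (Δt = 0) never pair in STDP — causality requires at
  least one step.
* Encoding ties (|diff| exactly θ) produce no spike.
* A constant signal under an SD-scaled threshold is an explicit error, not
  an all-zero train, because the threshold is undefined there.
* Input-map conflicts (two channels nearest to one neuron) fall through to
  the next-nearest free neuron in montage order; uniqueness is verified at
  fixture build time.
* Classifier majority ties break by smaller mean neighbour distance, then
  by class order, so classification is fully deterministic.
* The label-permutation control scores predictions against the *original*
  labels, making the chance level exactly 1/c for c balanced classes;
  scoring against the shuffled labels gives the slightly smaller
  leave-one-out chance level (n_c − 1)/(n − 1), and both options are
  exposed.

## 6. Problem sizes in the shipped analyses

The validation studies use reduced reservoirs so that the full suite runs
comfortably on a single CPU: 200-neuron farthest-point grids for the
replicate studies (50 cohort replicates for the planted Time×Group effect;
20 replicates of 100 participants for the FFMQ coupling) and 80-neuron
grids for fold-count, chance-level and orchestration checks. The planted
Time×Group recovery evaluates the frontal-site ANOVA with stimulus and
hemisphere as additional within factors — the design-matched analysis —
and detects the default effect in essentially every replicate; the
chance-level control sits at 1/3 within Monte-Carlo error.

## 7. Known limitations

* The spike-level dynamics are a minimal LIF/STDP system: no conductance
  synapses, no delay learning, no homeostasis.
* Regional attribution by nearest input channel is a coarse parcellation
  of a 1-cm grid; on 200-neuron reduced grids single cells can hold few
  connections and correspondingly noisy means.
* The deSNN accuracy on the default synthetic cohort is well above chance
  but far from ceiling: post-training time points differ only through the
  planted frontal gain, and two of the three classes share it.
* The packaged montage coordinates are a standard spherical-projection
  approximation scaled into the grid's frame, adequate for
  nearest-neighbour mapping, not for source modelling.
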