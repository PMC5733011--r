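---
title: "Sequence learning in spiking reservoirs with combined Hebbian and heterosynaptic plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence learning in spiking reservoirs with combined Hebbian and heterosynaptic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(resplast)
```

## The model

`resplast` simulates a two-layer recurrent spiking network: an input layer
of Poisson spike generators (one channel per image pixel) projecting onto a
reservoir of leaky integrate-and-fire (LIF) neurons, 80% excitatory (E) and
20% inhibitory (I). Recurrent pathways E→E, E→I, I→E and I→I are sparse
random Bernoulli graphs; only the connections onto excitatory neurons
(In→E and E→E) are plastic. There is no readout layer: recognition and
sequence generation are read directly from population spiking activity.

A LIF membrane obeys

$$\tau_m \frac{dv}{dt} = -(v - v_{rest}) + I_{syn}(t)\,\tau_m ,$$

integrated exactly per 0.5 ms step with the current held constant over the
step. A neuron fires when $v \ge v_{thresh} + \theta$, resets to
$v_{reset}$ and is refractory for $t_{ref}$. The homeostatic offset
$\theta$ (excitatory neurons only) grows by $\theta_+$ at every spike and
decays exponentially with $\tau_\theta$, so chronically active neurons
become harder to excite. Synapses are current-based with exponential
kinetics (decay $\tau_{syn,E}$ for excitatory pathways, $\tau_{syn,I}$ for
inhibitory ones); inhibitory charge per spike exceeds excitatory charge.

Three plasticity processes act simultaneously during training:

1. **Power-law STDP on In→E synapses.** When a post-synaptic neuron
   fires, every input synapse onto it changes by
   $\Delta w = \eta\,(x_{pre} - \text{offset})\,(w_{max} - w)^{\mu}$,
   where $x_{pre}$ is the pre-synaptic trace ($\tau_{pre} = 30$ ms,
   incremented by 1 at each pre spike). Pixels active shortly before the
   post spike potentiate; silent pixels depress. With $\eta = 0.05$,
   $w_{max} = 1$, offset $= 0.4$, $\mu = 0.9$.
2. **Exponential weight-dependent STDP on E→E synapses.** On a pre
   spike, $\Delta w = -\eta_1\, x_{post}\, w^{\mu}$; on a post spike,
   $\Delta w = +\eta_2\, x_{post}\, x'_{pre}\,(w_{max} - w)^{\mu}$, with
   fast traces $\tau'_{pre} = 10$ ms, $\tau_{post} = 20$ ms and slow rates
   $\eta_1 = 0.002$, $\eta_2 = 0.01$, $w_{max} = 0.5$. Because the
   potentiation term carries the *product* of two short traces, it only
   outweighs depression when pre and post fire within tens of
   milliseconds repeatedly — precisely at character transitions and
   within co-active groups.
3. **Non-Hebbian heterosynaptic decay on E→E synapses.** At every step,
   $dw/dt = -\gamma(t)\,(w - w_0)$ with
   $\gamma = k_{decay}\, x_{post}^2\,\bigl(1 + \theta/|v_{thresh}|\bigr)$
   and baseline $w_0 = 0.2$. The rate grows with the squared post trace
   and with the homeostatic threshold, so neurons that fire because of
   strong recurrent feedback — not because of their input — have their
   recurrent weights relaxed toward baseline. This curbs dominant
   attractor states and keeps the generated word distribution diverse.

The decay formula deserves a note: the threshold factor is written as
$1 + \theta/|v_{thresh}|$, a dimensionless magnitude that is 1 for a fresh
neuron and grows with the homeostatic offset. Writing it literally as
$(v_{thresh} + \theta)$ with the conventional negative $v_{thresh}$ would
make the rate negative; the decay is proportional to the *magnitude* of
the effective firing threshold.

## Training and generation protocol

Each word is presented as its characters in sequence, 350 ms each at
dt = 0.5 ms, Poisson-encoded with per-pixel rates proportional to
intensity (63.75 Hz at full intensity). Membrane state is *not* reset
between the characters of a word — this is what allows the E→E pathway to
bind consecutive characters — and each word is followed by a 300 ms
silent rest in which every variable except $\theta$ relaxes. Words are
presented in a fresh random order (one epoch by default).

After training, plasticity and threshold adaptation are frozen and each
excitatory neuron is assigned the character label for which its mean
spike count across test variants is maximal (ties to the lowest label;
never-firing neurons stay unassigned).

Generation is readout-free: present the first character for one window,
rank the per-label mean spike counts, and

* if the top-1/top-2 gap exceeds `gap_threshold` (10 spikes per window,
  per-neuron group mean), the word is complete;
* otherwise the top-2 label names the next character to present (top-3 if
  the top-2 label is the character just shown, since immediate repetition
  cannot be represented); the trial hard-stops at `length_cap` (10).

## Calibration of the operating point

The published constants above leave open the current units (the
per-pathway gains), the synaptic time constants, and the homeostasis
constants. These were calibrated once, against the qualitative operating
regime the method itself requires, and are the package defaults:

* **Per-neuron input-weight budget.** Each excitatory neuron's In→E
  column sum is held fixed (mean weight `w_norm_mean = 0.2` times its
  fan-in) by divisive normalization after every presentation. Without a
  budget, spike-gated potentiation is self-reinforcing: a fixed subset of
  neurons saturates all its pixel weights, fires for every character, and
  no receptive-field differentiation can occur (silent neurons never
  update). The budget forces within-neuron competition among pixels and
  is what makes single-character receptive fields emerge.
* **Gains** (`default_gains()`): input and E→E gains set so that matched
  character drive exceeds the firing threshold by a wide margin, the E→I
  gain set so the inhibitory population responds to a single active
  character group without saturating at its refractory ceiling, and the
  I→E return sized for soft winner-take-all: character groups compete,
  but co-activation of a primed successor group remains possible (the
  top-2 mechanism depends on it).
* **Homeostasis** ($\theta_+ = 0.01$ mV, $\tau_\theta = 3\times10^5$ ms). A
  quasi-permanent threshold (the $10^7$ ms scale often used for MNIST-style
  feed-forward training) acts as a pure spike counter here: with a small
  corpus it ratchets every neuron to a near-silent margin and inference
  rates collapse below the gap threshold's scale. The shorter constant
  gives an equilibrium $\theta^\ast \approx \theta_+ r \tau_\theta d$
  (duty cycle $d$), which equalizes duty across neurons while leaving
  winner groups firing at tens of Hz — the regime in which the 10/20 ms
  trace products of the E→E rule are non-negligible.
* **Synaptic kinetics** ($\tau_{syn,E} = 5$ ms, $\tau_{syn,I} = 2$ ms).
  The excitatory constant extends a character group's firing tail across
  the character boundary, creating the pre-before-post co-firing window
  through which consecutive-character association is learned.
* **Decay constant** `k_decay = 3e-5`/ms: with the threshold factor
  included, effective $\gamma$ at a hyperactive post neuron relaxes its
  incoming weights on the few-hundred-millisecond scale, strong enough to
  suppress weight crowding (ablation: disabling the decay raises the
  Gini concentration of E→E weights and collapses generation diversity)
  while leaving learned word-pair structure above baseline.
* **Size scaling.** Recurrent fan-in grows with the reservoir size N, so
  the recurrent gains are scaled by $N_{ref}/N$ (reference 200): the
  per-group recurrent drive, and with it the balanced operating point,
  is then invariant across the 200-, 400- and 500-neuron setups.
* **Fixed-pathway weights** are random uniform draws whose per-pathway
  upper bounds variance-match the initial E→E block. This serves the
  spectral analysis twice over: homogeneous block variances are what
  make the untrained eigenvalue spectrum a uniform (Girko) disc, and
  they hand the E→E block — the only block learning changes — the
  dominant share of the spectral variance, so that training visibly
  contracts the disc. Pathway strength in the dynamics is carried by the
  gains, calibrated to the fixed-pathway means.
* **Gaussian-profile experiment**: the input gain is raised 6× over the
  imagery default (a 5 Hz bump carries roughly an order of magnitude
  less input charge than 45 Hz glyph imagery) and 400 bump presentations
  are used — the point where the E→E distribution has equilibrated with
  its mean at the decay baseline, so the spectral contraction (radius
  and unstable-mode count) is stable across seeds.

## The synthetic glyph generator

Characters are rendered from a built-in 7×7 block font, upscaled ×4 to
28×28 (an optional stroke dilation exists but is off by default: thicker
strokes blur near-subset character pairs such as C and O).
Per-instance variability — ±2 px translation, ≤5% pixel flips, intensity
jitter on the 200–255 band — stands in for the intra-class diversity of
handwritten data. At the default settings nearest-template classification
recovers ≥99% of variants, so class identity is preserved.

What the generator does *not* emulate: correlated stroke deformations
(slant, curvature), varying stroke width within a character, and the
heavy between-writer variability of real handwriting. Block glyphs also
have sharper between-class overlap structure than handwriting — some
pairs are near-subsets (C ⊂ O), others nearly disjoint (A vs T). Passing
the packaged tests therefore demonstrates the mechanism under controlled
intra-class noise, not performance on real handwritten corpora.

The Gaussian-profile demonstration uses a bell-shaped rate profile
(population average 5 Hz) over 400 input channels whose *center is drawn
uniformly* across the input range on each presentation. A single fixed
center cannot produce the topographic (diagonal) weight structure that
the experiment is meant to exhibit; the drifting-bump ensemble is the
package's reading of that experiment.

## Numerical choices

* Exact exponential updates per step for the membrane leak, synaptic
  currents, traces and $\theta$; the heterosynaptic decay uses the
  forward map $w \leftarrow w - \gamma\,dt\,(w - w_0)$ with a stability
  guard $\gamma\,dt < 1$.
* Spikes propagate with a one-step (0.5 ms) synaptic delay.
* Within a step: currents decay → spikes delivered → traces decay →
  membranes integrate and spike → plasticity (reading traces *before*
  this step's increments, so a trace reflects strictly earlier spikes;
  this matches the triplet-rule convention in which the trace of the
  neuron triggering an update is read just before its own increment) →
  trace increments → threshold decay.
* Update order within the plasticity stage: input-rule potentiation at
  post spikes, then E→E depression at pre spikes, then E→E potentiation
  at post spikes, then the decay, then clipping to $[0, w_{max}]$.
* Ties in the neuron→label argmax break toward the lowest label index;
  ties in top-2 ranking resolve by label order.
* The C++ engine is mirrored by a pure-R reference implementation
  (`run_segment_r()`); the test suite holds them to $10^{-10}$ agreement
  on identical inputs, and holds the trace-based updates to a full-history
  brute-force oracle at the same tolerance.

## Diagnostics

`eigen_spectrum()` diagonalizes the signed recurrent matrix (all four
pathways; excitatory columns positive, inhibitory negative). Before
learning the eigenvalues fill a disc (circle law — checked by a KS test
of $|\lambda|^2$ against uniform inside a robust bulk radius, since the
E/I mean structure contributes a few outliers); modes with real part
above 1 index chaotic dynamics. After training the E→E block, the bulk
contracts and unstable modes are depleted, because learning moves E→E
weights from their broad initial distribution toward the tighter
decay-governed one. This is also why the E→E initialization is uniform on
$[0, w_{max}]$: the untrained reservoir must start in the
strongly-recurrent regime that learning subsequently contracts.

`pca_trajectories()` projects binned population rates (10 ms bins, 50 ms
boxcar) on leading principal components; `noise_sweep()` injects Gaussian
current noise ($I \mathrel{+}= N_0\,\mathcal{N}(0,1)$ per neuron per
step) during testing with each character's Poisson realization frozen, so
across-trial dispersion isolates the effect of the noise; dispersion is
the across-trial standard deviation of binned rates averaged over time,
computed within trials sharing a starting character.

## Problem sizes used by the packaged checks

The packaged tests and the acceptance script run the dictionary
experiments at reduced scale — 200-neuron reservoirs, 50–100 training
representations per word and 20–100 generation trials — and the
Gaussian-profile experiment at 80 presentations. These sizes were chosen
as the smallest at which the qualitative phenomena (selective receptive
fields, spectrum contraction, decay ablation contrasts) are stable across
seeds.

## Known limitations

* **Sequence generation is the weak link of the pipeline.** Character
  recognition is reliable (selective receptive fields; own-group
  responses of ~10 spikes per window against ~1–3 for other groups) and
  word termination is clean (terminal top-2 gaps above the threshold),
  but the *directed* cross-character associations that drive mid-word
  continuation are structurally hard to learn with the stated rule
  constants: the E→E potentiation term carries the product of 10/20 ms
  traces while the depression term does not, so potentiation outruns
  depression only when the pre-synaptic group keeps firing above
  ~50–70 Hz across the character boundary. Once competition sharpens
  recognition, a group's tail dies within tens of milliseconds of a
  character switch unless the consecutive glyphs share pixels — so
  near-disjoint pairs (A→T) never associate, while within-window
  co-activation builds symmetric, partly spurious structure
  (back-transitions). At the packaged scales the dictionary experiments
  therefore recognize and terminate well but emit full dictionary words
  in only a minority of trials, far below the reference accuracy
  reported for handwritten-character corpora.
* Words with repeated characters collapse (the top-2 rule cannot emit
  the same character twice in a row); such words are flagged by the
  corpus generator.
* The homeostatic equilibrium couples to character duty cycles: characters
  that appear in many words acquire higher thresholds, which can bias
  the top-1 label for near-subset glyph pairs.
* Conductance-based synapses, axonal delays and structured topologies are
  out of scope.
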