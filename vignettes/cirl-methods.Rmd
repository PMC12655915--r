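---
title: "Confounder-invariant representation learning for e-nose time series: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounder-invariant representation learning for e-nose time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chemiresistive electronic noses digitize an aroma as a multichannel
resistance time series (here 32 channels at 1 Hz). In breath analysis the
dominant nuisance factor is relative humidity: exhaled air is nearly
saturated, water competes for adsorption sites and distorts every channel,
and — worse — humidity is often *spuriously correlated with the class
label* in a training campaign (e.g. when case and control samples are
collected in different sessions or ambient conditions). A classifier
trained on such data can silently learn the humidity shortcut and collapse
when deployed under different humidity conditions.

This package implements an adversarial disentangled autoencoder for that
setting. A shared temporal-convolution encoder maps an input recording
$X \in \mathbb{R}^{L \times 32}$ into two latent codes: a task code
$z_{\mathrm{task}} \in \mathbb{R}^{32}$ and a confounder code
$z_{\mathrm{conf}} \in \mathbb{R}^{20}$. Four heads are trained jointly:

* a decoder reconstructing $X$ from $(z_{\mathrm{task}}, z_{\mathrm{conf}})$,
* a classifier predicting the label from $z_{\mathrm{task}}$ only,
* a confounder predictor (the adversary) reconstructing the co-recorded,
  z-scored humidity trace $C$ from $z_{\mathrm{task}}$, connected through a
  gradient-reversal layer,
* and nothing reads $z_{\mathrm{conf}}$ except the decoder — confounder
  information is free to live there, and reconstruction pressure puts it
  there once the adversary has chased it out of $z_{\mathrm{task}}$.

The composite objective is

$$L_{\mathrm{total}} = \lambda_{\mathrm{rec}} L_{\mathrm{rec}}
  + \lambda_{\mathrm{task}} L_{\mathrm{task}}
  - \lambda_{\mathrm{conf}} L_{\mathrm{conf}},$$

with masked mean-squared error for $L_{\mathrm{rec}}$ and
$L_{\mathrm{conf}}$, class-weighted cross-entropy for $L_{\mathrm{task}}$,
and defaults $\lambda = (1.0, 1.5, 0.3)$. The minus sign is realized by
the gradient-reversal connector: on the forward pass it is the identity;
on the backward pass it multiplies the gradient flowing from the adversary
into the encoder by $-s$ (reversal scale $s = 1$ by default, constant —
no annealing schedule). Two optimizers run per batch: the main one
(Adam, learning rate $3 \times 10^{-4}$) updates encoder, decoder and
classifier on $L_{\mathrm{total}}$; a second (Adam, $3 \times 10^{-3}$)
updates only the adversary to *minimize* $L_{\mathrm{conf}}$. The matched
baseline shares the encoder and classifier but uses a single unified 52-d
latent (equal capacity: $32 + 20 = 52$), no decoder and no adversary, at
its own tuned learning rate $10^{-3}$.

We keep the adversary's learning rate an order of magnitude above the
encoder's. When the adversary tracks its own optimum closely, the reversed
gradient received by the encoder approximates the gradient of the *actual*
conditional reconstruction error of humidity given
$z_{\mathrm{task}}$ (an envelope argument), which is the quantity the
encoder should be ascending. Empirically this choice turns the
training-time adversary validation MSE from a flat trace into the steadily
increasing one the method predicts; with a slow adversary the encoder
merely exploits its momentary weaknesses.

## Preprocessing

Each raw recording passes, in order:

1. **Ambient normalization** — per channel,
   $x' = x / \mathrm{median}(x_{\mathrm{baseline}}) - 1$, with the
   baseline window equal to the full ambient phase (first 30 samples) and
   the midpoint convention for even-length medians. This removes
   inter-sensor gain differences and each recording's own baseline state.
2. **Truncation** at the recovery-phase terminus plus a 60 s buffer
   (170 timesteps for the default protocol).
3. **Right zero-padding** to the dataset-wide maximum length with a
   boolean validity mask; padded positions are excluded from every loss
   and statistic (tested by perturbation).

The humidity target is z-scored with *training-fold* pooled moments, so a
humidity-blind predictor scores MSE on the order of the target's variance
and a perfect one near 0, making probe MSEs comparable across datasets.
The pipeline is deliberately not idempotent: recordings flagged as
normalized are rejected rather than silently renormalized. Class weights
$w_c = n/(K n_c)$ compensate imbalance in the task loss.

## The synthetic e-nose generator

The datasets the method was designed for (breath and headspace campaigns)
are not distributable, so the package ships a generative stand-in that
reproduces the *structure* of the problem, not any particular device:

* **Protocol**: 30 s ambient / 30 s exposure / 50 s recovery + 60 s
  buffer at 1 Hz — 170 timesteps.
* **VOC response**: first-order adsorption ($\tau_a = 8$ s) toward a
  class-specific per-channel amplitude pattern, first-order desorption
  ($\tau_d = 20$ s). The default patterns are smooth functions of channel
  index (amplitude 0.035, class modulation 0.30) so classes overlap and
  the class pattern alone leaves residual uncertainty — which is what
  makes the humidity shortcut genuinely valuable in-distribution.
* **Humidity**: rises toward a per-sample peak level with the adsorption
  constant and decays with a slower $\tau = 40$ s (water desorbs
  sluggishly — the familiar humidity hysteresis), with per-sample
  log-normal kinetics variability (CV 0.4, breath-flow variation).
  Ambient humidity varies across recordings (s.d. 0.15 around 0.40,
  clipped to [0.1, 0.7]), as in an uncontrolled lab.
* **Confounding**: each channel is distorted affinely in the humidity
  excess, $X = \mathrm{clean} \cdot (1 + \gamma_i h) + \beta_i h$, with
  per-channel gain pattern $\gamma$ (scale 0.4) and offset pattern
  $\beta$ (scale 1.0). Because the clean response multiplies the gain
  term, the distortion interacts with the class signal, and the
  across-sample humidity variability dominates the across-sample VOC
  variability — the "humidity dwarfs the signal" regime.
* **Spurious correlation**: in training data the peak humidity level is
  drawn from class-conditional Gaussians inside the breath range
  [0.85, 0.99], with label correlation $\rho = 0.6$. The
  `decorrelated` split draws the same marginal independently of the
  label; the `range_shift` split draws levels from the disjoint interval
  [0.55, 0.70] — the generalization test: a model that leans on the
  humidity shortcut faces test humidity outside anything it saw, and
  uncorrelated with the label.
* **Nuisance realism**: per-sample response gain (CV 0.2,
  breath-to-breath variability), per-sample per-channel sensitivity
  jitter (s.d. 0.5, sensor-state variability), Gaussian noise
  (s.d. 0.01) and slow baseline drift (random walk, s.d. 0.002/step).
  The sensitivity jitter is what makes the class pattern statistically
  marginal at realistic sample sizes, so that the humidity shortcut is
  genuinely tempting for an unconstrained model.

What the generator does **not** emulate: adsorption chemistry (no
isotherms), temperature coupling, sensor aging beyond drift, device-to-
device transfer, and real cross-sensitivity spectra. Passing the packaged
benchmark therefore demonstrates that the adversarial mechanism removes a
measured, structured confounder under a controlled shift — not that any
particular clinical performance would be attained on real breath data.

## The packaged benchmark study

`runStudy()` is the fixed experiment the test suite and
`scripts/acceptance.R` both run: per seed, a confounded training pool
(n = 400, $\rho = 0.6$), a range-shifted test set (n = 200), the three
variants (baseline / reconstruction-only / full adversarial model) trained
for up to 60 epochs (batch 32, early stopping patience 15 on validation
macro-F1), shifted-test macro-F1 for each, and — on the first three
seeds — post-hoc probe MSEs and the trend of the adversary's validation
MSE. Probes are fresh confounder-predictor networks (no reversal) trained
for 100 epochs (patience 10) from frozen latents. The epoch budget is
deliberately identical across variants; it is part of the study
conditions, chosen so a full five-seed study runs in minutes on one CPU
core. The reduced architecture (filters 32/16/8, same latent split
32 + 20, same kernel/stride/activations) is used for the same reason; the
full published geometry (filters 256/128/64) is constructed and
shape-checked in the tests.

Two measurement conventions deserve explanation:

* **Early stopping and model selection.** Training monitors validation
  macro-F1 and returns the best-validation parameters, with ties broken
  toward the *most recent* epoch; patience counts epochs since the best
  score was last matched. The tie-break matters for the adversarial
  variant: validation data are in-distribution, where the humidity
  shortcut still works, so validation F1 is blind to invariance — among
  equal-validation epochs the later one has had more adversarial
  refinement and is the scientifically preferable model. The same rule,
  budget and patience apply to every variant.
* **Adversary-trend burn-in.** The adversary starts from random weights,
  so its validation MSE first *falls* while it learns to read the latents
  at all; the encoder-driven purge only shows afterwards. The trend
  statistic is the least-squares slope over epochs after a fixed 10-epoch
  burn-in.

Probe MSEs are reported on two held-out splits. On the range-shifted
split, a purged $z_{\mathrm{task}}$ yields large probe MSE (the probe can
only reproduce training-range traces, which sit far from the shifted
ones), and this is the regime where the invariance claim has teeth. The
confounder code is additionally probed on an in-distribution
(decorrelated) split: recovering the *absolute* shifted humidity trace
from $z_{\mathrm{conf}}$ requires extrapolating the encoder ~8 standard
deviations beyond the training levels, which a batch-normalized
piecewise-linear network cannot be expected to do — measured directly,
even the best linear readout of the humidity level from
$z_{\mathrm{conf}}$ breaks on the shifted split while being accurate
in-distribution. The in-distribution probe is therefore the meaningful
check that humidity information was *isolated* rather than destroyed,
and the packaged study reports both numbers side by side.

## Numerical choices and degenerate inputs

* Convolutions use ceil-mode "same"-style padding at stride 2
  (170 → 85 → 43 → 22); the decoder mirrors with transposed convolutions
  and crops to the input length. Batch-norm precedes the leaky rectifier
  (slope 0.2); batch statistics are biased (moment) estimates with
  momentum-0.9 running averages for inference.
* Cross-entropy probabilities are clamped at $10^{-12}$, so a confident
  wrong prediction yields a large finite loss.
* All-masked inputs, zero baseline medians, empty classes, unknown
  variants, negative reversal scales and non-finite losses raise errors
  that name the offending component.
* Paired fold comparisons with zero-variance differences return p = 1
  (identical folds) or p = 0 (constant nonzero difference) explicitly
  rather than erroring inside the t-test.
* Optional adaptive loss weights (off by default) recompute
  $\lambda_i = \lVert \nabla L_i \rVert / \lVert \nabla L_{\mathrm{total}} \rVert$
  once per epoch from the last batch's encoder gradients, clipped to the
  tuning ranges; a zero total-gradient norm keeps the previous weights.

## Known limitations

* The adversary removes *one measured* confounder; multiple simultaneous
  confounders (temperature, aging drift) would need parallel adversaries
  and a larger confounder code.
* Invariance is enforced on the training distribution; it extends to
  shifted humidity only insofar as the confounding enters the inputs
  approximately affinely, as it does in the generator and approximately
  in real chemiresistors at moderate humidity excursions.
* The entire network stack is plain R; it is deliberately sized for
  hundreds of recordings at 170 x 32, not for datasets orders of
  magnitude larger.
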