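---
title: "Detecting damaged grapevine berries with a feature-perceptual VAE: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting damaged grapevine berries with a feature-perceptual VAE: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the one-class premise

Damaged or diseased grapevine berries (rot, sunburn, atrophy, malformation)
must be found before harvest, but labelled examples of damage are scarce and
heterogeneous while images of healthy berries are abundant. `berryvae`
therefore treats damage detection as one-class anomaly detection: a
variational autoencoder (VAE) is trained **only on image patches of healthy
berries**, and at inference time any region the model cannot reconstruct
well is flagged as anomalous. No damage labels enter training; labels are
used exclusively for evaluation.

The pipeline is patch-based. A berry segmentation mask (in the field, the
output of a segmentation network; for synthetic scenes, the generator's own
ground truth or the package's colour-threshold segmenter) defines regions of
interest. The image is tiled into non-overlapping 130×130 px windows
anchored at pixel (0,0); windows whose ROI coverage reaches a threshold
(default 0.1) are kept and resized to 64×64 by area averaging. 130 px was
chosen so a window holds roughly 6–10 berries.

## Model

The VAE encoder applies four 4×4 convolutions with stride 2 (each followed
by batch normalisation and LeakyReLU, negative slope 0.2), reducing a
64×64×3 patch to a 4×4 bottleneck map; two fully connected heads produce the
latent mean $\mu$ and log-variance $\log\sigma^2$. Sampling uses the
reparameterization trick $z = \mu + \sigma \odot \epsilon$,
$\epsilon \sim N(0, I)$, so the sampling step is differentiable. The decoder
expands $z$ through a fully connected layer to 4×4 and applies four stages
of nearest-neighbour ×2 upsampling + 3×3 stride-1 convolution with
replication padding (batch norm + LeakyReLU), and a final 3×3 convolution
squashed through a sigmoid so reconstructions live in $[0,1]$.

Two baseline autoencoders share the surrounding machinery: four 3×3
stride-1 padding-1 conv layers in encoder and decoder each (no spatial
downsampling), with compression by channel narrowing through a bottleneck
layer (default 8 channels). A stride-1/padding-1 stack literally cannot
halve resolution, so channel narrowing is the minimal faithful reading of
that baseline design; this is a deliberate interpretation, recorded here.
`ssim_ae` trains with $1 - \mathrm{SSIM}$, `fpl_ae` with the feature
perceptual loss.

## Losses

**Feature perceptual loss (FPL).** Both the patch $x$ and its
reconstruction $\hat x$ pass through the *same frozen* feature extractor
$\delta$; at each tapped layer $l$ with feature maps of size
$C^l \times W^l \times H^l$,

$$L_{rec}^{l} = \frac{1}{2\,C^l W^l H^l}
  \sum_{c,w,h}\bigl(\delta(x)^l_{c,h,w} - \delta(\hat x)^l_{c,h,w}\bigr)^2,
\qquad L_{rec} = \sum_l L_{rec}^l .$$

Only the encoder and decoder are updated during training; $\delta$ is fixed.

**KL term.** The divergence of the diagonal Gaussian posterior from the
standard-normal prior has the closed form
$\tfrac12\sum_i(\mu_i^2 + \sigma_i^2 - 1 - \log\sigma_i^2) \ge 0$.

**Total objective.** $L = \alpha L_{KL} + \lambda L_{rec}$.

**Choice of $\alpha$ (important).** With the per-layer normalisation above,
$L_{rec}$ is $O(10^{-2})$ while $L_{KL}$ summed over latent dimensions is
$O(1)$. Weighting both at 1 provably collapses the posterior: in our
measurements the KL term was ~98 % of the total loss, $\mu \to 0$,
$\sigma \to 1$, and the decoder degenerated to a near-constant blur — no
anomaly contrast can survive that. The package default is therefore
$\alpha = 1/\text{latent\_dim}$ (per-dimension KL weighting, resolved at
training time) with $\lambda = 1$. Both weights are exposed in
`train_config()` and logged in every run header.

**Feature extractor modes.** Production use taps a pre-trained 19-layer
VGG-style network (first three post-activation stages), loaded from a local
weights file. Because such weights cannot be shipped inside a source
package, the default mode is `deterministic_random`: a seeded random CNN
with the same conv–pool topology but reduced widths (16/32/64). Random
convolutional features preserve differences between images (they are a
structured random projection), are bit-reproducible from the seed, and keep
the entire test suite self-contained. In this mode the taps sit on the
*pre-activation* conv maps: with frozen random weights, post-ReLU taps
discard roughly half the gradient signal and measurably stall training,
while linear taps keep the loss well conditioned (for trained VGG weights
the conventional post-activation taps are kept). An `identity` mode
(features = raw pixels) serves as a stub in unit tests. Every extractor
carries a weights fingerprint that is logged with each run.

## Training

Healthy patches are split into training and validation sets (default 20 %
validation, stratified by growth stage, deterministic under the seed). The
trainer refuses any patch labelled anomalous — the one-class premise is a
hard contract. Optimisation uses Adam; early stopping monitors the
validation total loss (deterministic pass: eval-mode batch norm, zero
latent noise) with patience 10 and minimum improvement 1e-4, restoring
best-epoch weights. A NaN loss aborts with the epoch and batch in the
message.

Package defaults mirror the conventional full-scale setup: batch 64,
validation batch 16, initial learning rate 5e-4, `max_epochs` 200, encoder
widths 32/64/128/256, latent 100. **Desk-scale study conditions:** those
defaults presume thousands of optimiser updates (thousands of patches, many
epochs). The package's own end-to-end demonstration
(`synthetic_benchmark()`, also the basis of the acceptance script and the
heavy tests) trains ~720 patches from 100 healthy scenes for 20 epochs on
one CPU and therefore uses batch 8 and learning rate 2e-3 (more, larger
steps from the same sample budget) with reduced widths: encoder 8/16/32/64,
latent 64, decoder 32/16/8/8, extractor 16/32/64. Latent capacity matters
most: below ~64 dimensions the decoder cannot carry per-berry colour
variation, reconstructions lose specificity, and anomaly contrast collapses.
These are scaled-down stand-ins, not the full-scale configuration; both are
plain configuration settings.

## Scoring, thresholding, evaluation

A patch's anomaly score is the spatial mean of the channel-averaged
pixel-wise loss map ($\ell_1$, MSE, or BCE) between the patch and its
deterministic reconstruction (eval-mode batch norm; $\epsilon = 0$, i.e.
$z = \mu$). High reconstruction error ⇒ anomalous.

The decision threshold maximises accuracy over an exact candidate set: all
midpoints between consecutive sorted unique scores plus one cut below the
minimum and one above the maximum. This exhaustive search is $O(n \log n)$,
deterministic, and provably optimal over all thresholds; accuracy ties
break toward the smaller threshold. Stratified reporting (growth stages
`early`/`late`, standing in for the pea-size and pre-harvest regimes)
re-uses the single globally optimised threshold, so per-stratum confusion
counts add up exactly to the joint counts. Whether per-stage accuracies
should instead re-optimise the threshold per stage is genuinely open; the
shared-threshold convention is the more conservative choice and keeps the
stratified table additive.

Scores are means rather than sums over pixels; for a fixed patch size the
two are rank-equivalent, so the threshold search is unaffected.

## Heatmaps

For localisation, the per-pixel MSE map (squared error penalises anomalous
regions hardest) of each patch is upscaled back to its 130×130 source
window by nearest neighbour — which preserves loss values exactly on
constant regions — and placed at its origin. The grid is non-overlapping,
so no blending is required; uncovered pixels are zero with a `valid_mask`
of 0. Overlays colour-map the heat (dark blue = healthy, red = anomalous)
with per-image min-max normalisation by default; a fixed absolute scale is
available for cross-image comparability. An optional post-filter removes
connected heat blobs below a size threshold (off by default): isolated
few-pixel detections at berry/background borders are the method's known
false-positive mode, and reconstruction quality at ROI borders is
inherently poorer.

## The synthetic scene generator

Field imagery of the kind this method targets is not distributable with the
package, so a first-class generator produces labelled scenes: clustered
quasi-circular berries rendered as anti-aliased shaded ellipses with
per-berry radius/colour jitter and a specular highlight, on a textured
background, multiplied by a smooth random illumination field
(Gaussian-blurred noise, relative amplitude `illumination_sigma`, default
0.08). Berry spacing is calibrated so a fully covered 130×130 window holds
a berry count in the configured range (default 6–10). Two colour/size
regimes emulate growth stages: `early` (pea-sized, saturated green) and
`late` (pre-harvest, larger, yellow-green); their mean green-channel values
differ by well over 0.05, so a model must learn both regimes.

Anomalies are injected as: `discolor` — a connected sub-region of one berry
(20–80 % of its area) mixed 90 % toward rot-brown; `wither` — darkening
plus high-frequency texture on such a sub-region; `stem` — a 2–4 px wide
gently curved stroke hugging the berry region. The anomaly mask marks
exactly the altered pixels, and injection guarantees a nonzero pixel
difference on every masked pixel. Anomalous scenes damage ~35 % of their
berries by default: the regime of visibly damaged bunches, where several
berries in a patch are affected. Our first, subtler calibration (15 % of
berries at 75 % mixing) produced anomalies covering ~2 % of a patch — an
effect far below what field images of damaged bunches show — and was
revised once to the current value; detection difficulty scales directly
with this knob, and it is an explicit config field.

One integer seed drives a hierarchical RNG: every scene derives its own
substream from (collection seed, scene index), so per-scene reproducibility
is independent of generation order. Identical (spec, seed) reproduce a
scene bit-for-bit.

**What the generator does not emulate:** real bunch geometry and occlusion,
leaves and canopy background, specular sensor effects, red (post-veraison)
varieties, and the full visual diversity of field damage. Passing tests on
synthetic scenes demonstrates that the pipeline's machinery — one-class
training, score separation, threshold optimisation, localisation — works
end to end; it does not certify field performance.

## Numerical choices and degenerate inputs

- Area-average resampling for 130→64 (exact box filter; mean-preserving;
  constants stay constant). Nearest neighbour for heatmap upscaling.
- Grid anchoring at (0,0) with residual right/bottom margins discarded;
  coordinates 0-based, row-major, half-open windows.
- BCE inputs clamped to $[10^{-7}, 1 - 10^{-7}]$; all losses finite on
  finite inputs.
- SSIM uses a Gaussian window (11 px, $\sigma = 1.5$) with edge-renormalised
  weights, so constant images score exactly 1; its analytic gradient is
  verified against finite differences in the test suite, as are the full
  backward passes of all three training objectives.
- Patch labelling needs ≥ 30 anomalous source-scale pixels (~0.18 % of a
  window) — robust to single-pixel mask noise.
- Accuracy ties in threshold search break toward the smaller threshold;
  maxpool ties take the first element (both deterministic).
- Batch norm uses batch statistics during training (momentum 0.1 running
  updates) and running statistics for every scoring pass; a trailing batch
  of size 1 is processed in eval mode.

## Known limitations

- The FPL's production extractor (pre-trained VGG19) requires a locally
  supplied weights file; the shipped modes are the seeded random CNN and the
  identity stub.
- Desk-scale training budgets leave the VAE under-converged relative to a
  full-scale run; reported accuracies on synthetic data are a scaled-down
  demonstration, not an estimate of field accuracy.
- Border windows mixing berries and background inflate reconstruction error
  and can produce false positives — visible in heatmaps as elevated values
  at ROI borders.
- Single-threaded determinism is guaranteed; multi-threaded BLAS may
  reorder floating-point reductions.
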