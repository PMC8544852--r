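---
title: "Methods: synthetic benchmarking of stomata classification and detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic benchmarking of stomata classification and detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

Stomata are the gas-exchange pores of the plant epidermis; in grasses such
as maize they are dumbbell-shaped (two guard cells joined at a narrow pore)
and arranged in longitudinal files along the leaf. Counting them in
microscope images of epidermal impressions is the bottleneck of many
phenotyping studies. `stomadetect` implements a two-task pipeline:

1. **Classification.** Fixed-size subimages (151 × 258 px windows) labeled
   *stoma* / *non-stoma* are encoded by an image descriptor and classified.
   Descriptor × classifier tuples are compared by mean accuracy under
   image-level 5-fold cross-validation, and the best tuple is kept.
2. **Detection.** A sliding window (stride 100 px in both axes, full
   windows only) walks each full image; every window is classified by the
   best tuple; positive windows increment a per-pixel *occurrence matrix*;
   pixels with positive occurrence are merged into 8-connected components,
   each component counting as one detected stoma region. Region counts are
   scored against manual (ground-truth) counts as a detection rate.

The window geometry, stride, fold protocol, per-class window counts and
the evaluation arithmetic follow the published experimental design this
package re-implements; everything that design leaves unstated (descriptor
parameters, classifier hyperparameters, coordinate conventions, matching
criteria) is declared explicitly here and recorded in the objects the
package produces.

## Conventions

* Pixels are stored on the 8-bit scale (0–255); descriptors normalise
  internally. RGB is collapsed with BT.601 luminance weights
  (0.299, 0.587, 0.114).
* All boxes and window origins are 0-based, row-major and half-open, so a
  window at origin `(r, c)` covers rows `[r, r+151)` and columns
  `[c, c+258)`. One convention everywhere removes every off-by-one
  ambiguity in the occurrence arithmetic.
* The sliding grid contains full windows only: origins
  `(i·s, j·s)` with `i·s + h ≤ H`, `j·s + w ≤ W`. Partial or padded border
  windows are never generated, matching the published per-image window
  counts' order of magnitude.

## The synthetic scene generator

No annotated maize dataset is distributed with the original study, so the
package ships a generator (`scene_spec()` / `generate_scene()`) that
emulates the relevant image structure with exact ground truth:

* **Stomata** are rendered as dark dumbbells — two anisotropic Gaussian
  lobes at the poles plus a narrow central slit — with per-stoma length,
  width and orientation jitter (defaults 90 ± 8 px long, 42 ± 5 px wide,
  ±6° orientation SD). The dumbbell shape matters: it gives shape
  descriptors (HOG, DAISY) a signature that plain blobs would not.
* **Layout**: stomata sit in horizontal files (vertical spacing 150 px
  with jitter), the grass-like arrangement visible in real epidermis
  images. Every stoma keeps at least half a window's margin from the image
  border so centred training windows always fit.
* **Background**: a light epidermis (level 200) with sinusoidal file
  shading, faint transverse cell walls and a slow illumination gradient
  (amplitude 10), plus additive Gaussian pixel noise.
* **Artifacts** reproduce the five recurring noise types of impression
  micrographs: air bubbles (bright rings), leaf residuals (irregular dark
  blobs), grooves (elongated dark bands), degraded stomata (attenuation of
  a random subset of renderings), and low image quality (Gaussian blur +
  intensity quantisation). Artifacts never alter the ground truth.
* **Determinism**: a scene is a pure function of its spec, including the
  seed; reruns are bit-identical.

Scenes default to 1200 × 1600 px (instead of the full ~2750 × 3840 px of
real captures) to keep benchmarks at desk scale; the full size is one
`image_shape` argument away. Default stomatal density (12 per scene) is
chosen for test coverage, not biological fidelity — real densities vary by
cultivar and ploidy.

What passing on these scenes shows — and what it does not: the synthetic
benchmark proves the pipeline's plumbing, separability behaviour and
geometry end to end, but the generator's texture is far simpler than real
epidermis; accuracy numbers on it say nothing quantitative about accuracy
on real micrographs.

## Descriptors

All five handcrafted descriptors are pure functions of the grayscale
window with fixed output length; the original study names them without
parameters, so the defaults below are standard-literature values, recorded
in every `descriptor_spec` and serialised with every model.

* **HOG** — window resized to 144 × 256 (so the 16 × 16 cells tile
  exactly), unsigned gradient orientations in 9 bins per cell, 2 × 2-cell
  blocks at stride one cell, per-block L2 normalisation with an epsilon
  guard: 8 · 15 · 4 · 9 = 4320 values. A constant window maps to the zero
  vector by the epsilon guard.
* **DAISY** — 8 half-wave-rectified directional derivative maps, Gaussian
  pyramids (σ = 4, 8, 12, 16 px), grid step 32 px, radius 24 px, 3 rings ×
  8 samples: 200 values per grid point, 28 points, 5600 total.
* **LBP** — uniform patterns, 8 neighbours at radius 1 with bilinear
  interpolation, neighbour ≥ centre sets the bit (the common convention),
  59-bin histogram normalised to sum 1.
* **Haralick** — GLCMs at distance 1 and angles {0°, 45°, 90°, 135°},
  64 grey levels (256² co-occurrence cells would be sample-starved on a
  39k-pixel window), symmetrised and normalised; the 13 classic statistics
  averaged over angles. Natural logarithms with 0·log 0 = 0; correlation
  and the first information measure are defined as 0 when their
  denominators vanish (constant windows).
* **GIST** — 128 × 128 working size, log-intensity whitening and divisive
  contrast normalisation (epsilon-guarded), a frequency-domain Gabor bank
  of 4 scales (centre frequencies 0.25/2^(s−1) cycles/px) × 8 orientations,
  response magnitudes averaged over a 4 × 4 grid: 512 values.

Deep features (the six ImageNet-pretrained backbones of the original
study) are an optional capability: the package declares each backbone's
input shape, feature tap (global average pool; fc2 with 4096 units for
VGG16) and output width, but delegates the forward pass to a
user-registered provider (`register_backbone_provider()`), raising a
distinct capability error when none is present. The pipeline is fully
functional descriptor-only. The published "epochs" row for these backbones
is not reproduced: with frozen feature extractors there is nothing
well-defined to train, so any training here is confined to the downstream
classifier.

## Classifiers

* **Linear SVM** (`e1071`), cost 1, on features standardised to zero mean
  and unit variance with training-fold statistics only.
* **MLP** — a PCA compression fitted on the training fold (components
  covering 95% of variance, capped at 64) followed by a single-hidden-layer
  network (`nnet`, 16 units, up to 200 iterations, weight decay 1e-4).
  The compression step is part of the model because dense quasi-Newton
  training of a wide hidden layer directly on 4000–6000-dimensional
  descriptors is not numerically practical; the PCA + small-net
  combination is the standard R idiom for that regime.
* **AdaBoost.M1** with exact weighted decision stumps (globally optimal
  threshold over all features and both polarities per round, 100 rounds),
  implemented in the package with a small C++ kernel for the stump search.

All fits are deterministic given the classifier seed, which is stored in
the spec and in every fitted model.

## Cross-validation and leakage

Folds partition *images*, never regions: every region inherits the fold
of its parent image, fold sizes differ by at most one, and an assertion
inside the CV loop re-checks that no region of a test image ever enters
its training fold. This is the only leakage-safe reading of a protocol
that cross-validates a dataset of whole microscope images.

Best-tuple selection takes the argmax of the full-precision accuracy grid;
ties are broken by classifier preference (SVM, then MLP, then AdaBoost —
matching the adoption choice of the original study when SVM and MLP tie),
then by descriptor column mean. Tables display one decimal; comparisons
never use the rounded values.

## Detection design choices

* **Occurrence threshold 1**: any positive window marks its pixels. The
  published method says only "positive occurrence"; the threshold is
  exposed for experimentation.
* **8-connectivity** for region merging (configurable). Since the stride
  (100) is smaller than the window in both axes, overlapping positives
  always touch; 8-connectivity is the permissive default.
* **One region = one counted stoma.** Adjacent stomata whose positive
  windows overlap merge into one region; the package does not split
  merged regions. This is a documented limitation — at realistic spacing
  relative to the 151 × 258 window, neighbouring detections frequently
  merge, so the *matched-truth* count (below), not the raw region count,
  is the meaningful recovery statistic.
* **Matching criterion**: a ground-truth stoma counts as detected iff its
  centre pixel lies inside a detected region (`center_in_region`), which
  is robust to merged regions; an IoU mode is available. The criterion is
  recorded in every report. Window-level true positives use any
  positive-area overlap with a truth box, reproducing the published
  accounting in which window true positives far exceed region counts.
* The published window-level false-positive *percentages* use an
  undocumented denominator that cannot be reconciled with the printed
  counts; the package reports the raw TP/FP counts and leaves ratios to
  the reader.
* **Training-window jitter.** Sliding windows see stomata at arbitrary
  offsets, while hand-labeled training windows are centred. The detection
  benchmark therefore samples its training stoma windows with a uniform
  offset jitter of half the stride per axis (the stoma box always stays
  inside the window). Without this, position-sensitive descriptors (HOG,
  DAISY) under-recall sharply at detection time; with it, all descriptors
  behave comparably. Classification benchmarks keep exactly centred
  windows.

## Benchmark conditions and problem sizes

The package's reference benchmarks (used by its acceptance script and
heavyweight tests) run on the generator's *high-contrast* condition:
contrast 0.85, noise SD 4, no artifacts — the separable regime in which
descriptor-based tuples should approach perfect accuracy.

* Classification: 50 scenes × (5 stoma + 5 non-stoma) windows = 500
  regions, the full 5 descriptor × 3 classifier grid under image-level
  5-fold CV, plus a permuted-label control that must sit inside the 99%
  binomial interval around 50%.
* Detection: the grid's best tuple trained on 40 scenes (10 stomata
  each), evaluated on 10 held-out scenes; the recovery target is ≥ 90% of
  truth stomata matched with at most one false-positive region per image.

These sizes were chosen as the smallest at which fold accuracies stabilise
to within a percent across seeds; scenes scale linearly if more power is
wanted.

## Known limitations

* The generator does not attempt photorealistic epidermis texture,
  impression optics, or quantitative ploidy effects.
* Merged adjacent detections are not split (no non-maximum suppression,
  single-scale windows) — by design, matching the re-implemented method.
* Deep-feature extraction requires an external CNN runtime; the package
  ships only the contracts and treats the capability as optional.
* Published headline accuracies were computed on 200 real, undeposited
  maize images; nothing here claims to reproduce those numbers on real
  data. The package reproduces the method, its arithmetic, and its
  behaviour under controlled synthetic conditions.
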