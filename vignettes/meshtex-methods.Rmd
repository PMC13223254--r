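---
title: "Adaptive multiscale local mesh ternary patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive multiscale local mesh ternary patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshtex)
```

## The problem

Oral-lesion photographs carry diagnostic information mostly in their
*texture*: benign, malignant and healthy tissue differ in the
micro-structure of the mucosal surface more than in any single intensity
statistic. meshtex implements a handcrafted texture pipeline for such
images: enhancement, a local mesh ternary descriptor with an adaptive
dead zone, classical classifiers tuned by a population metaheuristic,
and a stratified evaluation protocol. Everything runs offline on seeded
synthetic textures, so the pipeline's behaviour is fully testable
without clinical data.

## Preprocessing chain

Three stages run in fixed order, each in floating point with rounding
and clamping to `[0, 255]` at the stage boundary:

1. **CLAHE** (contrast-limited adaptive histogram equalization). The
   image is split into a grid of tiles (default `8x8`); each tile's
   256-bin histogram is clipped at `clip_limit` (default 2.0) times the
   mean bin height, the excess is redistributed uniformly, and the
   clipped CDF becomes the tile's intensity mapping. Pixels are remapped
   by bilinear interpolation between the four nearest tile mappings.
   The published formulation of this stage can also be read as a local
   min–max stretch; because the two readings genuinely differ we kept
   both: `clahe_mode = "clahe"` (the default, matching the named method
   and its clip-limit parameter) and `clahe_mode = "minmax"` (the
   literal per-tile stretch). All defaults reproduce the published
   operating point, and the min–max mode has its own unit test against
   the closed-form stretch.
2. **Gamma correction**, `round(255 * (v/255)^gamma)` with
   `gamma = 0.4`. Exponents below one brighten; 0 and 255 are fixed
   points and the map is monotone, which the tests verify over all 256
   inputs.
3. **Laplacian sharpening**, `out = in - strength * lap(in)` with the
   4-neighbour second-derivative kernel `[[0,1,0],[1,-4,1],[0,1,0]]`,
   replicated borders, and `strength = 1.0`. "Order 2" is read as this
   standard second-derivative operator; flat regions pass through
   unchanged.

The chain is deterministic; idempotence is *not* claimed (CLAHE of a
CLAHE'd image differs), and the tests assert byte-exact reproducibility
instead.

## The AM-LMTP descriptor

For every pixel with full window support, the descriptor:

1. samples `P = 8` neighbors on a circle of radius `R` (1 for the 3x3
   window, 3 for the 7x7 window), neighbor `i` at angle
   `2*pi*(i-1)/8` counter-clockwise from the positive x-axis, with
   bilinear interpolation off the grid. Circular sampling at `R = 3`
   (rather than the 24 border pixels of a 7x7 square) keeps `P = 8`
   at both scales, hence 8-bit codes and comparable 256-bin histograms;
2. forms the **mesh** differences `d_i = g[beta(i,a)] - g[i]`, where
   `beta = 1 + mod(i + P + a - 1, P)` pairs each neighbor with the one
   `a` steps around the circle. Orders `a = 1, 2, 3` are used;
3. computes a per-pixel adaptive threshold
   `T = alpha * sigma + beta_offset` (defaults `alpha = 0.2`,
   `beta_offset = 5`), where `sigma` is the *population* standard
   deviation of the window at the pixel — the window of the scale being
   computed (3x3 SD for the 3x3 scale, 7x7 SD for the 7x7 scale), so
   each scale judges "significant change" against its own context.
   `alpha` scales the dead zone with local contrast; `beta_offset`
   floors it so flat regions do not code noise. A neighborhood with
   `sigma = 20` therefore gets `T = 0.2*20 + 5 = 9`;
4. ternary-encodes each difference: `+1` if `d_i >= T`, `-1` if
   `d_i <= -T`, else `0`, with *inclusive* boundaries (a difference of
   exactly `T` is significant — the choice is arbitrary but fixed and
   tested);
5. packs the `+1` bits into an "upper" code and the `-1` bits into a
   "lower" code with binomial weights `2^(i-1)`. The weights are the
   standard binary-pattern weights: intensity-valued weights would not
   produce codes in `[0, 255]` and would make a 256-bin histogram
   meaningless, so the descriptor uses `2^(i-1)` throughout.

Three orders x two polarities give **six pattern images per scale**.
Their per-pixel average (rounded) is available via
`lmtp_visualization()` for figures, but features always use the six
separate histograms: the average destroys exactly the information the
six-way split creates.

Two formulations coexist in the literature for *what* gets thresholded:
the centre-relative differences (the worked `centre +/- T` bounds, e.g.
72 ± 9 → 81/63) and the mesh-pair differences. The mesh pairing is what
distinguishes this descriptor family from plain ternary patterns, so
meshtex thresholds the mesh differences; the centre bounds remain
exposed verbatim through `center_bounds()` for inspection, but are not
on the feature path. A 50-image brute-force oracle test pins the chosen
semantics exactly.

**Borders.** Features are computed only on the region with full support
at the largest radius (inset 3 on all sides), shared by both scales; no
padding is invented inside the descriptor. Images smaller than 7x7 are
rejected.

**Histograms.** Each pattern image is histogrammed into 256 bins over
the valid region and L1-normalized (frequencies), so images of
different sizes are comparable; raw counts are available with
`normalize = FALSE`. The layout is fixed: for each `(order, polarity)`
in `(1,up),(1,low),(2,up),(2,low),(3,up),(3,low)`, the 3x3-scale
histogram then the 7x7-scale histogram — `6 x 512 = 3072` values.

Useful invariants, all under test: additive intensity shifts that do
not clip leave the features unchanged (both `sigma` and all differences
are shift-invariant); the upper and lower codes are bitwise exclusive;
and raising `alpha` or `beta_offset` can only shrink the count of
nonzero ternary codes.

## Grey Wolf Optimization

Hyperparameters are tuned by GWO, maximizing mean validation accuracy.
The pack's three best wolves (alpha, beta, delta) steer the rest: with
exploration coefficient `a` decaying linearly from 2 to 0 over the run,
each wolf moves to the average of three leader-directed candidates
`leader - (2*a*r1 - a) * |2*r2*leader - pos|`, clipped to bounds. The
bare single-leader update (toward alpha only) is kept as
`alpha_only = TRUE` for fidelity experiments; the three-leader form is
the default because the hierarchy of three named leaders is the point
of the method. Mixed spaces are handled by encoding: continuous
coordinates pass through, integers round and clamp, categoricals round
to an index. Ties in leader selection break by lowest wolf index, so
runs are reproducible under a seed.

Pack size (10) and iteration count (20) are desk-scale defaults — the
method's source material leaves them open — and the budget is always
`n_wolves * (n_iters + 1)` fitness evaluations, which the tests assert.
A `random_search()` baseline with the identical budget is provided; on
the 3-D sphere objective GWO must match or beat its median and locate
the optimum to `1e-2` in at least 18 of 20 seeds.

## Classifiers and the evaluation protocol

The five classifiers (random forest, gradient boosting, k-NN, a
single-hidden-layer network, and an SVC) are textbook models, so they
are thin adapters over established implementations (ranger, xgboost,
e1071, nnet); the in-package k-NN vote exists only because the tuned
search space includes the manhattan metric, which the standard k-NN
routine does not expose. The network adapter tunes hidden-layer size,
weight decay and training epochs: it is a batch-trained (BFGS)
single-hidden-layer network, so per-batch learning-rate and batch-size
knobs of an SGD trainer have no direct counterpart; depth beyond one
hidden layer is likewise out of scope for the adapter.

The protocol: an 80:20 **stratified** train/test split; train-only
augmentation (two label-preserving variants per original by default —
horizontal flip and +15° rotation with reflect padding; the published
protocol fixes only the count, two, so the transforms are chosen as
standard texture-preserving ones); stratified 5-fold tuning on the
training split with mean validation accuracy as the GWO fitness; refit
on the full training split; metrics on the untouched test split.
Augmented variants inherit their parent's fold and validation scores
originals only, so no variant of a validation image can leak into
training — a property test enumerates the fold intersections. The
classifier's default hyperparameters are seeded into the initial pack,
which guarantees tuned-vs-default is a true inequality rather than a
hope. `k = 5` folds is our choice; the protocol's source states
stratified k-fold without fixing k.

Metrics come from the per-class confusion counts: precision
`TP/(TP+FP)`, recall `TP/(TP+FN)` (both 0 with a warning on an empty
denominator), accuracy as a percentage, and one-vs-rest ROC staircases
swept over all score thresholds (the multi-class scheme is
one-vs-rest; per-class curves without a stated scheme admit nothing
else natural). The ROC area is cross-checked against an independent
implementation in the tests.

## The synthetic generator

`generate_texture_fixture()` emulates three texture regimes: `smooth`
(low-pass Gaussian blotches), `speckle` (35% impulsive salt-and-pepper
plus mild noise) and `grating` (an oriented sinusoid, period 6 pixels,
plus noise). They are deterministic in `(class, size, seed)` and
separable by construction — a 20-seed sweep asserts that speckle's mean
local SD strictly exceeds smooth's. What they do **not** emulate:
illumination gradients, color, lesion-scale shapes, specular
highlights, camera noise correlations. Passing the end-to-end test
therefore shows the pipeline's plumbing and the descriptor's
discriminative mechanics are sound, *not* that clinical accuracy
transfers; the published real-data accuracies require the clinical
datasets and are outside this package's tests.

Problem sizes in the test suite are deliberately desk-scale, as the
package's own choice: 30 images per class at 32x32 for the end-to-end
run (with a 6-wolf, 8-iteration tuning budget), 12x12–20x20 images for
the 50-image oracle-equivalence sweep, and 20-seed sweeps for the
stochastic optimizer properties.

## Numerical choices and degenerate inputs

- All image arithmetic in doubles; rounding + clamping to `[0, 255]`
  only at stage boundaries. Feature vectors are deterministic to
  `1e-12` across runs.
- Population (divide-by-n) SD; a `max(v, 0)` guard absorbs negative
  round-off before the square root.
- Flat tiles in min–max CLAHE mode map to identity (the stretch is
  undefined there); flat tiles in true CLAHE mode equalize like any
  other histogram, which leaves constant images spatially uniform.
- `precision`/`recall` on 0/0 return 0 with a warning rather than NaN.
- The mesh index symbol clash (the pairing index vs. the threshold
  offset, both conventionally written beta) is resolved in the API as
  `beta_index` (internal) vs. `beta_offset`.

## Limitations

- Pure-R descriptor: fine for test-scale images, slower than a compiled
  implementation on megapixel photographs.
- No rotation-invariant or uniform-pattern code mappings; no scales
  beyond those configured.
- The k-NN adapter is O(n^2) in distance evaluations.
- Peripheral image content is unseen by construction (inset-3 border),
  which matters for images whose discriminative texture hugs the edge.
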