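---
title: "Imbalance-aware semantic segmentation: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imbalance-aware semantic segmentation: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scalpelseg)
```

## The problem

Laparoscopic cholecystectomy scenes contain a handful of large, ubiquitous
structures (background, abdominal wall, liver, fat — together roughly 85% of
all pixels) and a set of small, rare but clinically critical ones: blood,
the cystic duct, the hepatic vein and the liver ligament each account for
less than 1% of pixels and appear in only 3–9% of frames. A per-pixel
classifier trained with a plain cross-entropy objective can reach high
global accuracy while never predicting a single pixel of those minority
structures. This package implements the two algorithm-level remedies —
per-class loss weighting and imbalance-aware loss functions — together with
the full training and evaluation machinery needed to study them: a
depth-configurable encoder–decoder network, SGDM/Adam training with a
piecewise learning-rate schedule, a per-class metric suite including the
boundary F1 score, and a synthetic scene generator that reproduces the
statistical structure of the real data so every claim can be exercised
end-to-end on a desk.

## Losses

All losses operate on per-pixel softmax probability maps $p \in
\Delta^{C-1}$ with $p_t$ the probability assigned to a pixel's true class.

* **Cross-entropy (CE)**: mean of $w_y \, (-\log p_t)$, normalized by the
  sum of the applied class weights $w_y$, so uniform weights reduce exactly
  to the unweighted mean. $p_t$ is clamped at $10^{-12}$ so the loss is
  finite even for a degenerate probability map; the clamp is far below any
  probability the softmax can produce in double precision during training.
* **Focal loss (FL)**: $\alpha_t (1-p_t)^\gamma (-\log p_t)$. The modulating
  factor suppresses easy (confident, correct) pixels; $\gamma = 0,
  \alpha_t = 1$ recovers CE exactly. $\alpha_t$ is applied as a scalar on
  the true-class term, the standard multiclass generalization of the
  binary formulation; a per-class $\alpha$ vector is accepted too.
* **Tversky loss (TL)**: $\sum_{c=1}^{C} (1 - TI_c)$ with
  $TI_c = \frac{\sum_m J_{cm} G_{cm} + \varepsilon}{\sum_m J_{cm} G_{cm} +
  \sigma \sum_m J_{cm} G_{\bar c m} + \beta \sum_m J_{\bar c m} G_{cm} +
  \varepsilon}$. $J$ is the *soft* predicted probability channel rather
  than the hard argmax, which keeps the loss differentiable; the metric
  suite uses hard counts. $\sigma$ weighs false positives, $\beta$ false
  negatives; the defaults $\sigma = 0.3 < \beta = 0.7$ penalize missed
  minority pixels harder than spurious ones. $\sigma = \beta = 0.5$ is the
  Dice loss (DiL).
* **Combined losses**: $\mathrm{CEDL} = \delta\,\mathrm{CE} +
  (1-\delta)\,\mathrm{DiL}$ and $\mathrm{CETL} = \delta\,\mathrm{CE} +
  (1-\delta)\,\mathrm{TL}$, default $\delta = 0.7$ (cross-entropy
  dominant). Class weights enter the CE term only by default
  (`weight_tversky = TRUE` extends them to the per-class Tversky terms; the
  Tversky index is already per-class-normalized, so weighting it is a
  second-order effect).

Two aggregation conventions exist for the Tversky sums over a mini-batch:
summing the pixel sums across the whole batch (default, one smooth term per
class, gradient-stable when a class appears in few images of the batch), or
computing the loss per image and averaging (`per_image = TRUE`). The
smoothing constant defaults to $\varepsilon = 10^{-6}$.

Every loss returns an analytic gradient with respect to the logits through
the softmax chain rule; the test suite verifies all six against central
finite differences at $10^{-4}$ relative tolerance.

## Class weighting

`compute_weights()` implements median-frequency balancing ($w_c =
\mathrm{median}(f)/f_c$, default), inverse-frequency ($w_c = 1/(C f_c)$,
which exactly equalizes $w_c f_c$) and uniform weights. Median-frequency is
the default because its rebalancing behavior — dominant shares pushed
down, minority shares pulled up, the median class untouched — matches the
rebalancing pattern this family of segmentation studies reports, and it is
the standard choice in the encoder–decoder literature. Weights are
computed on the **training partition only**; computing them on the full
dataset would leak test-set statistics into training. A class with zero
observed pixels makes the weights undefined; the function refuses with an
explicit message rather than silently smoothing (the experiment harness
opts into half-minimum-share smoothing, stated in its documentation).

## Network

`build_unet()` constructs the classical U-Net geometry: `depth` encoder
stages of two 3×3 convolution + batch-norm + activation blocks followed by
2×2 max pooling, channels doubling from `base_channels`; a bottleneck
double-conv; a mirrored decoder using 2×2 transposed convolutions with the
encoder tensors concatenated back at every stage; and a 1×1 convolution to
per-class logits. Block internals not fixed by the architecture family
(batch normalization after each convolution, max pooling, transposed-conv
upsampling) follow the canonical choices. The activation (ReLU, GELU, or
Swish in its SiLU form $x\,\sigma(x)$) is applied everywhere except the
logit layer and is orthogonal to all tensor shapes. The reference scale is
depth 5 at 224×224 with `base_channels = 64`; the desk scale used in tests
and examples is depth 3 at 96×96 with `base_channels = 8` (~120k
parameters).

The forward/backward passes are implemented as im2col patch matrices times
BLAS matrix products, with the C-level patch extraction writing into
per-layer reusable buffers (the patch matrices are the dominant allocations
of a training step; reusing them keeps the garbage collector out of the hot
loop). Gradients of every layer are verified against finite differences in
the test suite.

## Training

`train_config()` carries the published regime: 30 epochs, mini-batch 8,
weight decay $5\times 10^{-3}$ as coupled L2 (added to the gradient, the
convention of the study software family; decoupled decay is a flag),
momentum 0.9, Adam $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$. The initial learning rate is $10^{-3}$ (SGDM) or
$10^{-4}$ (Adam) and drops by a constant factor every 10 epochs. The drop
factor 0.3 is derived: it is the unique constant multiplier consistent with
the published initial and final rates ($10^{-3} \to 9\times10^{-5}$ and
$10^{-4} \to 9\times10^{-6}$) over the two drops of a 30-epoch run.
Validation runs once per epoch; final-epoch weights are returned (best-epoch
checkpointing would require a model-selection rule the training regime does
not specify). Training is deterministic given the seed under
single-threaded numerics.

## Metrics

The metric suite works from hard masks. Per class: one-vs-rest accuracy
(with true negatives), class accuracy (= recall), IoU, Dice, precision,
recall and the boundary F1 score. Two accuracy columns are kept
deliberately: the one-vs-rest form is inflated by the abundant true
negatives of rare classes, and published per-class accuracy tables in this
area are only consistent with the recall-style definition — so `MAcc`
aggregates `class_acc` while `acc_ovr` is reported alongside. A class
absent from both truth and prediction is *undefined* and excluded from all
means, never scored 0 or 1.

Boundary pixels are class pixels with a 4-neighbor of a different label
(image-edge pixels count as boundary); boundary precision/recall match
boundary pixels across masks within a Euclidean tolerance θ, default 0.75%
of the image diagonal — the documented default of the standard boundary-F1
implementations. Per-image, per-class scores are averaged over the images
where the class appears in either mask, then over classes for `Mbfs`.

## The synthetic scene generator

`cholecseg_profile()` encodes the 13-class structure this method targets:
pixel-share targets 0.27/0.22/0.21/0.15 for the four dominant classes, four
minority classes below 1%, and per-class image-presence probabilities
matching the published per-image frequencies (liver 1.00, cystic duct
0.0307, ...). Shape families are stylized — overlapping ellipses for organs
and tissue, dilated quadratic Bézier curves of width 1–8 px for tubular
minority structures, edge-entering tapered capsules for the two
instruments, scattered discs for blood — painted back-to-front so
instruments occlude tissue, as in laparoscopy. When a class is present its
target area is its pixel-share target divided by its presence probability
and by the expected cover of later-painted classes (first-order occlusion
correction), and the rasterizer tops up shapes that fall short of their
area after edge clipping. Images are per-class base colors plus a smooth
illumination gradient, Gaussian texture noise (sd 0.05 on the unit
intensity scale) and a 1 px Gaussian blur — enough texture that the task is
not color-lookup-trivial, chosen once as plausible desk-scale values.

What the generator does *not* emulate: anatomical shape realism, specular
highlights, motion blur, smoke, instrument reflections, or the correlation
between presence and size of real structures (presence and pixel share are
configured independently — the real joint distribution is not published).
Passing tests therefore demonstrate that the pipeline behaves correctly
under the *statistical* imbalance structure of the real data, not that any
particular accuracy transfers to real surgical video.

Determinism: each sample is generated under a counter-based sub-seed mixed
from `(seed, index)`, so datasets regenerate bit-identically and samples
are order-insensitive.

## The desk-scale experiment

`compare_imbalance_handling()` is the package's core empirical claim in
miniature: on the 13-class imbalanced preset (96×96, depth-3 network,
`base_channels` 8, 60 images split 60/20/20, 15 epochs, Adam at
$10^{-3}$ — the standard Adam default for a network this size), the
imbalance-aware configuration (median-frequency-weighted CETL with
$\delta = 0.7, \sigma = 0.3, \beta = 0.7$, Swish) achieves a higher
median minority-class mean IoU across seeds than an unweighted CE + ReLU
baseline. Two sizing choices deserve explanation:

* **Dataset size.** 60 images is the desk-scale band's lower-middle; with
  8080 real frames unavailable, training exposure to a 3%-presence class is
  necessarily one or two images. That *is* the severe-imbalance condition,
  made harsher by the small sample.
* **Held-out evaluation widening.** A 12-image test split contains, in
  expectation, well under one appearance of each minority class, making the
  minority IoU frequently undefined for both arms. The harness therefore
  appends 60 additional held-out samples (indices disjoint from every
  training/validation index, same distribution) to the evaluation set.
  This changes only the precision of the estimate, not the training
  conditions.

The aggregate quantities this produces are computed fresh by
`scripts/acceptance.R` and by the acceptance block of the test suite;
nothing in the documentation states numbers those runs do not compute.

## Numerical and degenerate-input choices

* Softmax is max-stabilized per pixel; adding a channel-constant leaves
  probabilities unchanged to machine precision.
* Argmax ties in `predict_mask()` break toward the lowest class id,
  making predictions deterministic.
* Labels are never interpolated: mask resizing is nearest-neighbor
  (bicubic interpolation of class ids would manufacture invalid classes),
  while images use Keys-kernel bicubic with kernel widening on downsizing
  and border replication.
* Color-mask lookup is exact byte equality — label masks are annotation
  artifacts, not photographs, so a tolerance would only mask corruption.
* `split_manifest()` shuffles a canonically path-sorted record list with a
  seeded generator and cuts by `floor(f N)` with the remainder to train,
  so an 8080-record manifest splits 4848/1616/1616 and the assignment is
  independent of filesystem enumeration order.

## Known limitations

* The reference-scale network (depth 5, 224×224, `base_channels` 64) is
  constructible and correct but not practical to train in R on one CPU;
  all empirical statements in this package are desk-scale.
* Pretrained-backbone architectures are out of contract; the
  `SegmentationModel` surface (`predict_probs()`/`predict_mask()`) is the
  extension point for third parties.
* Determinism is promised only under single-threaded numerics; a
  multi-threaded BLAS may reorder reductions.
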