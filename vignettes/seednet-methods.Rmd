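---
title: "Model family, counting conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model family, counting conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model family

Maize seed lots are sold by variety, and lot purity is assessed by
classifying individual seeds. `seednet` implements a family of 50-layer
bottleneck residual networks for single-seed RGB classification, organised
around three independent modifications of the classic architecture:

1. **Stage reorganisation (ResStage).** Each of the two early stages
   (bottleneck widths 64 and 128) is rebuilt as a *Start / Middle / End*
   sequence. The Start block's residual branch ends in a normalisation and the
   addition is left bare; Middle blocks are fully pre-activated (norm +
   activation at branch entry, branch ending in a convolution, so a zero
   branch is an exact identity); the End block's addition is followed by norm
   + activation. The point of the reorganisation is the trunk: a classic stage
   places one activation on the residual trunk per block (so the count grows
   with depth), while a reorganised stage carries exactly **one** trunk
   activation regardless of depth — four on the main propagation path of a
   four-stage network. `trunk_activation_count()` verifies this by walking the
   graph.

2. **Improved residual blocks.** In the two later stages (widths 256 and
   512) each block gains *efficient channel attention* after its first
   convolution — global average pooling, a width-`k` 1-D cross-channel
   convolution with `k = |log2(C)/2 + 1/2|_odd`, and a sigmoid gate — and its
   3×3 convolution is replaced by a *depthwise-separable* pair (9·C + C²
   parameters instead of 9·C²), with the stride taken in the depthwise
   sub-convolution.

3. **Mixed activation placement.** Swish (`x·sigmoid(x)`) at the stem
   activation and after the additions of End and improved blocks — the trunk
   transitions — and PReLU everywhere else. PReLU uses one shared learnable
   slope per activation site (initial value 0.25): per-channel slopes would
   add tens of thousands of parameters and visibly change the reported model
   size, whereas the design intent is that activation swaps are
   size-neutral.

A note on the PReLU definition: the source literature for this architecture
prints the parametric rectifier as `0 for x <= 0, alpha*x for x > 0`, which
contradicts its own description, figure and the original reference. The
standard definition (identity on the positive branch, `alpha*x` on the
negative) is implemented.

`variant_config()` exposes the three switches; the eight on/off combinations
are the package's ablation grid. Every variant is described first as a
symbolic *plan* (`build_plan()`); the complexity counters and the numeric
model are both derived from that one plan, so reported sizes can never drift
from the runnable network.

## Exact ordering inside reorganised stages

The published description fixes only: Start ends its branch with a norm
before the addition; End finishes with norm + activation after the addition;
parameter counts are unchanged. Within those constraints the ordering here
was chosen so that preservation is *exact*, not just approximate: the End
block's last convolution is left unnormalised, because its norm has moved
after the addition. Middle blocks take the entry norm on the branch (after
the split), keeping the trunk clean; since a middle block's input width
equals its output width (4× the bottleneck), the norm parameter total per
block is identical to the baseline's. `test-blocks.R` asserts stage-level
equality to the parameter.

## Counting parameters and MACs

Parameter counting is closed-form per layer (`count_params()`). As a
cross-check of the whole ledger, the 1000-class baseline variant counts
25,557,032 parameters — the canonical figure for the 50-layer bottleneck
network — and the 6-class baseline 23,520,326.

MAC counting (`count_macs()`) is deterministic, weight-independent and
batch-size-independent. Published FLOP counters disagree on which
non-convolutional layers to include and at what per-element cost, so the
convention here is fixed once and documented:

| layer | cost |
|---|---|
| conv (standard / depthwise / pointwise / 1-D attention) | exact MACs |
| fully connected | `in·out + out` |
| batch norm | 2 per element |
| ReLU | 1 per element |
| PReLU | 2 per element (both halves are computed and blended) |
| Swish | 1 per element (the product; the transcendental gate is not a MAC) |
| max pool | `k²` per output element |
| global average pool | 1 per input element |
| channel attention | pooled input elements + `C·k` + `C` |

The convention was calibrated so that the canonical baseline reports its
published 4.12 GMac at 3×224×224 *and* the improved variants report their
published 3.20 / 4.13 GMac under the same rule — the published numbers pin
the convention to within less than 0.002 GMac, because the convolutional
savings of the depthwise-separable substitution are fixed arithmetic
(0.9207 GMac). `count_macs(..., inclusive = FALSE)` gives the strict
conv+fc count for comparison.

## Numeric engine

No deep-learning framework is available to R in this package's dependency
set, so the forward/backward machinery is implemented here: batch tensors are
`(C, H, W, N)` arrays, k×k convolutions are GEMMs against C++-built patch
matrices, depthwise convolution and max pooling are direct C++ loops, and
everything else (batch norm with batch statistics, the three activations,
channel attention, global pooling, the classifier head, softmax
cross-entropy, SGD with momentum and L2 weight decay) is vectorised R on
BLAS. Gradients of every layer are verified against central finite
differences in the test suite's development history; the suite itself
asserts that one backward pass reaches every trainable tensor.

Numerical choices: double precision throughout; He-normal initialisation for
convolutions and the head; norm layers start at unit scale, zero shift;
normalisation epsilon 1e-5; running statistics by exponential average
(momentum 0.1) during training.

### Inference-mode normalisation on short schedules

After a few dozen SGD steps the exponentially averaged running statistics are
still far from the activation distribution, which wrecks inference-mode
accuracy long before the weights are at fault. `train_model()` therefore ends
with a *precise normalisation pass* (`recalibrate_bn()`): the exact
population moments E[x], E[x²] of every normalisation layer's input are
accumulated over class-mixed batches of the training set and replace the
running statistics. This touches no trained weight. On the study-scale
protocol (150 epochs) the pass is a no-op in practice; on desk-scale
schedules it is the difference between a working and a broken eval mode.

## Training protocol

`train_config()` defaults to the study protocol: 150 epochs, batch size 32,
SGD with learning rate 0.001, momentum 0.9, weight decay 0.0005, 5-fold
stratified cross-validation, with the validation folds doubling as the test
set (the protocol's own caveat: reported accuracies are means over the five
validation folds). The learning-rate grid explored upstream was
0.01/0.001/0.0001. No augmentation is applied (none is described).
Reported per-fold values are final-epoch values; best-epoch versus
final-epoch is not specified upstream, and final-epoch is the conservative
choice.

For the package's own *sanity training* checks a desk-scale schedule is
used: 240 synthetic crops (6 balanced classes × 40) at 48 px — class
identity in the generator is carried by colour and texture, so resolution is
immaterial and the architecture is resolution-agnostic through its global
pooling — for 5 epochs at batch 16 with learning rate 0.02 (the upper end of
the explored magnitude range), half-cosine learning-rate decay and
global-norm gradient clipping at 5. The two stabilisers matter: a 60-step
constant-rate schedule sits on a narrow ridge (nearby rates diverge or
stall), while with decay and clipping the same schedule clears the suite's
held-out sanity threshold (accuracy > 0.8) with a wide margin and does so
across seeds. Label-permuted training must stay at chance (±0.06 around
1/6). Both stabilisers default off in `train_config()`, matching the study
protocol.

## Segmentation pipeline

Multi-seed scene photographs are cut into fixed-size single-seed crops:
luminance conversion (0.299/0.587/0.114), automatic global thresholding by
between-class-variance maximisation (Otsu; a fixed threshold is available as
an escape hatch), morphological opening and closing with disk structuring
elements (default radius 3 px), hole filling, rejection of components under
`min_area` (default 400 px²), 8-connected component labelling, and one
`crop_size`² window per component centred on its centroid, padded with the
background grey when it overruns the border. Touching seeds form one
component by design — no watershed splitting is attempted. Standard image
operations are delegated to EBImage; the test suite checks the threshold
against a brute-force search over all 256 grey levels.

The per-class 80/20 split uses the *ceiling* rule
(`train_n = ceiling(0.8·n)`), the only rounding consistent with the published
per-class splits (e.g. 998 → 799/199); over the six published class totals it
yields the published 4703/1174 partition.

## Synthetic data

The original photographs are not deposited, so `synthetic_spec()` /
`generate_crop_dataset()` / `generate_scene()` emulate the inputs: oriented
ellipses with class-dependent base colour and sinusoidal texture frequency,
additive Gaussian noise (sd 5 grey levels), on a dark background kept below
grey 40; scenes place disjoint seeds by rejection sampling and record exact
ground truth (mask, centroids, count). Scenes are single-variety, mirroring
the acquisition protocol (each variety is photographed separately). The
model is deliberately minimal: it guarantees class separability (a
mean-colour nearest-centroid rule already exceeds 0.9 accuracy), which is
what makes the training sanity thresholds meaningful. It does **not**
emulate real seed morphology, specularities, shadows, or inter-cultivar
subtlety — passing these tests says the pipeline and optimiser work, not
that real-data accuracies are reproduced. Reproducing the study's real-data
accuracy (91.23%) is explicitly out of reach without the original dataset
and GPU-scale training.

## Grad-CAM

`grad_cam()` computes gradient-weighted class activation maps: spatially
averaged gradients of the class score weight the captured feature maps, the
rectified weighted sum is min–max normalised and bilinearly upsampled. The
capture point defaults to the last convolution of the last stage (the
upstream choice of layer is unstated). Two desk-scale caveats drive how the
localisation check is set up: the last-stage feature map must have genuine
spatial extent (3×3 at 96 px input, degenerate 2×2 at 48 px), and the
feature maps must have been *trained* at the geometry being probed — probing
a 48 px-trained model at 96 px leaves normalisation statistics and feature
scales off-distribution and the heatmaps diffuse. The localisation check
therefore trains its model on 96 px crops under the same short schedule and
probes at 96 px, where well over half of the top-decile heatmap mass falls
inside the generator's seed mask at the default layer.

## Known limitations

- The engine is a teaching/verification-scale implementation: single
  process, CPU, no autograd graph, no data augmentation hooks beyond the
  defaults. Study-scale (150-epoch, 224 px, thousands of images) training is
  out of its intended envelope.
- Only SGD with momentum is provided, as in the protocol.
- Confusion-matrix-level metrics assume single-label classification.
- The MAC convention is *a* convention; `inclusive = FALSE` exists precisely
  because other tools count differently.
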