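---
title: "Local structure information learning: models, parameters, and design choices"
author: "lsilearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local structure information learning: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsilearn)
```

# The problem

Fine-grained visual classification (FGVC) separates visually similar
subcategories — cultivars of a crop, bird species, car models — often from
very few training images per class. What distinguishes such classes is
local structure: the corners, edges, and blobs inside small salient
regions, and how they are arranged. `lsilearn` implements a local structure
information (LSI) learning framework with three parts: an
orientation-profile characterisation of local structures, an
information-preprocessing stage that augments each training image into a
rotation/shuffle group with continuous block-index labels, and a two-loss
training objective that makes a convolutional network both classify and
localise.

# Orientation profiles of local structures

## The filters

The anisotropic Gaussian at scale $\sigma$, anisotropy $\rho$, and
orientation $\theta$ is

$$ g(x, y) = \frac{1}{2\pi\sigma^2}\exp\!\left(
   -\frac{\rho^2 u^2 + v^2/\rho^2}{2\sigma^2}\right),
   \qquad u = x\cos\theta + y\sin\theta,\; v = -x\sin\theta + y\cos\theta. $$

The first-order directional-derivative kernel (FOAGDD) is
$\partial g/\partial u$, the second-order (SOAGDD) $\partial^2 g/\partial u^2$
— the standard construction of the anisotropic directional-derivative
literature. Kernels are sampled on the integer grid and mean-subtracted so
they sum to exactly zero: constant images give exactly zero response, and
adding any constant to an image changes nothing, while multiplying an image
by $s$ scales every response by $s$ exactly.

The orientation profile at a pixel is the vector of correlations with the
kernel at $P$ orientations $\theta_p = 2\pi p/P$. Derivative parity gives
two exact symmetries: the order-1 profile negates and the order-2 profile
repeats under $\theta \to \theta + \pi$. Two image-level invariances follow
and are verified to $10^{-6}$ in the tests: rotating an image by $\pi$
leaves response magnitudes unchanged at mapped pixels, and a horizontal
flip maps the response at $\theta$ to the one at $\pi - \theta$.

## Classifying structures by circular extrema

On the profile of the first-order responses, a step edge produces exactly
one circular local maximum and one minimum; a T-type junction of three
homogeneous sectors produces three of each; at the centre of an isotropic
Gaussian blob every first-order response vanishes by symmetry while the
second-order response is strong at every orientation. Extrema are counted
after collapsing runs of samples within a tolerance `eps` (default
$10^{-3}\,\max|{\rm profile}|$) so plateaus and float noise count once.
`classify_structure()` turns this into a fixed decision rule: flat order-1
profile with strong order-2 response → blob; two or more maxima → corner;
one → edge. The two thresholds default to fractions (0.1, 0.5) of peak
responses calibrated on generated canonical fixtures, so they adapt to the
filter normalisation; the decision rule itself is this package's choice —
the profile analysis names no detector.

## Parameter choices, and when the lobes resolve

`filter_params()` defaults to $\sigma = \rho = \sqrt{1.5}$ with $P = 64$
orientations and support radius $\lceil 4\sigma\rho \rceil$ (truncating
under $10^{-6}$ of kernel mass). These mild factors are appropriate for
feature extraction in the learning pipeline.

Resolving a junction's orientation profile into one lobe per boundary ray,
however, genuinely requires anisotropy. As $\rho \to 1$ the signed
first-order profile of *any* structure collapses toward a single cosine —
one maximum, one minimum — because an isotropic derivative filter measures
only the projection of one gradient vector. Numerically, the three-lobe
profile of the canonical T-junction first appears near $\rho \approx 2$ and
is stable across $\sigma \in [1.5, 3]$, the anisotropy range used in
anisotropic-directional-derivative corner analysis. There is a second
constraint: the kernel cross-section $\sigma/\rho$ must stay above roughly
half a pixel, or the sampled profile rings and spurious extrema appear.
`structure_analysis_params()` therefore fixes $\sigma = 2, \rho = 2$ for
all corner/edge/blob profile work, while the pipeline keeps the milder
default. Both are exposed.

The canonical T-corner fixture uses gray levels (0.1, 0.5, 0.9). With
non-monotone level assignments the two collinear half-edges can interfere
and merge lobes at moderate anisotropy; the monotone canonical fixture
exhibits the 3+3 profile robustly across the valid parameter region.

# Information preprocessing

An image is centre-cropped to a multiple of $N$ and partitioned into
$N \times N$ blocks. Block indices are the centred coordinates
$\{-(N-1)/2, \dots, (N-1)/2\}$ in unit steps — half-integers for even $N$.
(A symmetric integer range $-\lfloor N/2\rfloor..\lfloor N/2\rfloor$ holds
$N+1$ values for even $N$ and cannot index $N$ blocks; the centred scheme
has exactly $N$ symmetric values and maps onto itself under quarter-turn
rotations.)

Shuffling draws a permutation uniformly from all $(N^2)!$ arrangements with
a seeded RNG; the record is reproducible, conserves the pixel multiset, and
inverts exactly. Rotation uses bilinear interpolation about the image
centre with zero fill and unchanged size; 0 and $\pi$ are exact index
operations. Rotated images are *not* re-cropped, so every block position
persists and labels stay well defined.

Labels transform by the row-vector rule $[u, v] = [i, j]\,\mathbf R_k$ with
$\mathbf R_k$ the rotation matrix of angle $(k-1)\pi/K$ (or of an explicit
angle list; the view set $\{I, I_{\pi/6}, I_{\pi/4}, S\}$ is the default
and an explicit list always wins over the uniform schedule). Since
$\pi/6$ and $\pi/4$ rotations produce non-integer coordinates, labels are
continuous and never snapped back to the grid — the similarity loss is a
regression. Labels are normalised by $Z = \sqrt 2\,(N-1)/2$, the norm of
the outermost corner index, so every reachable label lies in $[-1, 1]$
componentwise, matching the saturating output of the prediction head
($Z := 1$ when $N = 1$).

The shuffled image's labels come from gray-value matching: each original
block's mean intensity is compared with each shuffled-position mean, and
indices are assigned greedily in ascending order of absolute discrepancy
with raster-order tie-breaks. The greedy one-to-one scheme guarantees a
bijection (a per-block "closest mean" rule could assign two originals to
one position) and coincides with the naive rule whenever means are
distinct, in which case it provably recovers the true inverse permutation
— verified against a brute-force assignment search in the tests. Labels of
rotated shuffled images are the matched labels passed through the same
rotation map.

# The model and its losses

## Heads and objective

The classification head is adaptive (global) average pooling over the
feature grid followed by an affine map and softmax. The index head is a
per-cell linear projection of the feature grid to two channels, a tanh
saturation into $(-1, 1)$, adaptive average pooling onto the $N \times N$
block grid, and axis reordering to per-block coordinate pairs.

For one training image with one-hot label $\boldsymbol l$ and augmented
views $\{I_1..I_{K_1}, S_1..S_{K_2}\}$:

$$ L_c = -\sum_{k=1}^{K_1} \boldsymbol l \cdot \log\varphi(I_k)
         -\sum_{d=1}^{K_2} \boldsymbol l \cdot \log\varphi(S_d), $$

$$ L_{sm} = \sum_{k=1}^{K_1}\sum_{\text{blocks}}
     \sqrt{(\tau_k(u)-u)^2 + (\tau_k(v)-v)^2}
   + \sum_{d=1}^{K_2}\sum_{\text{blocks}}
     \sqrt{(\varepsilon_d(p)-p)^2 + (\varepsilon_d(q)-q)^2}, $$

a sum of per-block 2-D distances, not a global norm, evaluated in
normalised index units (multiply by $Z$ for raw units). The total objective
is $L_c + \lambda\,L_{sm}$ with $\lambda = 1$ by default ($\lambda$ is not
prescribed by the method; it is exposed in the config, and $\lambda = 0$
ablates to plain cross-entropy). True-class probabilities are floored at
$10^{-12}$ inside the log purely as a numerical guard. Both heads share one
backbone pass per view — the cheaper of the two options and consistent
with a single shared feature extractor.

## The toy backbone

No deep-learning framework is assumed: the package ships a 4-layer
convolutional backbone in plain R with hand-written backpropagation,
verified against central-difference gradients at $10^{-10}$ relative error.
Design choices that matter:

* 3×3 "same" convolutions with **edge-replicate padding**, so constant
  images stay exactly constant through the network.
* **Per-channel spatial standardisation** (instance normalisation without a
  learned affine) after stages 1–3. Without it, activations drift to a
  regime where pooled features of different images are nearly identical and
  learning stalls. The final stage is left raw so that globally pooled
  features retain their between-image statistics — standardising it would
  remove exactly the signal the classification head pools.
* A **hypercolumn output**: the pooled stage-2, stage-3, and stage-4
  activations concatenated on the final grid. The index head needs
  small-receptive-field features (a shuffled block's identity is local
  content; deep features smear across shuffled-block boundaries), while the
  classifier benefits from deep ones. Default widths (8, 16, 32, 64) give a
  112-channel feature grid at 1/8 resolution.

Any function from an image to a spatial feature grid can replace the toy
backbone behind the same head contracts; heavyweight pretrained backbones
are deliberately not bundled.

## Optimisation

Training is stochastic gradient descent with momentum 0.9 in two phases:

1. **Head warm-up.** The backbone stays at its initial weights; features of
   every view are computed once and cached, and both heads are fitted on
   them (80 epochs at rate 0.05 by default — cheap, since no backbone
   passes are needed). Cached feature channels are standardised for this
   fit and the affine standardisation is *folded back into the head
   weights* afterwards — an exact reparameterisation. This step is what
   makes plain SGD work here: the pooled features have a large common
   component and a small discriminative one, and on the raw scale the
   logistic problem is so ill-conditioned that SGD at any stable rate
   barely moves.
2. **Joint fine-tuning** of backbone and heads (16 epochs, rate $10^{-3}$,
   decayed ×0.1 every 8, backbone at 0.1× the head rate, global
   gradient-norm clipping at 5). The differential rate and the clip keep
   the fine-tune from destroying the warm-started heads, whose folded
   weights are large.

The full-scale preset `lsi_fullscale_config()` (384×384 crops, $N = 6$,
batch 16, rate $10^{-3}$ decayed every 60 of 160 epochs, no warm-up) is the
benchmark-scale protocol, shipped untested at that scale.

The desk-scale protocol trains on 64×64 images, 5 classes × 5 training
images, the default view set, and $N = 2$; one run takes on the order of a
minute on one CPU. The epoch budget (80 warm-up + 16 joint) differs from a
pure-joint schedule because the warm-up epochs are roughly two orders of
magnitude cheaper than joint epochs.

Inference uses the plain image only — augmentation is a training-time
device.

# The synthetic data

`make_step_edge()`, `make_t_corner()`, and `make_blob()` generate the
structure fixtures: half-planes with a one-pixel linear boundary ramp,
three homogeneous sectors meeting at the centre pixel (8× supersampled for
anti-aliasing), and an isotropic Gaussian bump. Fixture size defaults to
129×129 with the feature point at the exact centre. Degenerate parameter
choices downgrade the truth label: equal edge levels give a constant image
("none"); a T with equal levels across the perpendicular pair degenerates
to a step edge; equal levels across one collinear pair leave an L-type
corner, flagged as degenerate.

`make_toy_dataset()` renders one star-shaped silhouette family per class —
$r(\phi) = r_0(1 + 0.25\cos(k_c\phi + \phi_c) + 0.12\sin\phi)$ with
class-specific lobe count $k_c$ and phase — under a fixed two-direction
shading gradient, with per-image jitter: position up to 5 % of the side,
rotation up to 10°, additive Gaussian noise $\sigma = 0.02$. The shading
gradient makes block means injective in block position, which serves two
purposes: gray-value matching recovers shuffle permutations with
probability 1, and block content carries a learnable position signal for
the index head. The $\sin\phi$ term breaks the $k_c$-fold symmetry that
would otherwise make quadrants of a shape indistinguishable. Generators are
pure functions of their parameters and seed.

What the toy data does *not* emulate: photographic texture, clutter,
occlusion, illumination changes, or class boundaries defined by subtle
part-level differences. Passing tests therefore demonstrate the
correctness of the mechanism — filters, labels, losses, optimisation — not
performance on real cultivar photographs.

# Numerical choices and degenerate inputs

* Extrema counting merges circular plateaus within `eps` before comparison;
  an all-constant profile has no extrema rather than raising an error.
* Point analyses (`directional_response()`) refuse locations within the
  kernel support of a border — no implicit padding; whole-image
  `response_map()` uses symmetric reflection padding, with a "valid" mode
  that masks the border band to `NA`.
* Matching ties break by raster (column-major) order, making shuffled-label
  assignment deterministic even with duplicated block means.
* The LSFSM gradient at an exact hit (distance 0) is taken as 0.
* Coordinates are R-style 1-based (row, col); $\theta$ is measured from the
  +x (column) axis, counterclockwise with +y up, and the row/column ↔ x/y
  flip is handled inside kernel sampling.
* Seeded operations save and restore the caller's RNG state.

# Known limitations

* The pure-R network is desk-scale: minutes for the toy protocol, far from
  the throughput needed for 384×384 benchmark datasets.
* Head-only label recovery depends on the random feature bank being wide
  enough; the shipped recovery experiment uses widths (16, 64, 128, 320).
* The blob's second-order profile is treated as near-constant over
  orientation; its exact shape is not asserted beyond the decision rule.
* Gray-value matching is only guaranteed when block means are distinct;
  natural images with large homogeneous regions can produce ties, resolved
  deterministically but not necessarily correctly.
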