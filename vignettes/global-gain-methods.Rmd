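---
title: "Modelling arousal as global gain: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling arousal as global gain: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gainsweep` studies how a single *global gain* scalar reshapes perceptual
decision-making in a hierarchical visual model. Cortical arousal, driven by
the diffuse release of noradrenaline, is modelled as one parameter
$\delta > 0$ that multiplicatively scales the output of **every** activation
function in a convolutional network:

$$ f(S) = \delta \cdot g(S), $$

where $S$ is the incoming activation of a unit and $g$ is the unscaled
nonlinearity. Two nonlinearities are provided (`activation_spec()`):

* a **rectifier**, $g(S) = \max(0, S)$;
* a **saturating** family,
  $g(S) = A_{max}\tanh\!\big(h\,\max(0, S - c_0)/A_{max}\big)$, which is
  non-negative, non-decreasing, behaves like the rectifier near threshold
  (within 2% of $\max(0,S)$ on $S\in[0,1]$ at the defaults $h=1$, $c_0=0$,
  $A_{max}=5$) and saturates at the response ceiling $A_{max}$, mimicking
  bounded firing rates. The defaults are a design choice of this package:
  the biologically derived constants of the original formulation live in an
  external reference and only the qualitative properties (threshold,
  near-linear rise, ceiling) matter for the analyses here.

Networks are trained exclusively in the neutral state $\delta = 1$ and then
evaluated across a grid of gain states without further training, so any
performance change across $\delta$ reflects how the *fixed* learned circuit
responds to a global excitability change — the model analogue of testing the
same observer at different arousal levels.

## The backbone and the normalization decision

`build_backbone()` constructs a reduced residual network: a convolutional
stem and eight residual blocks of two 3×3 convolutions (widths 8–64,
stride-2 downsampling at blocks 3, 5 and 7), global average pooling, and a
linear head. The block structure mirrors the eight residual stages of a
standard 18-layer residual network at a desk-trainable scale. Per-block
*tap points* — the output of the last activation in a block, after the
residual and skip branches are merged — are addressable for decoding and
activation analyses (`forward_with_taps()`).

Two normalization variants exist, and the choice matters greatly for gain
studies:

* `use_bn = TRUE`: batch normalization after every convolution, with batch
  statistics during training and frozen running statistics at evaluation
  (so gain effects propagate instead of being renormalized away).
* `use_bn = FALSE` (the pipeline default): no normalization layers, only
  per-channel convolution biases, with the second residual convolution
  down-scaled at initialization and gradient-norm clipping during training.

The default is normalization-free for a quantitative reason. A frozen
batch-norm layer is an affine map whose constants do not scale with
$\delta$; with roughly seventeen activation sites, the mismatch between the
$\delta$-scaled signal and the fixed affine constants compounds so steeply
at this network scale that class separation collapses outside
$\delta \in [0.95, 1.1]$ — too narrow for any difficulty-by-gain structure
to be resolved. A network whose only fixed constants are small learned
biases is close to positively homogeneous: its representation degrades
gradually and asymmetrically as $\delta$ moves away from 1, which is the
regime in which performance–gain profiles are informative. The rectifier is
the default pipeline activation because the thresholded saturating variant
trains substantially more slowly at this scale; the gain phenomenology of
interest replicates under a purely linear activation regime, and the
saturating family remains fully supported and property-tested.

For a bias-free, normalization-free sequential rectifier network
(`build_sequential_net()`), the logits under gain $\delta$ equal exactly
$\delta^L$ times the neutral logits ($L$ = number of activation layers).
This closed-form identity is used as the analytic oracle for the gain
mechanism in the test suite.

## Synthetic stimuli

All data are procedural (`generate_real_images()`,
`generate_category_dataset()`); nothing is downloaded.

A "real" scene is composed of: a **shared low-frequency layout** (a fixed
luminance gradient plus a fixed smooth field, entering every image at a
positive lognormal amplitude), multi-scale oriented gratings, soft
elliptical blobs, one convex polygonal occluder, and a per-image lognormal
contrast factor (`contrast_sdlog = 0.25`). The shared layout gives scenes a
mean pairwise pixel correlation of roughly 0.3, chosen to match the strong
common structure of natural scenes. This matters for the task: because
scenes correlate, a blend of many scenes retains the shared structure and a
substantial part of its contrast, so the discrimination below is carried by
*structure* (ghosting, loss of crisp detail) rather than by a single global
contrast scalar — as with photographs. Without the shared component the task
degenerates into a pure-amplitude discrimination, which is an artifact of
uncorrelated noise images.

**Perceptual difficulty task.** An *average image* at level $k$ is the
pixel mean of $k$ source scenes (`make_average_image()`): for integer $k$
the unweighted mean; for fractional $k = m + \alpha$ the weighted mean of
$m+1$ sources with weights $(1,\dots,1,\alpha)/k$, so $k = 1.25$ blends a
full-weight scene with a second scene at 25%. The binary task is
real-versus-average; larger $k$ makes the average less like any single
scene and the task easier. `build_difficulty_suite()` builds balanced,
disjoint train/validation/test triplets per level, sharing real images
across levels and rebuilding averages per level from a source pool disjoint
from the real class.

Two diagnostics characterize the manipulation: the mean correlation between
an average image and its own source scenes decreases with $k$
(`average_source_similarity()`), and the contrast-channel separability of
the two classes grows with $k$ (`contrast_separation()`). Note that the
correlation between average images and *unrelated* real images is not a
usable diagnostic: for any exchangeable generator with disjoint pools it
equals $\rho/\sqrt{\rho + (1-\rho)/k}$ ($\rho$ = scene–scene correlation),
which does not decrease with $k$. Similarly, the raw pixel distance between
the two classes *shrinks* with $k$ (the average class contracts toward the
population mean); what grows, and what makes the task easy, is
separability.

**Category task.** Eight categories defined by a soft blob with a
category-specific ring position and color signature over an uninformative
textured background; linearly decodable from raw pixels by design. This
dataset drives backbone pretraining and the answer-options analysis.

What the generator does *not* emulate: natural image statistics beyond
second order, semantic content, eccentricity effects, or the sheer
dimensionality of photographic datasets. Passing tests therefore show that
the pipeline's logic and the direction of its effects are sound at desk
scale, not that the quantitative results transfer to photographs.

## Training protocol

`pretrain_backbone()` trains all backbone weights on the category task with
momentum SGD (cosine-decayed learning rate 0.02, batch 32, gradient-norm
clipping at 2, 30 epochs on 640 images by default), entirely at
$\delta = 1$. `finetune_head()` then trains per-condition sigmoidal output
heads on the *frozen* backbone's pooled features — binary cross-entropy for
the real-vs-average heads, multi-label sigmoid cross-entropy for category
heads — with a small L2 penalty and per-dimension feature standardization
(train-set statistics frozen into the head as fixed affine constants; they
are not recomputed per gain state, so gain effects are not normalized
away). An integrity hash asserts the backbone is byte-identical before and
after head training.

Model *instances* are heads trained from distinct seeds. Because a
near-convex head fit converges to almost the same optimum from any seed,
each instance additionally trains on a bootstrap resample of the training
split; this emulates the run-to-run variability that full fine-tuning
stochasticity provides at larger scale and keeps across-instance confidence
intervals non-degenerate.

## Performance–gain profiles and their summaries

`sweep_gain()` evaluates every instance at every gain value of a grid
(geometric spacing, since gain acts multiplicatively; the neutral state 1
is always included). Binary tasks yield accuracy, hit and false-alarm
rates, sensitivity and bias:

$$ d' = z(\text{hit rate}) - z(\text{FA rate}), \qquad
   c = -\tfrac12\big(z(\text{hit rate}) + z(\text{FA rate})\big), $$

with extreme rates corrected by the $1/(2N)$ rule before the quantile
transform. Categorical tasks yield accuracy and the mean one-vs-rest AUC
(Mann–Whitney identity, ties counted ½).

`find_peak()` extracts, per instance, the set of gain values attaining the
best metric value — for bias, the value closest to zero — and summarizes
ties by their **median**; across instances it reports the median peak and a
Student-t 95% interval (`summarize_ci()`), a deterministic choice over
bootstrapping. The default analysis grid is 41 geometric points on
$[0.5, 2]$: at this model scale the informative gain range is narrower than
for a large pretrained network, and resolution near the neutral state is
what determines whether peak differences between conditions can be resolved
at all. The wider exploratory default `gain_grid()` spans $[0.125, 8]$.

## Decoding probes and mean activations

`decode_block()` fits an L2-regularized logistic regression (fixed small
ridge penalty, no standardization) on flattened tap activations, over five
iterations of randomly drawn disjoint train/test sets; features above 1024
dimensions are first reduced by a seeded Gaussian random projection, which
preserves probe accuracy to first order (verified in the tests).
`decoding_peak_gain()` reuses the tie-median peak rule on
iteration-averaged accuracies, excludes difficulty levels solved above 0.99
for every block and gain state (peak location is meaningless at ceiling),
and averages peaks across the remaining difficulties per block.
`most_informative_block()` reports first and last tied block indices.
`mean_activation()` is the plain scalar mean over images, channels and
space.

## Spatial scrambling

`scramble_block()` permutes the spatial positions within a seeded random
subset of $\lceil p \cdot C\rceil$ feature maps, independently per map and
per image, applied to the **residual branch** output before it is added
back to the skip branch. Permutation preserves each map's value multiset
(hence mean and variance) exactly while destroying its spatial information;
untouched maps are bit-identical. Permutations are drawn fresh per
repetition from the repetition seed.

`importance_curve()` measures accuracy at $\delta = 1$ against $p$;
`calibrate_rate()` smooths the curve isotonically (non-increasing), forms
the retention $r(p) = (\text{perf}(p) - \text{floor}) /
(\text{perf}(0) - \text{floor})$ with
$\text{floor} = \min(\text{perf}(1), \text{chance})$, and solves
$r(p^*) = 0.2$ by linear interpolation between grid points — i.e. $p^*$ is
the rate at which the block has lost 80% of its possible contribution. The
chance-floor normalization resolves the ambiguity between
"20% of the contribution" and "20% of baseline performance": the raw
reading is ill-defined when baseline performance is near chance. A flat
curve falls back to $p^* = 1$ with a warning; at this network scale that
fallback is common for the easy task, whose pooled-energy cue survives
single-block scrambling almost everywhere — global average pooling is
itself permutation-insensitive, so scrambling acts only through downstream
nonlinear processing.

`progressive_scramble_sweep()` scrambles the $s$ outermost blocks
(late-to-early or early-to-late) at their calibrated rates and sweeps the
gain grid per stage, ten repetitions by default differing only in their
permutation seeds.

## Numerical choices

* All randomness flows through named integer seeds (`withr::with_seed`
  internally); derived seeds stay below $2^{31}$.
* Exact ties in empirical accuracies are recognized with a $10^{-9}$
  tolerance in peak extraction.
* Ridge probes use a fixed penalty of 0.01 with a short warm-start path; if
  the path terminates early the target penalty is refit directly and
  predictions are computed from the coefficients.
* Degenerate single-class probe draws are redrawn (and logged).
* Multiplying by a gain of exactly 1 is skipped, so the neutral state is
  bit-identical to a network without the gain machinery.

## Scale of the shipped experiments

The experiments run by the test suite and the acceptance script use
deliberately small problem sizes, chosen as this package's study
conditions: 32×32×3 images, 640 pretraining images, 400/128/384 images per
difficulty split, five head instances, a 41-point gain grid on $[0.5, 2]$,
and reduced repetition counts for the scrambling analyses. The original
study conditions (64×64 or larger images, thousands of training images, ten
instances, wider sweeps) are reachable through the same configuration
surface.

## Known limitations

* The directional difficulty-by-gain interaction is real but small at this
  scale: easy-task peak gains sit at or slightly above the neutral state
  and hard-task peaks at or slightly below, with differences of a few
  percent in gain — far smaller than with a large pretrained backbone. The
  replication targets are therefore directional, not numeric.
* With frozen batch normalization the model is catastrophically
  gain-fragile at this scale (see above); the `use_bn = TRUE` variant is
  retained for completeness and contrast, not as the default.
* Importance curves of individual blocks are often flat for easy tasks, so
  calibrated scrambling rates frequently saturate at $p^* = 1$.
* Temporal dynamics (phasic versus tonic arousal), pupillometry-style
  readouts, and neuromodulator diversity are out of scope.
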