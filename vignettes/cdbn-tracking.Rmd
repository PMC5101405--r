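---
title: "Tracking with a convolutional deep belief network appearance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking with a convolutional deep belief network appearance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cdbntrack` tracks a single cell or object through an image sequence with
a discriminative appearance model built from a convolutional deep belief
network (CDBN).  The network is a stack of two convolutional restricted
Boltzmann machines (CRBMs) with probabilistic max-pooling, a fully
connected logistic layer, and a logistic output head.

A CRBM couples real-valued visible units $v \in \mathbb{R}^{n_V \times
n_V}$ (per channel) to binary hidden units $h^k \in \{0,1\}^{n_H \times
n_H}$, $n_H = n_V - n_W + 1$, through $K$ shared $n_W \times n_W$
convolution filters $W^k$:

$$E(v,h) = \tfrac12\sum_{ij} v_{ij}^2
  - \sum_k \sum_{ij} \sum_{rs} h^k_{ij} W^k_{rs}\, v_{i+r-1,j+s-1}
  - \sum_k b_k \sum_{ij} h^k_{ij} - c \sum_{ij} v_{ij},$$

subject to the probabilistic max-pooling constraint that at most one
hidden unit per $C \times C$ block may be active; a pooling unit $p_a^k$
is on iff its block has an active unit.  The constraint turns each
block's conditional into a $(C^2+1)$-way softmax over the block's units
and the all-off state, computed from the pre-activations
$I(h^k_{ij}) = (\tilde W^k \ast_v v)_{ij} + b_k$; the visibles are
conditionally Gaussian with mean $\sum_k W^k \ast_f h^k + c$ and unit
variance.  Because the visible conditional assumes unit variance, every
patch is standardised to zero mean and unit variance before entering the
network; the original mean/sd are kept as attributes.

CRBMs are highly overcomplete, so each layer is trained by one-step
contrastive divergence (CD-1) with a sparsity penalty that holds each
map's mean activation $q_k$ near a small target $p$ (0.003 for layer 1,
0.005 for layer 2).  The penalty is the squared error
$-\lambda\,(p - q_k)^2$, differentiated exactly through the block
softmax (the Jacobian contributes a factor
$P(h_u{=}1\mid v)\,P(p_a{=}0\mid v)$ per unit) and applied to both the
filters and the hidden biases.  The penalty's gradient vanishes
quadratically near the target, so $\lambda$ must be large for the
equilibrium activation to sit close to $p$; the default
`sparsity_weight = 1000` (with likelihood increments averaged per hidden
unit and per patch) settles within a few tens of percent of the target
at the default problem sizes.  CD step count is 1 and the negative-phase
reconstruction uses the Gaussian mean rather than a sample; both are the
standard fast choices.

## Architecture, pretraining and transfer

The full architecture is: 12 filters of $5\times5$ in layer 1 and 288
filters of $7\times7$ in layer 2, pooling ratio 2 at both layers, so a
$32\times32$ patch maps through $28 \to 14 \to 8 \to 4$; the $4\times4
\times 288$ pooled maps feed a 192-unit fully connected logistic layer
and a 10-unit logistic output for the 10-class pretraining task.  Layer
2 connects to all 12 layer-1 maps (grouped connectivity would also be
consistent with the filter count; full connectivity is the simpler
reading and is what we implement).  With this choice the model holds
about $1.06\times10^6$ parameters — the dominant term being the
$192 \times 4608$ fully connected weight matrix — which the model's
`print` method reports.

Pretraining is greedy and layer-wise: layer 1 on the standardised
patches, layer 2 on the pooled probabilities of layer 1
(`crbm_pooled_representation()`, the deterministic bottom-up signal),
then the head by minibatch gradient descent with momentum on
cross-entropy with the CRBM features fixed.  Three choices matter here
and were genuinely open:

* **Logistic outputs everywhere.**  The output layer uses elementwise
  logistic units (multi-label cross-entropy during pretraining) rather
  than a softmax, so the same forward contract covers the 10-unit
  classification head and the single-unit tracking head.
* **Frozen feature standardisation.**  Sparse pooled features live on a
  scale of $10^{-3}$–$10^{-2}$ with per-feature spreads around
  $10^{-5}$.  A per-feature affine standardisation (mean/sd measured on
  the pretraining features, then frozen into the model) brings them to
  $O(1)$ for the head; values are winsorised at $\pm 4$ so
  out-of-domain patches cannot saturate the head.  Without this the
  logistic head trains many orders of magnitude too slowly.
* **Head weight decay.**  A small $L_2$ penalty (`1e-3`) during head
  pretraining keeps the fully connected weights from growing until the
  logistic units saturate; a saturated head transfers badly because all
  gradients through it vanish.

Transfer replaces the 10-unit output with a single freshly initialised
logistic unit and preserves every other parameter bit-exactly
(`cdbn_transfer_output()`); the unit's activation is the foreground
confidence used as the particle filter's observation likelihood.

Fine-tuning (`cdbn_finetune()`) is end-to-end gradient descent with
momentum through the deterministic forward pass (pooling probabilities
as activations — no sampling, which is what makes the network
differentiable).  Defaults follow the published operating point:
learning rate 0.1, momentum 0.5, 500 epochs per frame under the full
preset.  Two robustness choices: samples are weighted inversely to
class frequency (online buffers are heavily skewed towards negatives),
and gradients are norm-clipped per parameter group
(`clip_norm = 0.1`) because the frozen feature standardisation
amplifies gradients entering the CRBM stages by up to five orders of
magnitude; without clipping a single update can destroy the pretrained
filters.  Analytic gradients are verified against central finite
differences in the test suite.

## The tracking loop

Tracking is a bootstrap particle filter over box states
$x_t = (p^x, p^y, w, h)$ with a Gaussian motion model
$p(x_t \mid x_{t-1}) = N(x_t; x_{t-1}, \Sigma)$.  Defaults:
$\Sigma = \mathrm{diag}(6^2, 6^2, (0.02 w_0)^2, (0.02 h_0)^2)$ — the
translation scale of benchmark-era particle trackers, configurable.
Each frame: propagate the 1,000 particles; weight each by
$w^i_t = w^i_{t-1}\, p(y_t \mid x^i_t)$, where the likelihood is the
CDBN confidence of the particle's patch (boxes are clipped to the
frame, resampled bilinearly to $32\times32$, standardised); take the
maximum-weight particle as $x_t^*$; resample multinomially when the
weight spread degenerates.  The degeneracy test is the effective sample
size $N_\mathrm{eff} = 1/\sum_i (w_t^i)^2 < N_1/2$, a monotone
transform of the weight-variance criterion and the numerically stable
convention.

The appearance model is updated every frame from three tiers of
positives plus negatives:

* **ground-truth** $s_g^+$ — the first-frame box and four one-pixel
  jitters, never modified afterwards;
* **long-term** $s_{lt}^+$ — a FIFO of the tracked patch of each past
  frame, capacity $T = 25$;
* **short-term** $s_t^+$ — the 10 highest-confidence particle patches
  of the current frame (after dropping duplicate boxes left by
  resampling);
* **negatives** $s_t^-$ — 100 boxes of the tracked size drawn from an
  annulus at $0.5$–$2\times \max(w,h)$ from the tracked centre, kept
  only when their IoU with the tracked box is below 0.3.  The annulus
  construction and the counts for $s_t^-$ and $s_g^+$ are this
  package's defaults; only $|s_t^+| = 10$ and $T = 25$ are fixed by the
  published operating point.

The mixture is what resists drift: short-term samples adapt to fast
appearance change, the FIFO remembers the recent past, and the immutable
first-frame samples anchor the model so that a run of bad updates cannot
permanently re-label the background as foreground.

## Synthetic data

`make_class_dataset()` generates the 10-class labelled patch set used
for pretraining: parametric texture families (four grating orientations,
checkerboard, blob, ring, corner, cross, spot lattice) with per-sample
jitter and additive noise.  It stands in for a generic natural-image
patch collection so that everything here builds and tests offline; a
reader for the CIFAR-10 binary format (`read_cifar10_batch()`) is
provided for users who want the real source task.

`make_sequence()` renders microscopy-like tracking sequences: a
Gaussian-blob target on a moving linear path, with optional intensity
drift, a rotating illumination plane, clutter blobs performing random
walks, an opaque occluder pinned to the target during a configurable
window, Gaussian pixel noise, and 8-bit quantisation.  The shipped
presets (60 frames at $320\times240$) cover a clean linear target, an
illumination ramp, a 10-frame full occlusion, and a dense low-contrast
"cell" regime.  What these do **not** emulate: nonrigid deformation,
division events, out-of-plane rotation, photometric sensor noise beyond
additive Gaussian — so green tests here demonstrate the machinery and
its contracts, not performance on real microscopy.

## Numerical choices and degenerate inputs

* Block softmaxes subtract the block maximum before exponentiating, so
  conditionals are invariant under any constant shift of a block's
  pre-activations (tested up to $b_k = 500$).
* Ties in the argmax over particle weights resolve to the lowest
  particle index; uniform weights therefore return particle 1.
* Constant patches standardise to all zeros rather than dividing by a
  near-zero sd.
* If every particle likelihood underflows to zero, weights reset to
  uniform with a warning rather than dividing by zero.
* A box that has drifted partly outside the frame is clipped before
  resampling; a box with no frame intersection gets zero likelihood.
* Divergent CRBM training (non-finite parameters) aborts with the epoch
  number rather than propagating NaNs.

## Problem sizes used by the tests

The shipped tests and the acceptance script run a reduced preset — 8
and 32 filters, 64 FC units, 150–300 particles, short per-frame
updates, 200–500 training patches, 40–50 CD epochs — which reproduces
every structural and behavioural contract of the full configuration at
a few percent of its cost.  The full preset (12/288 filters, 192 FC
units, 1,000 particles, 500 epochs per frame) is the package default
for real use.

## Known limitations

* Single-target only; no data association, so multi-cell scenes need
  one tracker per cell.
* The scale dimensions of the motion model are weakly observable from a
  $32\times32$ standardised patch; long sequences can drift in scale.
* CD-1 with a mean-field reconstruction biases the likelihood gradient;
  this is the usual trade of fidelity for speed and is sufficient for
  the feature-learning role the CRBMs play here.
* Per-frame updates at the full operating point (500 epochs over the
  buffers) dominate runtime; `update_every` trades adaptation speed for
  throughput.
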