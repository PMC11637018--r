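---
title: "Uncertainty-aware mean-teacher segmentation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware mean-teacher segmentation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Delineating a clinical target volume (CTV) on cone-beam CT is a
segmentation problem with two unusual difficulties: CBCT volumes are noisy,
shaded and laterally truncated compared with planning CT, and expert CTV
contours are expensive, so labeled CBCT volumes are scarce while unlabeled
ones accumulate with every treatment fraction. `uamt3d` implements a
semi-supervised answer: train a segmentation network on the few labeled
volumes while extracting a consistency signal from the many unlabeled ones,
trusting that signal only where the model is demonstrably confident.

## The model

Two networks share one architecture. The **student** (parameters $z$) is
trained by gradient descent; the **teacher** (parameters $z'$) is never
touched by gradients and instead follows the student as an exponential
moving average after every step,

$$z'_t = \varepsilon z'_{t-1} + (1 - \varepsilon) z_t, \qquad
  \varepsilon = 0.99,$$

so 99% of the teacher is kept and 1% is transferred from the student per
step. The teacher starts as an exact copy of the student.

The joint objective over $M$ labeled and $Q$ unlabeled cases is

$$L = \sum_{i=1}^{M} L_{sup}(f(x_i; z), y_i)
    + \lambda \sum_{i=M+1}^{M+Q} L_{con}\big(f(x_i; z, \xi),
      f(x_i; z', \xi')\big),$$

with independent input noise $\xi, \xi'$ for student and teacher.
$L_{sup}$ is the unweighted mean of a smoothed soft-Dice loss on the
softmax foreground probability and the voxelwise cross-entropy. The
consistency weight follows the Gaussian ramp
$\lambda(t) = \lambda_{max} \exp(-5 (1 - t/T)^2)$ for $t < T$.

**Uncertainty gating.** Before the consistency loss is evaluated, the
teacher is run $N$ times (default $N = 8$) on independently perturbed
inputs with dropout active. The passes are averaged into a mean class
probability $M_c = \frac{1}{N}\sum_t p_t^c$ and condensed into a voxelwise
entropy $U = -\sum_c M_c \log M_c$ (natural log, so $0 \le U \le \ln c$).
Only voxels with $U$ strictly below a threshold $I$ contribute:

$$L_{con}(f, f') = \frac{\sum_i H(u_i < I)\, \lVert f_i - f'_i \rVert^2}
                        {\sum_i H(u_i < I)},$$

where the per-voxel squared difference is averaged over classes (keeping
the loss in $[0,1]$ for probability inputs) and an empty mask yields 0 by a
guarded division. Ties $u_i = I$ count as uncertain, matching the strict
indicator. The threshold ramps from $\tfrac{3}{4}\ln c$ to $\ln c$ with the
same ramp as $\lambda$, admitting only confident voxels early. The
consistency target $f'$ is the Monte-Carlo mean $M_c$ itself — the stack is
computed for the uncertainty map anyway, and the averaged prediction is the
lower-variance teacher output.

## The backbone

The backbone is a 3D U-Net whose blocks are two (3×3×3 convolution →
InstanceNorm → leaky ReLU) operations, with max-pooling down and trilinear
upsampling + skip concatenation up, and a final 1×1×1 convolution to raw
class scores. Two switchable features form the ablation axis:

* **Residual skips** across each block (identity, or a 1×1×1 projection
  when the channel count changes; post-activation addition).
* **CBAM attention** appended to each block: channel attention first
  (global max- and average-pooled descriptors through a shared two-layer
  bottleneck, summed, sigmoid), then spatial attention (channelwise max and
  mean maps, a shape-preserving convolution, sigmoid). The order is
  structural — channel strictly before spatial — and is asserted by a
  composition test.

Both flags off gives a plain 3D U-Net; residual only, and residual+CBAM,
complete the three ablation architectures. Design choices the source
material left open, resolved here once: CBAM sits in encoder *and* decoder
blocks; residual addition is post-activation, and attention refines the
convolutional branch before the skip is added (the CBAM-ResNet
arrangement; it also guarantees the identity path is never attenuated by
the attention product, which desk-scale probes showed can otherwise
produce degenerate constant-output initializations); upsampling is trilinear
interpolation followed by convolution rather than transposed convolution
(avoids checkerboard artifacts); convolution weights are Kaiming-initialized
for leaky-ReLU networks; dropout (the Monte-Carlo ingredient) sits after
every block group at rate 0.1, and 0.5 after the bottleneck. The engine —
direct cache-blocked convolution kernels, manual backpropagation, SGD — is
implemented in this package (R + C++); an im2col+GEMM convolution path is
retained purely as an independent numerical cross-check.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ema_decay` | 0.99 | teacher EMA decay $\varepsilon$ |
| `mc_passes` | 8 | stochastic teacher passes $N$ |
| `lambda_max` | 0.1 | peak consistency weight |
| `rampup_length` | 1000 steps | ramp $T$ for $\lambda$ and $I$ |
| `lr`, `momentum`, `weight_decay` | 0.001, 0.9, 1e-4 | SGD settings |
| `dropout_rate` / `dropout_bottleneck` | 0.1 / 0.5 | MC-dropout rates |
| `cam_reduction`, `sam_kernel` | 8, 7 | CBAM bottleneck ratio / kernel |
| noise `sigma`, `clip` | 0.1, 0.2 | input perturbation $\xi$ (normalized units) |

The learning rate 0.001 and batch composition (1 labeled + 1 unlabeled per
step) are the conventional settings for clinical-scale training of this
model family, where a run spans tens of thousands of steps. An epoch is one
pass over the unlabeled pool (this also step-count-matches a $\lambda = 0$
baseline); purely supervised datasets fall back to the labeled pool.

## The phantom generator

Clinical CT/CBCT pairs with CTV contours are not freely available, so the
package ships a generator whose cases mimic the geometry of the clinical
problem: a half-ellipsoidal soft-tissue target (the "breast", intensity
0.5) resting on the anterior face of a high-intensity planar slab (the
"chest wall", intensity 1.0) over a zero background, in abstract intensity
units. The degraded sibling of each case applies a low-frequency
multiplicative shading field (amplitude 0.2), additive Gaussian noise
(default sd 0.1 — CBCT-like noise at 20% of the tissue contrast, and large
enough that degraded volumes always carry strictly more intensity variance
than their clean siblings), and zeroes the outermost 10% of lateral
columns, mimicking CBCT truncation. Geometry is randomized per case within
bounds that keep the target fraction in roughly 2–6% of voxels, away from a
two-voxel border. Every case draws from an RNG stream derived from
`(seed, case_index)`, so any case regenerates independently and
bit-identically.

What the phantoms deliberately do **not** emulate: CBCT artifact physics
(scatter, beam hardening, motion), HU calibration, anatomical variability
beyond affine-ish geometry changes, and inter-observer contour ambiguity.
Tests passing on phantoms therefore demonstrate that the machinery —
losses, uncertainty gating, EMA, inference, metrics — behaves as specified,
and that consistency training extracts usable signal from unlabeled
degraded volumes; they do not certify clinical accuracy.

## Desk-scale experiment sizes

The test suite and the acceptance script run a scaled-down semi-supervised
experiment chosen to be meaningful yet desk-sized: 40 phantom cases of
64×64×16 voxels (spacing 1×1×3 mm), 10% labeled, a 20% held-out test split,
training on the whole volume (the training window equals the phantom size,
the desk-scale analogue of trimming a centered sub-volume that covers the
anatomy), 15 epochs, a 2-level backbone with 2 base channels, 2 Monte-Carlo
passes, and learning rate 0.1 with a short linear warmup. The raised
learning rate is the package's deliberate re-scaling: a desk run spans
~400 steps rather than tens of thousands, and the clinical-scale 0.001
barely moves the loss in that budget. The ramp length (168 steps ≈ 40% of
training) mirrors the conventional 40-of-100-epochs schedule
proportionally. The fully supervised reference uses 100% labels and
$\lambda = 0$.

## Numerical choices and degenerate inputs

* Entropy uses natural log with $0 \log 0 := 0$; probability stacks are
  validated to sum to 1 per voxel within 1e-6.
* The 95th-percentile Hausdorff distance pools directed nearest-surface
  distances from both directions and takes the type-7 (linear
  interpolation) percentile; the printed one-directional Hausdorff formula
  in the source literature is treated as the usual typographical shorthand
  for the symmetric variant.
* A surface voxel is a mask voxel with at least one face-adjacent
  (6-connectivity) background neighbour; array borders count as background.
* Both-empty mask pairs score overlap 1 and distance 0; a single empty mask
  makes surface distances undefined (error, reported as `NA` per case).
* Sliding-window inference averages overlapping softmax maps (the mean of
  simplex points stays on the simplex) and breaks argmax ties toward
  background — the conservative choice for a target volume.
* Center crops use floor/ceil offsets (65 → 32 leaves 16 left, 17 right);
  volumes smaller than the window are padded symmetrically with background
  and predictions re-embedded through recorded offsets.
* Training aborts with the offending step number if any loss goes
  non-finite.

## Known limitations

A consequence of the phantom design worth stating plainly: the phantom
target is separable from its surroundings by voxel intensity alone
(soft tissue 0.5 vs slab 1.0 vs background 0, noise sd 0.1), so a handful
of labeled cases plus a few hundred convergent SGD steps already saturate
the task — supervised-only training at 10% labels reaches test Dice above
0.99. In that regime the consistency term has no headroom: semi-supervised
and supervised-only runs land within seed noise of each other
(differences on the order of 1e-3 with mixed sign), and shortening training
to leave the baseline label-limited still yields differences within seed
noise. The semi-supervised benefit the framework exists for requires data
where the labeled subset genuinely under-determines the decision boundary —
harder, less separable volumes than these phantoms provide. Phantom tests
therefore validate the machinery, not the clinical effect size.


* The engine is CPU-bound and desk-scale by design; clinical 400×400×48
  volumes with a 4-level, 16-channel backbone are expressible in the same
  configuration surface but not practical without GPU acceleration.
* Only Gaussian input noise is implemented for $\xi$.
* The comparison methods of the source literature other than the
  mean-teacher family (configuration subsets of this framework) are out of
  scope; published values for them ship as a benchmark table for
  relative-change reporting only.
* Uncertainty is Monte-Carlo-dropout entropy only; ensembles and evidential
  estimators are out of scope, as is calibration analysis.
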