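# uamt3d — uncertainty-aware mean-teacher semi-supervised 3D segmentation

`uamt3d` is an R implementation of semi-supervised volumetric segmentation
for settings where labeled volumes are scarce and unlabeled ones are
plentiful — the motivating case being delineation of the clinical target
volume (CTV) on cone-beam CT during breast radiotherapy, where expert
contours exist for only a small fraction of the daily CBCT volumes.

The framework trains a **student** 3D U-Net with residual blocks and
channel-then-spatial (CBAM) attention on the labeled volumes, while a
**teacher** network — an exponential moving average of the student,

    z'_t = 0.99 z'_{t-1} + 0.01 z_t,

supervises it on unlabeled volumes through a consistency loss. The teacher
is run N = 8 times with dropout and input noise (Monte-Carlo dropout); the
passes are averaged (M_c = (1/N) Σ_t p_t^c) and condensed into a voxelwise
entropy U = −Σ_c M_c log M_c, and only voxels with U below a ramping
threshold contribute:

    L = L_sup + λ(t) · Σ_i H(u_i < I) ||f_i − f'_i||² / Σ_i H(u_i < I),

with L_sup the mean of soft-Dice and cross-entropy losses and
λ(t) = λ_max · exp(−5(1 − t/T)²) the usual Gaussian ramp. Evaluation uses
DSC, Jaccard, the symmetric 95th-percentile Hausdorff distance and the
average surface distance, plus relative-change reporting between methods.

Because clinical CT/CBCT cohorts are not redistributable, the package ships
a **synthetic phantom generator**: paired clean (CT-like) and degraded
(CBCT-like: shading field, additive noise, lateral truncation) volumes of a
half-ellipsoidal target against a high-intensity slab, with ground-truth
masks and a labeled/unlabeled manifest. Every other component is exercised
end-to-end on these phantoms. The neural-network engine itself (direct 3D
convolution kernels, manual backpropagation, SGD, EMA) is part of the
package, written in R with C++ kernels.

## Worked example

```r
library(uamt3d)

# 1. a reproducible phantom dataset: 40 cases, 10% labeled
spec <- phantom_spec(volume_shape = c(64L, 64L, 16L), n_cases = 40L,
                     labeled_fraction = 0.10, seed = 1L)
manifest <- generate_dataset(spec, "phantoms")

# 2. mean-teacher training at desk scale
fit <- train(list(
  data    = list(manifest = manifest, window = c(64L, 64L, 16L)),
  model   = list(levels = 2L, base_channels = 2L, cam_reduction = 2L,
                 sam_kernel = 3L),
  loss    = list(lambda_max = 0.1, rampup_length = 168L),
  trainer = list(epochs = 15L, seed = 11L, lr = 0.1, warmup_steps = 28L,
                 mc_passes = 2L)))

# 3. evaluate the EMA teacher on the held-out test split
report <- evaluate(fit, manifest)
report
#> Segmentation metric report (mm)
#> # A tibble: 4 × 4
#>   metric     mean       sd     n
#>   <chr>     <dbl>    <dbl> <int>
#> 1 asd     0.00863 0.00390      8
#> 2 dsc     0.998   0.000807     8
#> 3 hd95    0       0            8
#> 4 jaccard 0.996   0.00161      8
```

Mean test DSC 0.998 with only 4 labeled cases: every module — phantom
generation, mean-teacher training with Monte-Carlo-dropout uncertainty
gating, EMA teacher inference, surface-distance evaluation — runs
end-to-end at desk scale. (These phantoms are intensity-separable enough
that supervised-only training also masters them; the vignette discusses
what the phantom experiments do and do not demonstrate about the
semi-supervised effect.) `autoplot(fit)` draws the loss curves,
`autoplot(report)` the per-case metrics, and `tidy()` / `glance()` return
both as tibbles. The published relative improvements between
mean-teacher-family methods can be recomputed from the shipped benchmark
table:

```r
relative_change_table(dplyr::filter(benchmark_metrics(),
                                    setting == "labeled_10pct"),
                      proposed = "res_cbam_uamt")
```

A command-line front end over the same functions (verbs `generate-data`,
`train`, `predict`, `uncertainty`, `evaluate`, `report`) is installed at
`system.file("cli", "uamt3d.R", package = "uamt3d")`.

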