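# dcac — depth-corrected convex active contour segmentation

`dcac` automatically segments 3D confocal microscopy stacks (multi-page
TIFF) into tissue and background when the images show the depth-dependent
intensity fall-off typical of imaging through thick, optically cleared
specimens — for example volumetric scans of embryonic hearts, where the
same myocardium is bright near the objective and several-fold dimmer tens
of slices deeper. Users are imaging labs that today trace such stacks by
hand and want a reproducible, automatic segmentation plus overlap (Dice)
and volumetry numbers.

## The model

The package minimizes a two-phase convex active contour energy in which
both phase intensities are modulated by a multiplicative depth bias
`γ^z` (`z` = slice index, `γ ∈ (0, 1]`):

    E(c1, c2, u) = Σ |∇u|
                 + λ Σ (Ĩ0 − c1 γ^z)² u
                 + λ Σ (Ĩ0 − c2 γ^z)² (1 − u),     u ∈ [0, 1]

where `Ĩ0` is the median-smoothed volume, `c1`, `c2` are the surface
intensities of the two phases and the first term is the isotropic discrete
total variation. `γ = 1` recovers the classic convex Chan–Vese model. The
energy is minimized by the Split Bregman method (closed-form `c1`/`c2`
updates, Gauss–Seidel sweeps on `u`, isotropic vector shrinkage, Bregman
accumulation) and the mask is `{u > α}` with `α = 0.5`. A calibration
helper estimates `γ` from the data by regressing log per-slice medians on
depth. See `vignette("depth-corrected-segmentation")` for the full model,
assumptions, and numerical choices.

## Worked example

Segment a synthetic volume that has exactly the structure the model
assumes — two chambers joined by a channel, 5:1 contrast, `γ = 0.95` depth
decay over 32 slices, Gaussian noise at 10% of the contrast:

```r
library(dcac)

ph <- generate_phantom(phantom_spec(shape = c(32, 64, 64),
                                    geometry = "two_chamber",
                                    c1 = 10, c2 = 2, gamma = 0.95,
                                    sigma = 0.8, seed = 1))
smoothed <- median_smooth(ph$image)          # 3x3 in-plane median

fit_gamma(ph$image, ph$truth)                # calibrate the decay
#> [1] 0.951

fit <- split_bregman_segment(smoothed, model_params(bias = depth_bias(0.95)))
fit
#> dcac_segmentation:
#>   c1 = 9.83808, c2 = 2.02803 (original intensity scale)
#>   33 outer iterations, converged
#>   final energy (normalized scale): 7793.39
#>   mask foreground: 17082 voxels (13.03%)

dice_coefficient(fit$mask, ph$truth)
#> [1] 0.9939
region_volume(fit$mask)                      # at 12.9 x 1.75 x 1.75 um voxels
#> [1] 0.000674846
```

The recovered surface intensities (9.84 and 2.03 against the true 10 and 2),
the Dice overlap of 0.994 with the ground truth, and the region volume in
mm³ are the quantities a study would report. Running the same data with
`depth_bias(1)` (no correction) drops the Dice overlap to 0.974 —
the deep ends of the chambers fall below the single global threshold.

## Command line

The same pipeline is scriptable via the installed `dcac` CLI
(`system.file("cli", "dcac", package = "dcac")`):

```sh
dcac phantom --shape 32,64,64 --geometry two_chamber --gamma 0.95 \
     --sigma 0.8 --seed 1 --out-image vol.tif --out-truth truth.tif
dcac segment --input vol.tif --output-mask mask.tif --gamma 0.95 \
     --report run.json
dcac evaluate --mask-a mask.tif --mask-b truth.tif --report eval.json
```

`segment` writes an 8-bit `{0, 255}` mask TIFF plus a JSON report
(`c1`, `c2`, iterations, convergence, mask volume); `evaluate` reports
Dice and per-mask volumes. Spacing defaults to 12.9 × 1.75 × 1.75 µm and
can be overridden with `--spacing`; flags can also come from a YAML file
via `--config` (explicit flags win).

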