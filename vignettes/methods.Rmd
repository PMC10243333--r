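---
title: "Methods: simulated acquisition-time reduction for pediatric renal planar scintigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated acquisition-time reduction for pediatric renal planar scintigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pediatric ^99m^Tc-DMSA renal scintigraphy acquires a posterior planar view
as a 10-minute dynamic series (ten 1-minute frames) that is summed into a
composite image for reading and for quantifying renal uptake. Shortening the
acquisition reduces the chance of motion artifacts in young children, but a
2-minute image carries roughly five times fewer counts and visibly more
Poisson noise. This package implements, end to end on synthetic data, a
workflow that restores full-acquisition image quality from 2-minute inputs
with convolutional denoising networks: phantom simulation, rigid frame
registration, frame-pair dataset construction, three residual architectures
(DnCNN, Win5RB, ResUnet) with training, image-quality metrics, and renal
uptake quantification with agreement analysis.

Clinical series of this kind are not publicly available, so every stage is
exercised on a seeded synthetic phantom whose count statistics are
calibrated to published clinical levels. All computation lives in package
functions; the numbered scripts under `analysis/` are thin drivers that run
the stages in order and write their tables under `results/analysis/`.

## The phantom and what it does (not) emulate

A case is a stack of `n_frames` (default 10) frames of independent Poisson
counts around a noiseless intensity map: an elliptical body with expected
`background_mean_counts_per_frame` (default 2) counts/pixel/frame, and two
elliptical kidneys whose *total* expected level is
`kidney_mean_counts_per_frame` (default 21) — i.e. kidney activity is
additive on top of the body background, which is what makes Gates-style
background subtraction exact in truth recovery tests. The default 21
counts/pixel/frame yields ~210 counts/pixel in the 10-minute sum, matching
the clinical average count level in kidney ROIs. A pixel belongs to an
ellipse if its (integer, 0-based) center lies inside it.

Ground-truth uptake is defined by the sensitivity model *counts = activity*:
the fraction of the dose in a kidney is its expected excess-over-background
counts over the full acquisition divided by the total dose count `D`. When
`D` is not supplied it is derived so the realized fractions total the
requested ones; the realized per-kidney fractions (recorded in the ground
truth) are what recovery tests compare against. Cohorts vary the kidney
count level (normal, sd 3 counts/pixel/frame, mirroring the across-patient
spread of clinical kidney counts) and the uptake fractions (uniform on
0.15–0.27, bracketing typical relative-function values around ~21%).

Deliberately not modelled: renal cortex structure and cortical defects,
scatter, septal penetration, depth-dependent collimator blur, and intra-frame
motion. An optional radial uptake profile (`kidney_profile_amp`) can
concentrate counts toward the kidney center — with it the clinical *maximum*
count level (~390) can also be approached — but the default is uniform so
that the intensity map reads back exactly at the stated mean. Consequently,
green tests here show the pipeline's correctness and its behavior under
Poisson statistics; they do not certify performance on anatomical structure
the phantom lacks.

A useful closed form: for a pixel with per-frame mean μ, the 2-frame sum x
is a subset of the 10-frame sum y, so y − x is the remaining 8-frame sum and
E[(y−x)²]/E[y²] = (64μ² + 8μ)/(100μ² + 10μ). Averaged over the phantom's
kidney (μ = 21) and background (μ = 2) pixels this puts the expected
short-time NMSE at ~64%, which is both what the synthetic cohort measures
and the level reported for clinical 2-minute images — the noise scaling is
count-statistics physics, not anatomy, which is why this number transfers
across domains.

## Rigid registration

Frames are registered to the first frame under a rotation + translation +
isotropic-scale model; the transform maps source to target coordinates with
rotation about the geometric image center, and resampling is bilinear with
zero fill outside the source domain. The similarity is the MSE of
mean-normalized images (normalization decouples the step size from the
count scale; the registered image is produced from the unnormalized
source).

Optimization is Adam on normalized parameters (rotation in radians,
translations divided by the image side, log-scale) with central-difference
gradients, 100 iterations, initial step 0.01 with a cosine decay to zero,
and the best-MSE iterate returned. The decay plus best-iterate selection is
what brings the final accuracy below half a pixel: with a constant step the
iterate orbits the optimum at step-size amplitude. Degenerate all-zero
images return the identity with a warning (the gradient is zero
everywhere). Registration is single-resolution and unregularized; motions
far larger than the defaults (|t| ≤ 5 px, |θ| ≤ 5°, scale 0.95–1.05 in the
recovery tests) may exceed its capture range.

## Dataset construction and standardization

All C(10, 2) = 45 unordered two-frame subsets of a case form its short-time
inputs (exact integer sums), each paired with the case's 10-frame sum.
Splitting is by case (never by pair) with a seeded permutation and
largest-remainder rounding, reproducing a 109/23/23 partition at n = 155.

Standardization uses the population (divide-by-N) standard deviation, and —
a deliberate choice where the protocol is underdetermined — the *input*
image's mean/sd standardize both the input and the target of a pair. The
roughly fivefold count amplification from 2-minute to 10-minute images then
becomes a learnable, invertible mapping: predictions are returned to the
count scale with the input's parameters and clipped at zero.

## Architectures and their numerical choices

*DnCNN*: Conv3×3+ReLU, fifteen Conv3×3+BN+ReLU units, final Conv3×3 — 17
convolutions predicting a residual that is subtracted from the input (the
canonical residual direction; the sign is configurable). *Win5RB*: four
Conv7×7+BN+ReLU layers plus a final Conv7×7+BN, with an additive
input-to-output skip; five convolutions, 31×31 receptive field. *ResUnet*:
pre-activation residual units ((BN→ReLU→Conv3×3)×2 with identity or
1×1-projection shortcut), three encoder levels (64/128/256 filters) with
stride-2 downsampling in each unit's first convolution, a 512-filter
bridge, nearest-neighbor upsampling + Conv3×3 and encoder-decoder
concatenation on the way up, and a final 1×1 convolution; level count and
widths are configurable and the input sides must be divisible by
2^levels.

Convolutions are zero-padded to preserve shape. Initialization is Kaiming
fan-in, except each network's final convolution, which is zero-initialized:
the two residual architectures then start exactly at the identity mapping
and ResUnet starts at a constant field, a standard stabilization for
restoration networks that materially shortens the training needed at desk
scale. Batch normalization uses batch statistics during training (momentum
0.1) and frozen running statistics at inference, so inference is
deterministic and translation-equivariant up to border effects. The network
engine (im2col/GEMM convolutions with hand-derived backward passes, and
Adam) is compiled C++ under `src/`; every backward pass is verified against
numeric differentiation in the test suite.

## Training protocol

Defaults follow the clinical-scale protocol: MSE loss in standardized
space, Adam, initial learning rate 1e-4, at most 50 epochs, batch size 8,
no learning-rate schedule, data reshuffled each epoch from the config seed,
and the returned checkpoint is the epoch with minimum validation loss (all
epochs are run; selection is post hoc). Validation loss is computed in
standardized space, the objective's own space; count-scale NMSE is reported
separately by the evaluation stage.

The desk-scale studies in the tests and `analysis/` scripts use 20 cases at
64×64 (12/4/4 case split, 15 training pairs per case), architecture widths
at 1/16 of the clinical defaults (DnCNN and Win5RB 4 filters; ResUnet
4/8/16 with a 32-filter bridge — preserving the relative capacities), batch
size 2, learning rate 2e-3, and 6 epochs. These sizes were chosen once as
the smallest configuration at which all three networks converge visibly
past the short-time baseline on a single CPU; the higher learning rate and
smaller batch compensate for the ~40-fold smaller number of gradient steps
relative to the clinical-scale protocol.

## Metrics

NMSE is 100·Σ(y−x)²/Σy² against the full-time reference y; PSNR is
20·log10(max(y)/√MSE), reported as +Inf for identical images and excluded
from aggregate means with a message. SSIM defaults to the literal
single-window global-statistics formula with c1 = (0.01·L)², c2 = (0.03·L)²
and L = max(y) per pair (mirroring the PSNR convention); a conventional
windowed variant (11×11 Gaussian, sd 1.5, border-renormalized, mean
aggregated) is available by flag since published values may stem from
either. Summary tables report mean (SD) and median (Q1, Q3) with
linear-interpolation quartiles. Joint voxel-wise histograms pool voxel
pairs over images and report Pearson r².

## Renal uptake

Uptake is (U − B)/D · (1/k) · 100 with U the kidney-ROI counts, B the
background ROI's per-pixel mean scaled to the kidney-ROI area, D the total
dose count, and k a depth-attenuation coefficient. Kidney depth follows the
Tauxe regression Y = (0.82W − 0.36H − 0.06A + 61.088)/10 cm; k defaults to
narrow-beam exponential attenuation exp(−μY) with μ = 0.153 cm⁻¹ for
^99m^Tc in soft tissue, both configurable — the exact rule used by clinical
workstation software is proprietary, so uptake comparisons across image
types are made with a common k (the phantom, which has no attenuating
tissue, uses k = 1 and the ground-truth D; short-time images use D scaled
by the acquisition-time ratio 2/10). Negative uptake (background exceeding
kidney counts) is preserved and flagged, never clipped. Agreement between
image types is summarized by Pearson r², Bland-Altman bias and 1.96·sd
limits of agreement.

## Known limitations

The phantom's uniform ellipses cannot probe cortical-defect conspicuity;
registration is single-resolution rigid only; the CPU-scale networks are
far narrower than their clinical-scale counterparts, so absolute metric
values from the desk-scale study are not comparable to values obtainable
with full-width networks on clinical data — only directions of effect
(denoisers beat the short-time input; the multi-scale ResUnet converges
best at matched budgets) are meaningful at this scale. Series export covers
a compressed CSV + JSON container and 16-bit PNG; no DICOM writer is
provided.
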