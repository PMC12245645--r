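---
title: "Automated photoacoustic oximetry at the superior sagittal sinus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated photoacoustic oximetry at the superior sagittal sinus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Perinatal hypoxic-ischemic brain injury calls for continuous, noninvasive
monitoring of cerebral oxygenation. Multiwavelength photoacoustic (PA)
imaging of the coronal plane of the head makes this possible: hemoglobin
absorbs pulsed near-infrared light and re-emits ultrasound, so the
per-wavelength acoustic amplitude of a pixel encodes the local blood
oxygenation. The superior sagittal sinus (SSS) — the large midline vein
that drains both hemispheres — integrates the brain's venous return, so
its oxygen saturation (`O2Satss`, percent) is a compact summary of global
oxygen supply.

`paoxi` implements the fully automatic two-step measurement:

1. **Localize** the SSS in the 21-channel PA stack with a U-Net trained
   to regress a Gaussian heatmap centred on the vessel.
2. **Measure** `O2Satss` by least-squares spectral unmixing of the window
   around the detected point, Gaussian smoothing, and averaging over a
   small rectangular ROI whose geometry is fixed by a grid search.

A Monte Carlo dropout (MCD) layer wraps the whole measurement and
attaches a confidence score to every reading.

## Data model

A sample couples a `spectral_image` (array `H x W x 21`, wavelengths
700–900 nm in 10 nm steps, pixel spacing 0.3 mm, y = depth) with subject
id, inspired-oxygen fraction FiO2, the blood-gas ground truth `O2Satss`,
and the expert point annotation of the SSS centre (0-based `(x, y)`).
Studies hold several subjects with unequal series lengths, because
subjects reach terminal hypoxia at different rates. Containers are
single versioned serialized files with a CSV annotation sidecar
(`save_dataset()`, `export_annotations()`).

## Spectral unmixing

The reference response table `S(lambda, s)` is the convex blend
`s/100 * HbO2 + (1 - s/100) * Hb` of embedded molar extinction endpoints
(700–900 nm, 10 nm steps; values rounded from published spectrophotometric
compilations — the calibrated response table of the original acquisition
system is not public, so the extinction blend is a documented stand-in).
The per-pixel estimate is the grid argmin over candidate saturations `s`
of the mean squared residual between the (attenuation-compensated)
measured spectrum and `S(., s)`:

- **Free amplitude (default).** Absolute PA amplitude depends on system
  gain and fluence, so the default fit projects out a per-pixel scale:
  `rss(s) = ||x||^2 - <x, S_s>^2 / ||S_s||^2`. This makes the estimate
  scale-invariant; `fit_scale = FALSE` reproduces the literal
  fixed-amplitude comparison.
- **Saturation grid.** 0–100 % in 1 % steps by default; the step is the
  quantization floor of every downstream error.
- **Compensation.** A `compensation_profile` holds per-wavelength gains
  calibrated at the typical skin-to-SSS depth. By default the unmixer
  scales the gains continuously with pixel depth
  (`gain^(depth/reference_depth)`), the exponential-fluence reading of a
  single-depth calibration; `per_depth = FALSE` applies the calibrated
  gains verbatim at every depth.
- Only the `50 x 80` px window around the SSS is unmixed; pixels outside
  the window, and all-zero spectra, are flagged invalid rather than
  conflated with a saturation of zero.

Smoothing of the O2Sat map is mask-normalized (blur of `value * valid`
divided by blur of `valid`), so invalid pixels never dilute the average.
Smoothing precedes ROI averaging, matching the role of the kernel size as
a grid-search dimension over the maps.

## ROI parameterization and grid search

The measurement ROI is a `d x c` px rectangle displaced `(b, a)` px from
the detected point, with pre-smoothing `sigma`. Membership uses inclusive
integer bounds; even edges bias toward the lower index (documented
convention). The exhaustive search covers displacements `[-5, 5]` px
(±1.5 mm), edges `[2, 20]` px (0.6–6 mm; the median fetal SSS diameter is
3.6 mm) and `sigma` in {1, 2, 3, 4}; among settings whose
hypoxia/normoxia classification (boundary exactly 30 %: `< 30` is
hypoxia) achieves sensitivity and specificity above 0.9, the MSE
minimizer wins. Ties break toward smaller area `c * d`, then smaller
`|a| + |b|`, then scan order — fully deterministic. Infeasible searches
(no setting meets the constraint, or only one class is present) return a
flagged result carrying the unconstrained optimum for diagnosis.
Summed-area tables make the full 175 000-combination search tractable in
seconds. The package's reference default is
`a = 1, b = -4, c = 4, d = 11, sigma = 1` — a laterally narrow,
lightly smoothed rectangle elongated along x, consistent with the SSS
presenting as a midline structure conforming to the brain curvature.

## The localizer

`SSSLocNet` is a standard four-level U-Net: per level two `3 x 3`
convolution + leaky-ReLU blocks (widths 8, 16, 32, 64; 64 at the deepest
level), `2 x 2` max-pooling down, nearest-neighbour upsampling with skip
concatenation up, and a linear `1 x 1` output head trained with MSE
against the `[0, 1]` heatmap target (no output sigmoid). Dropout
(p = 0.5) follows every pooling and every upsampling operation and can be
re-enabled at inference for MCD. Design choices the architecture sketch
leaves open, fixed here: feature widths double per level; upsampling is
nearest-neighbour (transposed convolution is an equivalent standard
choice); the nonlinearity is a leaky rectifier with slope 0.01 — with
plain ReLU the small blob target lets MSE training collapse the network
into an all-dead constant predictor from which no gradient escapes,
while the leaky slope keeps that basin escapable without changing the
converged solutions. Two further standard stabilizers make the shortened
schedules reliable across seeds: the `1 x 1` head is initialized near
zero (so the initial prediction already sits at the target's background
level, preventing an early loss blow-up), and per-step gradients are
clipped to a global L2 norm of 1.

The heatmap target is a delta at the annotated pixel, Gaussian-filtered
and min-max normalized to a peak of exactly 1. "Kernel size 3" is read
as sigma = 3 px (the window-size reading, a 3 x 3 box, differs only in
peak width; both normalize to 1, so downstream contracts are unchanged).
Coordinates come out of a heatmap as the argmax, ties broken toward the
smallest row-major index.

Training (`train_config()`) uses the full-budget recipe: batch 4, Adam,
learning rate 1e-4, MSE, 2000 epochs, with three augmentation families —
the rectification coefficient `k` drawn from `[0, 1]` per sample, paired
geometric transforms (horizontal flip, rotation <= 10 degrees, scale
0.9–1.1, shift <= 10 % of the frame, smooth grid distortion; magnitudes
are this package's choices, since only the families are prescribed), and,
with probability 0.5, a binned 5-wavelength channel subset (one draw from
each of 700–730, 740–770, 780–820, 830–860, 870–900 nm) with the other
16 channels zeroed. Inference always uses all 21 channels, rectified at
`k = 0.5` and jointly min-max normalized.

**Dynamic-range rectification.** Raw amplitudes span 1.75e3 to 2.3e6 AU
across acquisitions; clipping at `T = mean + k * sd` (population sd over
all 21 channels jointly) equalizes micro- and macro-vessels so the
"M"-shaped brain curvature, not raw amplitude, drives learning.

## Synthetic phantom studies

No public dataset exists, so `generate_study()` renders a controlled
stand-in with every label known by construction:

- **Anatomy.** An "M"-shaped cortical curvature (cosine arc, shoulders at
  ±28 % of the frame width) dented at a jittered midline; the SSS is a
  fully perfused disc (3.6 ± 0.6 mm diameter) at the dent at 20 ± 2 mm
  depth; ~14 minor cortical vessels trace the curve; a thin skin/skull
  band sits near the surface. Per-subject randomness covers curvature
  amplitude, midline position, SSS depth/diameter, vessel layout and a
  log-uniform global intensity scale spanning the observed AU range.
- **Physics.** Noiseless intensity is
  `scale * blood_frac * S(lambda, O2Sat) * exp(-mu(lambda) * depth)` with
  `mu` a linear ramp 0.08–0.14 mm^-1 over the band (the ex vivo
  attenuation calibration of the original system is not printed, so the
  ramp is configurable). `matched_compensation()` returns the gains that
  invert this fluence model exactly, which is what makes noiseless
  end-to-end recovery testable to the 1 % grid step.
- **Oxygenation protocol.** Per subject, FiO2 steps linearly from 1.0
  down to 0.08; `O2Satss` starts at 45–60 %, decays quadratically in the
  normalized FiO2 toward a 5 % floor with 3-percentage-point Gaussian
  reading noise, and the first (healthiest) sample is floored at > 30 %
  to satisfy the curation assumption. Under the default 10-subject
  series lengths (10, 5, 6, 9, 11, 9, 8, 11, 6, 9 — 84 samples) about
  70 % of samples are hypoxic.
- **Noise.** Additive Gaussian noise (2 % of the frame's peak intensity
  by default, clamped at zero). This emulates amplitude variability
  only: real PA speckle, skull aberration and probe-tilt appearance
  changes are *not* modelled, so green tests certify the algorithmic
  chain, not in vivo performance.

## Uncertainty

Every MCD run re-executes the full measurement. `model` mode re-samples
the dropout masks on the full 21-channel input (400 runs by default);
`data` mode keeps the weights fixed and feeds a fresh binned 5-channel
subset per run (400 by default), so the two variance sources stay
separable; `combined` mode crosses 20 mask draws with 20 subsets into
exactly 400 configurations. The per-sample uncertainty `epsilon` is the
population standard deviation (n divisor; the n-1 distinction is
negligible at hundreds of runs, and the zero-spread contract must hold
exactly) of the O2Satss readings in percentage points; the confidence
score is `beta = 1 - 2 * epsilon` with `epsilon` as a fraction, reported
as-is (possibly negative) and interpreted as very low confidence beyond
`epsilon = 0.5`. Dataset-level summaries average the per-sample spreads
(mSTD).

## Evaluation harness

`loso_folds()` holds out all samples of one subject per fold, so trained
networks are always tested on unseen anatomy; a runtime assertion
enforces zero subject leakage. Pooled predictions are scored by OLS of
prediction on ground truth (R-squared, slope, intercept; a constant
predictor scores R² = 0 by convention, zero-variance ground truth is
flagged undefined) and by hypoxia sensitivity/specificity at the strict
30 % boundary. `curation_check()` implements the protocol sanity rule
that a series must start normoxic. Four end-to-end CNN baselines are
included for comparison (M1: normalized 21-channel raw stack; M2:
windowed O2Sat map; M3: their 22-channel concatenation; M4: a 20 x 20
patch of M3 at the annotation), trained as a small LeNet-type regressor
(two conv+pool blocks and two dense layers; one of each for M4) with
batch 8, Adam, lr 1e-6, MSE, 10 000 epochs by default, and minibatches
drawn from the hypoxia/normoxia groups with equal probability to counter
the ~70/30 imbalance. M1–M3 skip rectification so the spectral ratios
the regression needs survive; their inputs are jointly min-max
normalized, and the O2Sat channel is scaled to `[0, 1]`.

## Desk-scale problem sizes

The full-budget training schedules (2000 and 10 000 epochs) target a GPU;
this package's networks run on a single CPU core (~0.13 s per U-Net
training step at 96 x 128 through the compiled GEMM-based kernels), so
the test suite and worked examples use reduced schedules chosen before
the suite was frozen:

- Localization acceptance: two leave-one-subject-out folds (held-out
  subjects S01 and S02) of the default 84-sample study at 96 x 128,
  30 epochs at learning rate 3e-3 — when the schedule shrinks ~70-fold,
  the Adam step size is raised to keep the total parameter displacement
  comparable — with augmentation disabled. Augmentation exists to fight
  overfitting over thousands of epochs on real data; inside a 30-epoch
  budget it simply prevents convergence, so the reduced runs omit it.
  The 4 px accuracy bound is the workflow's qualitative accuracy target
  and is not relaxed.
- Workflow comparison: the same two default-study folds (the trained
  localizers are shared between the two checks), two-step against the
  M1 full-frame regressor at an equal epoch budget, predictions pooled
  over both held-out subjects. The claim tested is the *ordering*, not
  absolute performance. Small-frame (48 x 64) multi-seed variants were
  evaluated first and proved numerically unstable — with ~11 training
  samples from two subjects, heatmap training converges or fails
  depending on the seed — so the comparison is made where training is
  reliable.
- Unmixing, ROI search, MCD and container tests are exact or
  deterministic and run at full fidelity.

## Numerical conventions and degenerate inputs

- Min-max normalization of a constant image returns all zeros.
- An all-zero spectrum unmixes to `NA` (flagged), never 0 %.
- An ROI without valid pixels is a flagged measurement failure; failed
  samples are excluded from regression and counted in the report.
- Gaussian kernels truncate at 3 sigma and are clamped to the frame.
- All randomness flows from one master seed through labelled
  sub-streams (phantom, training, MCD), so `simulate`/`train`/`evaluate`
  runs are bit-reproducible for a fixed seed; the RNG state of the
  caller is always restored.

## Known limitations

- The phantom's additive Gaussian noise does not reproduce PA speckle
  statistics, skull attenuation heterogeneity, or probe-tilt anatomy
  changes; field-of-view and probe-angle curation rules are therefore
  documented but not simulated.
- The extinction-blend reference table is a stand-in for the original
  system's calibrated response table.
- In vivo performance cannot be certified here: real acquisitions are
  not distributed with the package, so the harness computes its metrics
  on synthetic studies only.
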