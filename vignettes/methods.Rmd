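---
title: "Methods: quantitative CT features and recurrence modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative CT features and recurrence modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrecur)
```

`ctrecur` re-implements, on synthetic data, a quantitative-CT analysis of
resected lung adenocarcinoma: 2D tumor segmentation on one representative
axial slice, ten size/attenuation/shape/histogram features, slice-thickness
agreement, and logistic recurrence modelling. This vignette documents the
models, the numerical choices, and what the synthetic data do and do not
demonstrate.

## Image model and segmentation

A slice is a matrix of Hounsfield units with explicit row/column pixel
spacing (anisotropic spacing is carried everywhere; the phantom default is
isotropic 0.7 mm, a typical thoracic-CT in-plane resolution — the source
protocol does not state the field of view, so this is a package choice).
Coordinates are (row, col) pixel centers; every millimetre quantity passes
through the spacing. HU are floating point internally; integer storage
conventions live at the file boundary, because phantom smoothing and noise
produce non-integer HU.

Segmentation is seeded region growing: the ROI is the 8-connected component,
containing the seed, of pixels whose HU lies in a fixed absolute interval.
The reference procedure says only "attenuation-based region growing", so the
growing criterion is deliberately the simplest reproducible reading — a fixed
interval around the seed-neighbourhood median (3×3 median ± 350 HU by
default), with the half-width exposed as a parameter rather than presented as
recovered truth. 8-connectivity (the wand-tool family default) is fixed
because connectivity changes results; 4-connectivity fragments thin
lobulations. Growth widening is monotone: enlarging the interval can never
shrink the mask, and the result is invariant to the seed's position within
its component (both properties are tested).

Interior holes are *not* auto-filled: air bronchograms are excluded from the
reference ROIs, so hole filling would change the measured distribution. The
"manual" separation of vessels, bronchus and chest wall is represented by
scripted exclusion masks: subtraction followed by restriction to the
seed-side connected component, with the exclusion history kept on the mask.
The thin/thick ROI pair is compared by Dice overlap (`juxtapose_check`),
mirroring the reference workflow in which mismatched ROIs were re-delineated;
0.8 is the default tolerance, a conventional good-overlap threshold.

## The ten features

Area is pixel count × pixel area. The perimeter is the traced outer boundary
(Moore-neighbour tracing; interior hole boundaries excluded) with
corner-corrected chain weights — 0.980 per straight step, 1.406 per diagonal
step, −0.091 per direction change. Raw pixel-edge counting overestimates a
circle's circumference by ~27%; with these weights a radius-50 px disk
measures within 1% of 2πr (tested at 3%). An axis-aligned n×n square measures
≈ 0.98·4(n−1)·s, i.e. the tracer is calibrated for smooth boundaries, not
axis-aligned rectangles; the documented square tolerance is a few corner
weights. Masks under 3 pixels fall back to exposed-edge counting.

The Feret diameter is the maximum pairwise distance between boundary pixel
centers, computed on the convex hull (tested equal to the brute-force
all-pairs maximum). The ellipse fit is the second-moment (inertia) ellipse
rescaled so its area equals the ROI area. The rescaling is what makes
`roundness × aspect_ratio = 1` an exact identity — and that identity is the
only reading consistent with the published worked examples (aspect ratio 1.15
with roundness 0.87 ≈ 1/1.15). Degenerate (collinear) masks are an error.

Histogram statistics use population (n) normalization — the plain expectation
in the defining formulas, not the n−1/n−2 bias-corrected sample versions —
and kurtosis is excess (the −3 is part of the definition). The published
formula text swaps the labels of μ and σ ("σ = mean, μ = standard
deviation"); the implementation uses the universal convention, the only
reading that makes the moments dimensionless. Entropy is computed over
fixed-width 1-HU bins spanning the observed ROI range, in bits (log₂): the
reference software's exact binning is unrecoverable, but unit bins with base
2 match the printed magnitudes (≈ 6.7–7.1 bits for solid tumors); both bin
width and base are parameters. A uniform 128-bin histogram gives exactly
7 bits. Zero-variance samples raise a "degenerate distribution" error rather
than returning NaN — on noiseless phantoms, add a noise floor before asking
for skewness.

One printed-arithmetic caveat: the recurred-tumor worked example prints
perimeter 95.50 mm, area 409.96 mm² and circularity 0.57, but
4π·409.96/95.50² = 0.5649, which rounds to 0.56; interval arithmetic on the
printed inputs bounds the value to [0.5648, 0.5650], so the printed 0.57 can
only descend from unrounded internal values. The package reports what it
computes. The non-recurred example (0.51) and the roundness identity (0.87)
reproduce exactly.

## Phantoms

`generate_nodule_pair()` renders a disk, ellipse or lobulated nodule
(default tissue values: solid 40 HU, ground-glass −450 HU, lung background
−800 HU) and returns two reconstructions of the same scene: the *sharp* slice
(1-mm tag) adds Gaussian noise of SD 40 HU; the *smooth* slice (5-mm tag)
is Gaussian-blurred (σ = 1.5 px) and then given noise of SD 15 HU. The blur
stands in for the thick-slice/standard-kernel point-spread behaviour — only
the sharp-vs-smooth agreement behaviour matters to the analysis, so no
projection/reconstruction physics is simulated. The reference protocol states
no noise magnitudes; the defaults were chosen once as visually plausible
thoracic-CT noise and are spec parameters, not claims about the scanner.
Lobulated shapes are star-convex boundaries with Fourier harmonics k = 3–6 of
controllable total amplitude, rasterized by pixel centers with the base
radius iterated until the pixel count is within one pixel of the target area.
Part-solid nodules render a concentric solid core covering `1 − ggo_fraction`
of the area; raising the fraction strictly lowers the noiseless mean
attenuation. An optional air hole (−1000 HU) emulates an air bronchogram and
is excluded from the ground-truth mask.

All generators are pure functions of (spec, seed).

## Cohort simulation

`simulate_cohort()` draws per-patient 1-mm features: area lognormal
(meanlog 5.325, sdlog 0.818 — mean ≈ 287 mm², SD ≈ 280 mm², matching the
pooled observed moments), attenuation normal (−154 ± 225 HU, truncated to
[−1000, 150]), circularity Beta (mean 0.475, SD 0.15), aspect ratio
1 + Gamma (mean 1.46, SD 0.34). Geometry is kept internally consistent:
perimeter = √(4πA/c), major axis from the area-preserving ellipse, Feret
diameter = 1.10 × major (lobulated outlines exceed their ellipse axis
slightly; 1.10 reproduces the observed diameter means). Recurrence is
Bernoulli with log-odds `b0 + ln(1.002)·area + ln(1.005)·attenuation` — the
published multivariable odds ratios — and the intercept is calibrated
deterministically (quadrature over the feature marginals, independent of the
user's seed) so the expected prevalence equals 25/194, the source cohort's
rate; that keeps simulated power realistic.

The 5-mm feature set comes from `perturb_for_thickness()`: additive Gaussian
noise with variance from the identity `ICC = var_between/(var_between +
var_noise)`, per feature, using the source agreement profile (0.98 diameter …
0.53 kurtosis) as targets. Because the derived column carries all of the
added noise while the input column carries none, the estimated pair-ICC sits
slightly above the target (`vb/(vb + vn/2)`); at the high targets that matter
for the acceptance checks the shift is under 0.01, and it is the price of
leaving the 1-mm features untouched. Follow-up times are tied to the
recurrence indicator (event times uniform on the observed 0.5–2.6-year
recurrence range, censoring on 0.6–3.5 years) so the Cox cross-check sees the
same events the logistic model sees, as in the source data; the Cox routine's
own parameter-recovery tests simulate proper proportional-hazards data
separately.

What the simulation does *not* emulate: correlation between area and
attenuation (independent by construction), inter-scanner variability (the
source deliberately used one scanner), measurement error in the clinical
covariates, and any nonlinearity in the recurrence model. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes —
not that real tumors satisfy that structure.

## Statistics

The ICC is the two-way random-effects, absolute-agreement, single-measure
coefficient, computed from the ANOVA mean squares, with the
Satterthwaite-approximate F confidence interval and an F-test of ICC = 0.
The source names only "ICC"; absolute agreement is the defensible variant for
comparing measurement systems (a consistency ICC would forgive a constant
thickness offset), and under consistency definitions third-decimal shifts are
expected. The implementation is cross-checked in the tests against values
frozen from an independent reference implementation. Band labels use the
printed κ-style boundaries on the value rounded to two decimals (0.80 →
substantial, 0.81 → excellent).

Logistic regression is ordinary maximum likelihood (`glm`). Odds ratios are
reported on explicit per-predictor scales (per mm², per HU, per 10 HU …)
because published reports mix scales between text and tables; the scale is a
column of the result. Stepwise selection uses the conventional
forward-conditional defaults — score-test entry at p < 0.05,
likelihood-ratio removal at p > 0.10 — and records the full entry/removal
trace; ties and cycles terminate deterministically (a just-entered term that
immediately qualifies for removal ends the search). With five pure-noise
candidates these thresholds admit a noise term in roughly 1 − 0.95⁵ ≈ 23% of
datasets — that is the procedure's nominal behaviour, not a defect, and the
tests assert it at that rate. Confidence intervals for ORs and HRs are Wald
(matching the reporting style of the reference tables). The C-index is the
in-sample ROC AUC with a DeLong interval (`pROC`), flagged as apparent — the
source had no validation cohort, and neither does the simulation. Group
comparisons use Student's t (equal variances), Pearson chi-square without
continuity correction, or Fisher's exact test when an expected cell is
below 5; the method can be forced, since the reference applied chi-square to
one table a strict expected-count rule would send to Fisher. The Cox
cross-check fits a univariate proportional-hazards model with Efron ties.

## Problem sizes and determinism

The test suite exercises phantoms up to 128×128 pixels (where region growing
is verified against an exhaustive flood-fill oracle and the Feret diameter
against brute-force all-pairs), cohorts of 194–4,000 patients for the
statistical operations, 100 replicate cohorts of n = 2,000 for odds-ratio
coverage, and 200 replicates of n = 500 for coefficient recovery — sizes at
which the Monte-Carlo noise is far below the asserted tolerances while the
full suite runs in well under a minute. Every stochastic component takes an
explicit integer seed, RNG state is restored after each generator call, and a
fixed pipeline seed yields byte-identical CSV outputs.

## Known limitations

Single representative axial slice only (no 3D segmentation or volumetrics,
as in the source analysis); no DICOM networking or enhanced multi-frame CT —
image I/O is a plain raster + JSON-sidecar dialect with HU rescale applied at
the boundary; no gray-level co-occurrence/run-length texture families (the
feature set is first-order + shape by design); no automatic vessel/bronchus
detection (exclusions are scripted); PET maxSUV is consumed as a plain cohort
column, never computed. The perimeter tracer's corner weights are tuned for
smooth boundaries and under-measure axis-aligned rectangles by ~2%, which is
immaterial for tumor-like shapes but visible in unit tests on squares.
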