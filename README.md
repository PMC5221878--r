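# ctrecur

Quantitative CT features and recurrence modelling for surgically resected
lung adenocarcinoma.

After curative resection of early-stage (I–II) lung adenocarcinoma, roughly
one patient in eight recurs, and the decision between adjuvant therapy and
watchful follow-up would benefit from objective preoperative markers.
`ctrecur` implements, as a tested and reusable pipeline, a quantitative
analysis of the preoperative CT: semi-automatic 2D tumor segmentation on one
representative axial slice, extraction of ten first-order and shape features,
agreement analysis between thin (1-mm, sharp kernel) and thick (5-mm,
standard kernel) reconstructions, and logistic recurrence modelling. Because
no patient images are redistributed, the package ships a phantom generator
and a cohort simulator that reproduce the statistical structure the analysis
assumes, so the entire pipeline runs — and is tested — on synthetic data.

It is aimed at radiology/radiomics researchers who want a transparent,
scriptable reference implementation of this class of analysis rather than an
interactive workstation tool.

## What it computes

**Segmentation.** Tumors are delineated by seeded, attenuation-based region
growing under the lung window (width 1500 HU, level −700 HU): starting from a
click point, the ROI expands over 8-connected pixels whose HU lies in a fixed
interval (by default the seed-neighbourhood median ± 350 HU). Vessels,
bronchus, chest wall and air bronchograms are removed with scripted exclusion
masks; the 1-mm and 5-mm ROIs are juxtaposed (Dice overlap) and flagged for
re-delineation when they disagree.

**Features.** For a mask *M* on a slice with pixel spacing *s*:

- area `A = |M|·s²` (mm²), perimeter `P` from corner-corrected boundary
  tracing (mm), Feret diameter = max pairwise boundary distance (mm),
  mean attenuation = mean HU in *M*;
- circularity `4πA/P²`; an area-preserving second-moment ellipse gives
  aspect ratio `major/minor` and roundness `4A/(π·major²)` (so
  roundness × aspect ratio ≡ 1);
- histogram statistics of the HU sample *X*: skewness `E[((X−μ)/σ)³]`,
  excess kurtosis `E[((X−μ)/σ)⁴] − 3` (population normalization), and
  entropy `−Σ p(xᵢ) log₂ p(xᵢ)` over 1-HU bins.

**Statistics.** Thickness agreement via the two-way random-effects,
absolute-agreement, single-measure ICC with κ-style interpretation bands;
univariate logistic regression of recurrence on each feature (odds ratios on
explicit reporting scales); multivariable selection by the forward-conditional
method (score-test entry at p < 0.05, likelihood-ratio removal at p > 0.10);
apparent C-index (ROC AUC with DeLong CI) of the final model; and a
univariate Cox cross-check (Efron ties).

## Worked example

```r
library(ctrecur)

# a 410 mm^2 lobulated nodule, paired sharp/smooth reconstructions
spec <- nodule_spec(shape = "lobulated", target_area_mm2 = 410, seed = 42)
pair <- generate_nodule_pair(spec)

bounds <- grow_bounds_from_seed(pair$sharp, pair$truth$seed)
roi <- region_grow(pair$sharp, pair$truth$seed, bounds[1], bounds[2])
dice_coefficient(roi, pair$truth)
#> [1] 1
extract_features(pair$sharp, roi)
#>   diameter_mm perimeter_mm area_mm2 mean_attenuation_hu circularity
#> 1        24.5         72.1      410                38.5        0.99
#>   aspect_ratio roundness skewness kurtosis entropy_bits
#> 1         1.01     0.994   0.0396    0.145         7.13

# a simulated 194-patient cohort with the assumed recurrence structure
co <- simulate_cohort(cohort_spec(n = 194, seed = 42))
sum(co$recurrence)
#> [1] 26

icc_agreement(co$area_mm2_1mm, co$area_mm2_5mm)$table
#>       term estimate    lo    hi         p
#> 1 ICC(A,1)    0.995 0.994 0.996 7.72e-198

forward_conditional_logistic(
  co, paste0(c("diameter_mm", "perimeter_mm", "area_mm2",
               "mean_attenuation_hu"), "_1mm"))
#> <model_result: stepwise_logistic>
#>                     term estimate    lo    hi        p
#>  mean_attenuation_hu_1mm    1.005 1.002 1.007 0.000435
#>             area_mm2_1mm    1.002 1.001 1.004 0.003110
```

The segmentation recovers the phantom exactly (Dice 1); the extracted area
matches the construction (410 mm²) and the near-circular shape shows
circularity ≈ 1. In the simulated cohort the stepwise model selects tumor
area (OR 1.002 per mm²) and mean attenuation (OR 1.005 per HU) — the two
generating signals — with odds ratios at their generating values.

The full pipeline (phantoms → segmentation → features → cohort → statistics,
with CSV outputs, a run log and a markdown report) runs from one config:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "ctrecur"))
```

or from the shell via the thin wrapper
`inst/scripts/ctrecur <phantom|cohort|segment|features|stats|run> [options]`.

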