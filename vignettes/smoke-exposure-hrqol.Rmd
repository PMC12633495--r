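---
title: "Wildfire-smoke exposure attribution and HRQoL linkage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wildfire-smoke exposure attribution and HRQoL linkage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokelink)
```

## The problem

Populations far downwind of large wildfires experience *episodic* smoke
exposure: for days to weeks, transported plumes overlap a region and
near-ground PM2.5 and black carbon (BC) rise above their seasonal baseline.
Linking such episodes to health-related quality-of-life (HRQoL) instruments
administered at cohort visits requires four steps, each implemented here as
an independently testable module: classifying smoke days from plume
geometry, attributing the smoke share of daily concentrations, summarising
exposure over recall-relevant windows before each visit, and fitting
covariate-adjusted linear models. A synthetic-data generator with complete
ground truth stands in for the restricted cohort and air-quality rasters.

## Smoke-day geometry

A calendar day is a smoke day when the union of its plume polygons overlaps
the study area by at least 1 km^2 (inclusive: exactly 1.0 km^2 is a smoke
day). Decisions worth stating explicitly:

* **Equal-area projection.** Areas in km^2 are computed in a spherical
  Lambert azimuthal equal-area projection centred on the study area. Over a
  region ~200 km across, the spherical-vs-ellipsoidal area error is orders
  of magnitude below the 1 km^2 threshold; a test checks that areas are
  stable to 0.5% under plume-sized displacements of the projection centre.
* **Per-day union before intersection.** "Area overlapped" is a coverage
  quantity; two plumes covering the same ground must not count twice. Union
  semantics are asserted by test. (Whether multiple same-day plumes should
  be unioned is a design decision of this package, not something the
  workflow we emulate states.)
* **The overlap engine.** Intersection areas come from an exact scanline
  union-area routine (strips cut at every vertex and pairwise edge
  crossing; inside a strip the slice structure is combinatorially constant,
  so midpoint evaluation integrates exactly), with
  `area(A ∩ S) = area(A) + area(S) − area(A ∪ S)`. Rings are validated
  (finite, ≥3 distinct vertices, nonzero area); self-touching rings are
  interpreted by the even-odd rule; degenerate rings are hard errors naming
  the feature. Tests compare against an independent Monte-Carlo
  point-in-polygon oracle. Classification applies an absolute slack of
  1e-6 km^2 so floating-point round-off cannot turn the inclusive boundary
  exclusive.
* **Default catchment.** A schematic convex outline of the four-county
  greater-Albuquerque region, rescaled in the equal-area plane to exactly
  18,719 km^2. The outline's vertices are not county borders; location,
  extent, and area are what the exposure computations use.

## Deviation-method attribution

Smoke PM2.5 (and identically BC) on a smoke day is the observed value minus
the median of non-smoke-day values from the same *calendar month* pooled
over three years (year before, index year, year after), truncated at zero.
Choices:

* "Same month" is calendrical (all Junes in y−1..y+1), not a rolling ±30-day
  window.
* Smoke days never enter the baseline pool, including month-mates in
  neighbouring years.
* The even-count median is the mean of the middle pair.
* **Empty pools and series boundaries.** If a month has no qualifying
  non-smoke day across all three years, the default fallback widens to the
  adjacent calendar months (`fallback = "widen"`); `"missing"` propagates NA
  instead. At the first/last year of a series the missing neighbour year is
  simply not pooled, with a warning. Neither situation is prescribed by the
  source workflow; both are exposed as configuration.
* **Analysis level.** Region-level attribution operates on the area-mean
  daily series of the member cells; per-cell attribution is also provided
  and agrees with it exactly on spatially constant fields (tested).

A property worth knowing: at the *single-cell* daily level the deviation
estimate is upward-biased, because the lognormal baseline is right-skewed
(mean above median) and the zero-truncation clips only the left tail.
Averaging cells into a regional series symmetrises the baseline noise, and
there the median bias is within 5% of the planted elevation at the default
noise level (tested). Users attributing individual noisy cells should expect
the cell-level bias.

## Exposure windows

For each visit and window length X ∈ {7, 15, 30, 60} days the pipeline
reports the mean smoke PM2.5, mean smoke BC, mean total PM2.5 (all divided
by X, so non-smoke days contribute zeros), the smoke-day count, and the
cumulative overlapped area (summed day by day without de-duplication, so it
can exceed the study-area size — the reported 60-day means in this
literature exceed the catchment area, which forces summation semantics).
The window is the X days *ending the day before* the visit: the instruments
ask about the past four weeks before questionnaire filling, and whether the
visit day itself counts is not stated anywhere we emulate — exclusion is
this package's convention, asserted in tests so any change is visible.

Residence-level metrics assign each visit the nearest grid-cell centre
(ties broken by lowest cell id, equivalent to the containing cell on a
regular grid); region-level metrics use the area-mean series.

## HRQoL scoring

* **SGRQ** scores are weighted endorsement sums scaled to 0–100 (higher =
  worse). The official item weights are licensed and are *not* shipped;
  they are user configuration (YAML or data frame). Missing items are
  renormalised out of numerator and denominator up to a 25% cap (then NA).
* **SF-36** uses the standard public-domain 0–100 item recoding
  (reverse-keyed items flipped) and per-domain means of answered items
  (higher = better).
* **Two-factor reduction.** The eight domains are reduced to physical and
  mental factor scores by a *confirmatory* two-correlated-factor model with
  fixed simple structure (physical: physical functioning, role physical,
  bodily pain, general health; mental: mental health, role emotional,
  social functioning, vitality), estimated by maximum likelihood on the
  covariance of the standardized domains (so reported loadings are
  standardized). Factor scores use the regression (Thomson) method and are
  standardized to mean 0, SD 1 on the fitting sample. The estimator details
  (ML discrepancy minimised by BFGS, uniquenesses parameterised on the log
  scale and floored at 0.001 with a Heywood warning, factor correlation via
  tanh, iteration cap 1000) are this package's defaults: the workflow we
  emulate names confirmatory analysis and a US-norm structure but not an
  estimator or score-extraction method. Parameter recovery (±0.05 on
  loadings at n = 5000) and a brute-force multivariate-normal likelihood
  check are in the test suite.

## Association models

OLS per outcome × exposure metric × window, with adjustment sets fixed by
outcome family: SGRQ models adjust age, sex, ethnicity, BMI, education,
current smoking, pack-years and airway obstruction (FEV1/FVC ≤ 70%); SF-36
models swap airway obstruction for baseline comorbidity. Covariates are
0/1 indicators or untransformed continuous values — the simplest coding
consistent with the emulated workflow, which states none. Reporting units
(per 1 µg/m³, per 0.05 µg/m³, per day, per IQR) are pure
reparameterizations: the per-0.05 coefficient is exactly 0.05 times the
per-unit coefficient (tested to machine precision). Nominal P values only;
evidence is weighed across metrics and windows rather than through a
multiplicity correction, matching the emulated analysis. Interactions add a
modifier × exposure product (candidate modifiers: sex, education, current
smoking, woodsmoke history, chronic mucous hypersecretion, ethnicity),
flagged as meaningful at P < 0.1, and are conventionally run on 7-day
metrics. The winter-exclusion sensitivity drops December–February visits by
default; "winter" is configurable because it is nowhere defined.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions the validation suite runs
under:

* **Calendar.** Monthly smoke probabilities near zero in winter and peaking
  in June–July, chosen so a 2006–2017 daily record (4383 days) yields ≈474
  smoke days — the smoke/non-smoke split of the record we calibrate to.
  Each smoke day receives 1–2 star-shaped plume polygons verified to
  overlap the study area; a few non-smoke days carry far-field plumes
  disjoint from it, so the classifier is exercised from both sides.
* **Fields.** Per cell and day, concentration = lognormal baseline
  (multiplicative noise, sdlog 0.5, month-stationary median) + additive
  exponential day-level smoke elevation on smoke days only. Baselines are
  calibrated so the *means* match the published contrast: non-smoke mean
  PM2.5 4.14 µg/m³ (median 4.14/exp(0.125)), smoke elevation mean
  2.41 = 6.55 − 4.14; BC baseline mean 0.16 with elevation ratio
  0.09/2.41. Multiplicative baseline + additive elevation is deliberate:
  it keeps the planted quantity in exactly the units the deviation method
  estimates. The within-region spatial variance of the smoke elevation is
  not pinned down by any published summary, so it is a parameter
  (`smoke_spatial_sd`, default 0 — spatially uniform elevation).
* **Grid.** `n_cells` (default 25) 1 × 1 km cells on a coarse lattice
  spanning the catchment's bounding box — a spatial sample rather than the
  ~19k-cell full tiling, sufficient because generated fields have no
  spatial correlation (a stated non-goal).
* **Cohort.** One baseline visit per subject (n = 747), covariates drawn
  independently from the published marginals (mean age 56.9 y, 51.27%
  female, 24.77% Hispanic, 64.12% some college, 59.84% current smokers,
  mean 41.4 pack-years, 32.26% woodsmoke-exposed, 30.66% CMH). Airway
  obstruction (40%) and comorbidity (50%) prevalences are not published for
  this cohort; the defaults are realistic for a ≥10-pack-year smoker cohort
  and were fixed once. Visit months are down-weighted in winter so ≈9% of
  visits fall in December–February, matching the scale of the winter
  sensitivity analysis (66 of 747).
* **Outcomes.** Each outcome is intercept + covariate effects + planted
  β × exposure + Gaussian noise. The default planted betas are the
  published 7-day smoke-PM2.5 coefficients (SGRQ activity 5.51, impacts
  3.27, symptom 6.15, total 4.68 points per µg/m³; SF-36 mental −0.172,
  physical −0.214 SD per µg/m³). SGRQ noise (SD 15 points) and intercept
  (40) were chosen so the linear model rarely leaves [0, 100]: scores are
  clamped, clamps are counted (warning above 5%), and pre-clamp values are
  kept as ground truth, because visible clamping would attenuate
  planted-coefficient recovery. SF-36 factor outcomes are generated
  directly on the standardized factor scale with unit variance by
  construction and are not re-standardized per sample — planting a
  coefficient and then regressing on *estimated* factor scores would
  attenuate it by the factor-score reliability, which is not the property
  under test; CFA scoring is validated separately.

What the generator does **not** emulate: spatial correlation of pollutant
fields, realistic plume morphology, repeated visits, time-activity or
indoor-infiltration differences, and correlated covariates. Passing tests
therefore demonstrate that the *pipeline's arithmetic and inference* are
correct under known conditions — not that any particular real-world
association is causal or correctly sized.

## Validation design and problem sizes

* Deviation-method output is compared exactly against a naive double-loop
  enumeration on 50-cell × 3-year instances.
* Planted-coefficient recovery holds one 12-year exposure record fixed and
  replicates the cohort 500 times (n = 747 per replicate; covariates,
  visit dates and noise redrawn): the mean estimate is required to sit
  within 2 Monte-Carlo standard errors of the planted value, with 95% CI
  coverage in [0.93, 0.97]. Note the 2-MC-SE criterion is self-calibrating:
  an exactly unbiased estimator fails it with ~5% probability per outcome,
  so a marginal failure under a new seed is an expected event, not evidence
  of bias.
* Calibration targets (smoke/non-smoke mean PM2.5 and smoke-day BC) are
  checked on a single simulated record at the 474/3909-day scale within 3
  Monte-Carlo SEs.
* `scripts/acceptance.R --seed N --out f.json` re-runs all of the above
  from the installed package and writes the resulting numbers as JSON.

## Known limitations

* The overlap engine's pairwise-crossing enumeration is O(E²) per day —
  ample for daily plume sets, not for continental-scale vector processing.
* Bowtie (zero-signed-area) rings are rejected rather than repaired; there
  is no buffering.
* Cell-level deviation estimates carry the skewness bias discussed above.
* The CFA assumes complete domains per fitted row (listwise deletion) and
  a fixed simple structure; cross-loadings are deliberately out of scope.
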