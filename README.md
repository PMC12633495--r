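# smokelink

Wildfire smoke ("WFS") reaching a population as aged, long-range plumes is an
episodic exposure: for days to weeks, satellite-visible smoke overlaps a
region and near-ground PM2.5 and black carbon (BC) rise above their seasonal
baseline. `smokelink` implements, as a reusable and fully tested R pipeline,
the exposure-assessment and health-linkage workflow used to study such
episodes in smoker cohorts:

1. **Smoke-day detection** — a calendar day is a *smoke day* when the union
   of that day's satellite-detected plume polygons overlaps the study area by
   at least 1 km² (boundary inclusive). All area arithmetic runs in an
   equal-area projection; the default study area is a four-county catchment
   of 18,719 km².
2. **Deviation-method attribution** — smoke PM2.5 (and BC) on a smoke day is
   the observed concentration minus the median of non-smoke-day
   concentrations from the same calendar month pooled over three years (the
   year before, the index year, the year after), truncated at zero:

   `smoke_c(d) = max(0, c(d) − median{ c(d') : d' non-smoke, month(d') = month(d), |year(d') − year(d)| ≤ 1 })`

3. **Windowed exposure metrics** — for each subject visit, means of smoke
   PM2.5, smoke BC and total PM2.5, the smoke-day count, and the cumulative
   plume-overlap area over the 7, 15, 30 and 60 days before questionnaire
   completion (visit day excluded; means divide by the window length, so
   non-smoke days contribute zeros).
4. **HRQoL scoring** — SGRQ (activity/impacts/symptom/total, 0–100, higher =
   worse; weights supplied by the user, never shipped) and SF-36 (eight
   0–100 domains, higher = better) reduced to physical and mental factor
   scores by a fixed simple-structure two-correlated-factor model fitted by
   maximum likelihood, with regression-method factor scores.
5. **Association models** — OLS of each outcome on each exposure metric with
   the conventional adjustment set (age, sex, ethnicity, BMI, education,
   current smoking, pack-years, plus airway obstruction for SGRQ or
   comorbidity for SF-36), per-unit / per-0.05 µg/m³ / per-day / per-IQR
   reporting scales, exposure-by-modifier interactions (meaningful at
   P < 0.1), and a winter-exclusion sensitivity filter.

Because the underlying cohort and air-quality rasters are restricted, the
package ships a **synthetic-data generator** with complete ground truth
(plume calendars, lognormal baseline fields with additive exponential smoke
elevations, a 747-subject smoker cohort with realistic covariate marginals,
and outcomes generated from a linear model with planted exposure effects).
Every pipeline stage is validated against that ground truth or an
independent oracle.

## Worked example

```r
library(smokelink)
library(dplyr)

cfg   <- sim_config(seed = 1, n_subjects = 747)
study <- simulate_study(cfg)   # calendar -> fields -> attribution -> windows -> outcomes

cal <- study$calendar$smoke_days
sprintf("smoke days: %d of %d", sum(cal$is_smoke), nrow(cal))
#> "smoke days: 474 of 4383"

s <- study$series
sprintf("mean total PM2.5: %.2f (smoke) vs %.2f (non-smoke) ug/m3",
        mean(s$pm25[s$is_smoke]), mean(s$pm25[!s$is_smoke]))
#> "mean total PM2.5: 6.63 (smoke) vs 4.14 (non-smoke) ug/m3"

run_full_grid(study$rows) |>
  filter(metric == "mean_smoke_pm25",
         outcome %in% c("sgrq_total", "sf36_physical"), window %in% c(7, 15)) |>
  select(outcome, window, beta, ci_lo, ci_hi, p)
#>         outcome window   beta  ci_lo   ci_hi        p
#> 1    sgrq_total      7  4.513  2.717  6.3091 1.00e-06
#> 2    sgrq_total     15  4.264  1.894  6.6354 4.40e-04
#> 3 sf36_physical      7 -0.252 -0.369 -0.1340 3.02e-05
#> 4 sf36_physical     15 -0.252 -0.407 -0.0975 1.43e-03
```

Read: one extra µg/m³ of 7-day mean smoke PM2.5 is associated with a 4.5-point
higher (worse) SGRQ total score — this single synthetic cohort was generated
with a true effect of 4.68, so the fit recovers the planted value within its
confidence interval — and with a 0.25-SD lower (worse) physical-health factor
score. A single cohort is noisy; `simulate_recovery()` replicates the cohort
hundreds of times over a fixed exposure record to check bias and CI coverage
systematically.

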