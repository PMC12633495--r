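# Synthetic study generator: plume calendars, gridded pollutant fields, a
# smoker cohort, and HRQoL outcomes with planted effects and full ground
# truth. The defaults ARE the study conditions the pipeline is validated
# against: a 2006-2017 daily record over an arid south-western catchment with
# summer-concentrated smoke, calibrated so that smoke/non-smoke day mean
# concentrations match the published Albuquerque summary (PM2.5 6.55 vs 4.14
# ug/m3, BC 0.25 vs 0.16 ug/m3 over 474/3909 days), and a 747-subject
# baseline cohort with the published covariate marginals.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study. Baseline concentrations are
#' lognormal (multiplicative noise, month-stationary median); smoke adds an
#' exponentially distributed daily elevation on smoke days only, so the
#' deviation method's subtract-the-median logic estimates exactly the planted
#' additive quantity.
#'
#' @param seed integer master seed; fixed seed implies byte-identical output
#'   at every stage.
#' @param n_subjects cohort size (default 747).
#' @param n_cells number of simulated 1x1 km grid cells, laid out as a coarse
#'   lattice spanning the study-area bounding box (default 25).
#' @param date_range character/Date length-2; must span at least three
#'   calendar years so the attribution baseline (year before / year after)
#'   exists.
#' @param smoke_season_prob length-12 per-day smoke probability by calendar
#'   month (Jan..Dec), each in `[0,1]`. Defaults give ~474 smoke days over
#'   2006-2017 with near-zero winter occurrence.
#' @param baseline_pm25_median,baseline_bc_median lognormal baseline medians,
#'   ug/m3. Defaults are calibrated so baseline *means* equal the published
#'   non-smoke-day means (4.14 and 0.16 ug/m3) given `baseline_sdlog`.
#' @param baseline_sdlog lognormal sigma of the per-cell multiplicative
#'   baseline noise (default 0.5).
#' @param smoke_elevation_pm25_mean mean of the exponential day-level smoke
#'   PM2.5 elevation, ug/m3 (default 2.41 = 6.55 - 4.14).
#' @param bc_pm25_smoke_ratio BC:PM2.5 ratio of the smoke elevation (default
#'   0.09/2.41, reproducing the published BC contrast).
#' @param smoke_spatial_sd sd (ug/m3) of per-cell deviation of the smoke
#'   elevation around the day-level value; the within-region spatial
#'   variability of smoke is not pinned down by published summaries, so it is
#'   a parameter (default 0: spatially uniform elevation).
#' @param noise_sd_sgrq,noise_sd_factor Gaussian outcome noise, SGRQ points
#'   and factor-score SD units.
#' @param planted_betas tibble (`outcome`, `metric`, `window`, `beta`): true
#'   exposure effects per stated unit; defaults plant the published 7-day
#'   smoke-PM2.5 coefficients.
#' @param covariate_effects list of named coefficient vectors (`sgrq`,
#'   `factor`) for the outcome data-generating model.
#' @param covariate_dists named list of cohort marginals (see
#'   [gen_cohort()]); defaults reproduce the published cohort table.
#' @param visit_month_weights length-12 relative sampling weights for visit
#'   months (winter down-weighted so roughly 9% of visits fall in Dec-Feb).
#' @param clamp_warn_rate warn when more than this fraction of generated
#'   scores had to be clamped into `[0, 100]` (default 0.05).
#' @return a `sim_config` list (validated).
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 747L,
                       n_cells = 25L,
                       date_range = c("2006-01-01", "2017-12-31"),
                       smoke_season_prob = c(0.005, 0.005, 0.03, 0.08, 0.18,
                                             0.35, 0.30, 0.18, 0.10, 0.05,
                                             0.02, 0.005),
                       baseline_pm25_median = 4.14 / exp(0.5^2 / 2),
                       baseline_bc_median = 0.16 / exp(0.5^2 / 2),
                       baseline_sdlog = 0.5,
                       smoke_elevation_pm25_mean = 2.41,
                       bc_pm25_smoke_ratio = 0.09 / 2.41,
                       smoke_spatial_sd = 0,
                       noise_sd_sgrq = 15,
                       noise_sd_factor = 0.95,
                       planted_betas = default_planted_betas(),
                       covariate_effects = default_covariate_effects(),
                       covariate_dists = default_covariate_dists(),
                       visit_month_weights = c(0.3, 0.3, 1, 1, 1, 1, 1, 1, 1,
                                               1, 1, 0.3),
                       clamp_warn_rate = 0.05) {
  dr <- as.Date(date_range)
  if (any(is.na(dr)) || length(dr) != 2 || dr[2] < dr[1]) {
    stop("sim_config(): invalid date_range")
  }
  if (length(smoke_season_prob) != 12 ||
      any(smoke_season_prob < 0 | smoke_season_prob > 1)) {
    stop("sim_config(): smoke_season_prob must be 12 probabilities in [0,1]")
  }
  if (baseline_pm25_median <= 0 || baseline_bc_median <= 0) {
    stop("sim_config(): baseline medians must be positive")
  }
  if (smoke_elevation_pm25_mean < 0 || bc_pm25_smoke_ratio < 0) {
    stop("sim_config(): smoke elevations must be non-negative")
  }
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         n_cells = as.integer(n_cells), date_range = dr,
         smoke_season_prob = smoke_season_prob,
         baseline_pm25_median = baseline_pm25_median,
         baseline_bc_median = baseline_bc_median,
         baseline_sdlog = baseline_sdlog,
         smoke_elevation_pm25_mean = smoke_elevation_pm25_mean,
         bc_pm25_smoke_ratio = bc_pm25_smoke_ratio,
         smoke_spatial_sd = smoke_spatial_sd,
         noise_sd_sgrq = noise_sd_sgrq,
         noise_sd_factor = noise_sd_factor,
         planted_betas = planted_betas,
         covariate_effects = covariate_effects,
         covariate_dists = covariate_dists,
         visit_month_weights = visit_month_weights,
         clamp_warn_rate = clamp_warn_rate),
    class = "sim_config"
  )
}

#' Default planted exposure effects
#'
#' The published 7-day smoke-PM2.5 coefficients, used as ground truth for
#' parameter-recovery validation: SGRQ activity 5.51, impacts 3.27, symptom
#' 6.15, total 4.68 points per 1 ug/m3; SF-36 mental -0.172 and physical
#' -0.214 factor-score SD per 1 ug/m3.
#'
#' @return tibble with columns `outcome`, `metric`, `window`, `beta`.
#' @export
default_planted_betas <- function() {
  tibble::tibble(
    outcome = c("sgrq_activity", "sgrq_impacts", "sgrq_symptom", "sgrq_total",
                "sf36_mental", "sf36_physical"),
    metric = "mean_smoke_pm25",
    window = 7L,
    beta = c(5.51, 3.27, 6.15, 4.68, -0.172, -0.214)
  )
}

#' @rdname default_planted_betas
#' @export
default_covariate_effects <- function() {
  list(
    sgrq = c(intercept = 40, age = 0.10, female = -2, hispanic = 1,
             bmi = 0.15, some_college = -3, current_smoker = 4,
             pack_years = 0.08, airway_obstruction = 8, comorbidity = 0),
    factor = c(intercept = 0, age = -0.008, female = 0.05, hispanic = 0,
               bmi = -0.01, some_college = 0.08, current_smoker = -0.10,
               pack_years = -0.002, airway_obstruction = 0,
               comorbidity = -0.35)
  )
}

#' @rdname default_planted_betas
#' @export
default_covariate_dists <- function() {
  list(
    age = list(mean = 56.87, sd = 9.08, min = 40, max = 75),
    female = 0.5127, bmi = list(mean = 28.78, sd = 6.35, min = 15, max = 55),
    hispanic = 0.2477, some_college = 0.6412, current_smoker = 0.5984,
    pack_years = list(mean = 41.41, sd = 20.96, min = 10),
    woodsmoke_ever = 0.3226, cmh = 0.3066, pulmonary_disease = 0.1339,
    airway_obstruction = 0.40, comorbidity = 0.50
  )
}

check_baseline_span <- function(dr) {
  if (as.numeric(dr[2] - dr[1]) < 2 * 365) {
    stop(paste("date_range must span at least three calendar years:",
               "the deviation-method baseline pools non-smoke days from the",
               "same month in the year before and the year after"))
  }
}

# random star-shaped plume ring around a centre, radii in km
random_plume_ring <- function(center, r_lo = 15, r_hi = 120) {
  k <- 10L
  ang <- sort(runif(k, 0, 2 * pi))
  r <- runif(1, r_lo, r_hi) * runif(k, 0.6, 1.4)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

sample_points_in_area <- function(n, area) {
  bb <- apply(area$ring, 2, range)
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- runif(m, bb[1, 1], bb[2, 1])
    y <- runif(m, bb[1, 2], bb[2, 2])
    keep <- point_in_ring(x, y, area$ring)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a smoke-day calendar and matching plume polygons
#'
#' Draws per-day smoke occurrence from the monthly probabilities, then builds
#' 1-2 plume polygons per smoke day guaranteed to overlap the study area by at
#' least `threshold_km2` (verified geometrically, redrawn otherwise). A small
#' fraction of non-smoke days carry a far-field plume disjoint from the study
#' area, so the classifier is exercised on both label sources.
#'
#' @param config a [sim_config()].
#' @param area a [study_area()]; default [study_area_default()].
#' @param threshold_km2 smoke-day detection threshold (km^2).
#' @param seed RNG seed for this stage (default derived from the config).
#' @param require_baseline_span enforce the three-calendar-year minimum span
#'   needed by the attribution baseline (default TRUE).
#' @return list with `smoke_days` (tibble `date`, `is_smoke`, `overlap_km2`)
#'   and `plumes` (tibble `date`, `plume_id`, `ring`).
#' @export
gen_smoke_calendar <- function(config, area = study_area_default(),
                               threshold_km2 = 1,
                               seed = config$seed + 101L,
                               require_baseline_span = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (require_baseline_span) check_baseline_span(config$date_range)
  set.seed(seed)
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  mon <- as.integer(format(dates, "%m"))
  is_smoke <- runif(length(dates)) < config$smoke_season_prob[mon]
  ctr <- colMeans(area$ring)
  overlap <- numeric(length(dates))
  rows <- list()
  for (i in which(is_smoke)) {
    repeat {
      np <- 1L + stats::rpois(1, 0.5)
      ctrs <- sample_points_in_area(np, area)
      rings <- lapply(seq_len(np), function(j) random_plume_ring(ctrs[j, ]))
      ov <- overlap_area(rings, area)
      if (ov >= threshold_km2) break
    }
    overlap[i] <- ov
    rows[[length(rows) + 1L]] <-
      tibble::tibble(date = dates[i], plume_id = seq_along(rings),
                     ring = rings)
  }
  # occasional far-field plumes on non-smoke days (disjoint by construction)
  far <- which(!is_smoke & runif(length(dates)) < 0.03)
  for (i in far) {
    off <- ctr + c(800, 800) + runif(2, -50, 50)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(date = dates[i], plume_id = 1L,
                     ring = list(random_plume_ring(off)))
  }
  plumes <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(date = as.Date(character()), plume_id = integer(),
                   ring = list())
  plumes <- dplyr::arrange(plumes, .data$date, .data$plume_id)
  list(
    smoke_days = tibble::tibble(date = dates, is_smoke = is_smoke,
                                overlap_km2 = overlap),
    plumes = plumes
  )
}

#' Lay out the simulated pollutant grid cells
#'
#' `n_cells` 1x1 km cells whose centres form a coarse regular lattice spanning
#' the study-area bounding box (the full catchment at 1 km resolution would be
#' ~19k cells; a spatial sample is enough because the generated fields have no
#' spatial correlation). Cell ids increase row-major from the south-west.
#'
#' @param config a [sim_config()].
#' @param area a [study_area()].
#' @return tibble `cell_id`, `x_km`, `y_km`, `lon`, `lat`.
#' @export
gen_grid_cells <- function(config, area = study_area_default()) {
  bb <- apply(area$ring, 2, range)
  k <- ceiling(sqrt(config$n_cells))
  gx <- seq(bb[1, 1], bb[2, 1], length.out = k)
  gy <- seq(bb[1, 2], bb[2, 2], length.out = k)
  pts <- expand.grid(x_km = gx, y_km = gy)[seq_len(config$n_cells), ]
  ll <- if (!is.null(area$center)) {
    laea_inverse(as.matrix(pts), area$center)
  } else {
    cbind(lon = NA_real_, lat = NA_real_)[rep(1, nrow(pts)), , drop = FALSE]
  }
  tibble::tibble(cell_id = seq_len(nrow(pts)), x_km = pts$x_km,
                 y_km = pts$y_km, lon = ll[, 1], lat = ll[, 2])
}

#' Inverse of [laea_project()]
#'
#' @param xy two-column matrix of planar km coordinates.
#' @param center projection centre (lon, lat) in degrees.
#' @return two-column matrix (lon, lat) in degrees.
#' @export
laea_inverse <- function(xy, center) {
  xy <- as.matrix(xy)
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  rho <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  cc <- 2 * asin(pmin(1, rho / (2 * EARTH_RADIUS_KM)))
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(cc) * sin(phi0) +
                       xy[, 2] * sin(cc) * cos(phi0) / pmax(rho, 1e-12)))
  lam <- lam0 + atan2(xy[, 1] * sin(cc),
                      rho * cos(phi0) * cos(cc) -
                        xy[, 2] * sin(phi0) * sin(cc))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Generate daily pollutant fields with known smoke contributions
#'
#' Per cell and day: concentration = lognormal baseline draw (median equal to
#' the configured baseline median) + additive smoke elevation on smoke days
#' only. The day-level elevation is exponential with the configured mean,
#' shared across cells up to optional Gaussian spatial jitter (truncated at
#' zero); BC elevation is the PM2.5 elevation times the smoke BC:PM2.5 ratio.
#' The exact planted terms are returned as ground truth.
#'
#' @param config a [sim_config()].
#' @param smoke_days smoke-day table from [gen_smoke_calendar()] (or
#'   [detect_smoke_days()]).
#' @param cells cell layout from [gen_grid_cells()].
#' @param seed RNG seed for this stage.
#' @return list with `grid` (tibble `cell_id`, `x_km`, `y_km`, `date`, `pm25`,
#'   `bc`) and `ground_truth` (same keys plus `baseline_pm25`,
#'   `smoke_pm25_true`, `baseline_bc`, `smoke_bc_true`); identically ordered,
#'   and `pm25 == baseline_pm25 + smoke_pm25_true` exactly.
#' @export
gen_pollutant_fields <- function(config, smoke_days,
                                 cells = gen_grid_cells(config),
                                 seed = config$seed + 202L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  dates <- smoke_days$date
  nd <- length(dates); nc <- nrow(cells)
  elev_day <- ifelse(smoke_days$is_smoke,
                     rexp(nd, rate = 1 / max(config$smoke_elevation_pm25_mean,
                                             1e-12)), 0)
  if (config$smoke_elevation_pm25_mean == 0) elev_day <- rep(0, nd)
  df <- tidyr::expand_grid(cell_id = cells$cell_id, date = dates)
  df <- dplyr::left_join(df, cells[, c("cell_id", "x_km", "y_km")],
                         by = "cell_id")
  n <- nrow(df)
  elev <- elev_day[match(df$date, dates)]
  if (config$smoke_spatial_sd > 0) {
    elev <- pmax(0, elev + ifelse(elev > 0,
                                  rnorm(n, 0, config$smoke_spatial_sd), 0))
  }
  base_pm <- rlnorm(n, meanlog = log(config$baseline_pm25_median),
                    sdlog = config$baseline_sdlog)
  base_bc <- rlnorm(n, meanlog = log(config$baseline_bc_median),
                    sdlog = config$baseline_sdlog)
  elev_bc <- elev * config$bc_pm25_smoke_ratio
  grid <- tibble::tibble(cell_id = df$cell_id, x_km = df$x_km,
                         y_km = df$y_km, date = df$date,
                         pm25 = base_pm + elev, bc = base_bc + elev_bc)
  gt <- tibble::tibble(cell_id = df$cell_id, date = df$date,
                       baseline_pm25 = base_pm, smoke_pm25_true = elev,
                       baseline_bc = base_bc, smoke_bc_true = elev_bc)
  list(grid = grid, ground_truth = gt)
}

truncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a baseline smoker cohort
#'
#' One baseline visit per subject. Covariates are drawn independently from the
#' configured marginals (defaults reproduce the published cohort: mean age
#' 56.9, 51.27% female, 24.77% Hispanic, 64.12% some college, 59.84% current
#' smokers, mean 41.4 pack-years, 32.26% ever woodsmoke-exposed, 30.66% CMH,
#' 13.39% pulmonary disease). Visit dates are sampled over the simulated range
#' (leaving room for the longest exposure window) with winter months
#' down-weighted; residences are uniform inside the study area.
#'
#' @param config a [sim_config()].
#' @param area a [study_area()].
#' @param max_window longest exposure window that must fit before each visit
#'   (days; default 60).
#' @param seed RNG seed for this stage.
#' @return tibble, one row per subject, with `subject_id`, `visit_date`,
#'   residence `x_km`/`y_km`, and 0/1-coded or continuous covariates.
#' @export
gen_cohort <- function(config, area = study_area_default(), max_window = 60,
                       seed = config$seed + 303L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  if (n == 0) stop("gen_cohort(): n_subjects is zero; nothing to simulate")
  n_adj <- 8L  # largest adjustment set used downstream
  if (n <= n_adj) {
    stop(sprintf(paste("gen_cohort(): n_subjects = %d is not larger than the",
                       "%d adjustment covariates; downstream models would be",
                       "unidentifiable"), n, n_adj))
  }
  set.seed(seed)
  d <- config$covariate_dists
  eligible <- seq(config$date_range[1] + max_window, config$date_range[2],
                  by = "day")
  w <- config$visit_month_weights[as.integer(format(eligible, "%m"))]
  visit_date <- sample(eligible, n, replace = TRUE, prob = w)
  res <- sample_points_in_area(n, area)
  pk <- d$pack_years
  pack <- pmax(pk$min, rnorm(n, pk$mean, pk$sd))
  tibble::tibble(
    subject_id = seq_len(n),
    visit_date = visit_date,
    x_km = res[, 1], y_km = res[, 2],
    age = truncnorm1(n, d$age$mean, d$age$sd, d$age$min, d$age$max),
    female = rbinom(n, 1, d$female),
    bmi = truncnorm1(n, d$bmi$mean, d$bmi$sd, d$bmi$min, d$bmi$max),
    hispanic = rbinom(n, 1, d$hispanic),
    some_college = rbinom(n, 1, d$some_college),
    current_smoker = rbinom(n, 1, d$current_smoker),
    pack_years = pack,
    woodsmoke_ever = rbinom(n, 1, d$woodsmoke_ever),
    cmh = rbinom(n, 1, d$cmh),
    pulmonary_disease = rbinom(n, 1, d$pulmonary_disease),
    airway_obstruction = rbinom(n, 1, d$airway_obstruction),
    comorbidity = rbinom(n, 1, d$comorbidity)
  )
}

#' Generate HRQoL outcomes with planted exposure effects
#'
#' Linear data-generating model per outcome: intercept + covariate effects
#' (age/BMI/pack-years centred at cohort-typical values) + planted beta x
#' exposure metric + Gaussian noise. SGRQ scores are clamped to `[0, 100]`
#' (clamp counts reported; pre-clamp values kept as ground truth); SF-36
#' factor outcomes are generated directly on the standardized factor-score
#' scale (unit variance by construction) and are not clamped.
#'
#' @param visits cohort tibble from [gen_cohort()].
#' @param exposures long exposure table (one row per subject x window) from
#'   [build_analysis_table()]; must contain every metric/window referenced by
#'   `config$planted_betas`.
#' @param config a [sim_config()].
#' @param seed RNG seed for this stage.
#' @return tibble `subject_id` + six outcome columns (`sgrq_activity`,
#'   `sgrq_impacts`, `sgrq_symptom`, `sgrq_total`, `sf36_mental`,
#'   `sf36_physical`), with attributes `clamped` (named counts) and
#'   `pre_clamp` (ground-truth tibble).
#' @export
gen_outcomes <- function(visits, exposures, config,
                         seed = config$seed + 404L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pb <- config$planted_betas
  for (i in seq_len(nrow(pb))) {
    sub <- exposures[exposures$window == pb$window[i], , drop = FALSE]
    if (nrow(sub) == 0 || !pb$metric[i] %in% names(sub)) {
      stop(sprintf(paste("gen_outcomes(): planted beta for %s references",
                         "exposure metric '%s' in window %d, absent from the",
                         "supplied exposures"),
                   pb$outcome[i], pb$metric[i], pb$window[i]))
    }
  }
  n <- nrow(visits)
  ce <- config$covariate_effects
  lin_cov <- function(eff) {
    eff[["intercept"]] +
      eff[["age"]] * (visits$age - 57) +
      eff[["female"]] * visits$female +
      eff[["hispanic"]] * visits$hispanic +
      eff[["bmi"]] * (visits$bmi - 29) +
      eff[["some_college"]] * visits$some_college +
      eff[["current_smoker"]] * visits$current_smoker +
      eff[["pack_years"]] * (visits$pack_years - 41) +
      eff[["airway_obstruction"]] * visits$airway_obstruction +
      eff[["comorbidity"]] * visits$comorbidity
  }
  exposure_for <- function(metric, window) {
    sub <- exposures[exposures$window == window, , drop = FALSE]
    sub[[metric]][match(visits$subject_id, sub$subject_id)]
  }
  out <- tibble::tibble(subject_id = visits$subject_id)
  pre <- tibble::tibble(subject_id = visits$subject_id)
  clamped <- integer(0)
  for (oc in c("sgrq_activity", "sgrq_impacts", "sgrq_symptom", "sgrq_total",
               "sf36_mental", "sf36_physical")) {
    is_sgrq <- startsWith(oc, "sgrq")
    eff <- if (is_sgrq) ce$sgrq else ce$factor
    y <- lin_cov(eff)
    rows <- which(pb$outcome == oc)
    for (i in rows) {
      y <- y + pb$beta[i] * exposure_for(pb$metric[i], pb$window[i])
    }
    sdn <- if (is_sgrq) config$noise_sd_sgrq else config$noise_sd_factor
    y <- y + rnorm(n, 0, sdn)
    pre[[oc]] <- y
    if (is_sgrq) {
      yc <- pmin(100, pmax(0, y))
      clamped[oc] <- sum(yc != y)
      y <- yc
    }
    out[[oc]] <- y
  }
  rate <- sum(clamped) / (length(clamped) * n)
  if (length(clamped) && rate > config$clamp_warn_rate) {
    warning(sprintf("gen_outcomes(): %.1f%% of SGRQ scores clamped to [0,100]",
                    100 * rate))
  }
  attr(out, "clamped") <- clamped
  attr(out, "pre_clamp") <- pre
  out
}
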