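test_that("identical configuration yields byte-identical output at every stage", {
  cfg <- tiny_config(seed = 5)
  a <- gen_smoke_calendar(cfg)
  b <- gen_smoke_calendar(cfg)
  expect_identical(a$smoke_days, b$smoke_days)
  expect_identical(a$plumes, b$plumes)
  fa <- gen_pollutant_fields(cfg, a$smoke_days)
  fb <- gen_pollutant_fields(cfg, b$smoke_days)
  expect_identical(fa$grid, fb$grid)
  expect_identical(gen_cohort(cfg), gen_cohort(cfg))
})

test_that("degenerate smoke probabilities give all-or-nothing calendars", {
  cfg0 <- tiny_config(smoke_season_prob = rep(0, 12))
  cal0 <- gen_smoke_calendar(cfg0)
  expect_equal(sum(cal0$smoke_days$is_smoke), 0)
  cfg1 <- sim_config(seed = 2, date_range = c("2011-07-01", "2011-07-31"),
                     smoke_season_prob = c(rep(0, 6), 1, rep(0, 5)))
  cal1 <- gen_smoke_calendar(cfg1, require_baseline_span = FALSE)
  expect_true(all(cal1$smoke_days$is_smoke))
  expect_equal(nrow(cal1$smoke_days), 31)
})

test_that("a date range too short for the attribution baseline is rejected", {
  cfg <- sim_config(date_range = c("2011-01-01", "2012-06-30"))
  expect_error(gen_smoke_calendar(cfg), "year before and the year after")
})

test_that("smoke-day fraction matches the configured marginal probability", {
  cfg <- tiny_config(seed = 9)
  cal <- gen_smoke_calendar(cfg)
  dates <- cal$smoke_days$date
  p <- cfg$smoke_season_prob[as.integer(format(dates, "%m"))]
  expected <- mean(p)
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(cal$smoke_days$is_smoke) - expected), 3 * se)
  # generated plumes reproduce the calendar through the classifier
  sd2 <- detect_smoke_days(cal$plumes, study_area_default(),
                           min(dates), max(dates))
  expect_equal(sd2$is_smoke, cal$smoke_days$is_smoke)
})

test_that("total concentration decomposes exactly into baseline plus planted smoke term", {
  cfg <- tiny_config(seed = 3)
  cal <- gen_smoke_calendar(cfg)
  fld <- gen_pollutant_fields(cfg, cal$smoke_days)
  gt <- fld$ground_truth
  expect_equal(fld$grid$pm25, gt$baseline_pm25 + gt$smoke_pm25_true)
  expect_equal(fld$grid$bc, gt$baseline_bc + gt$smoke_bc_true)
  # planted term is zero exactly on non-smoke days
  ns <- !cal$smoke_days$is_smoke[match(gt$date, cal$smoke_days$date)]
  expect_true(all(gt$smoke_pm25_true[ns] == 0))
  expect_true(all(fld$grid$pm25 >= 0 & fld$grid$bc >= 0))
})

test_that("zero planted elevation leaves smoke and non-smoke days identical in law", {
  cfg <- tiny_config(seed = 4, smoke_elevation_pm25_mean = 0)
  cal <- gen_smoke_calendar(cfg)
  fld <- gen_pollutant_fields(cfg, cal$smoke_days)
  expect_true(all(fld$ground_truth$smoke_pm25_true == 0))
  sm <- cal$smoke_days$is_smoke[match(fld$grid$date, cal$smoke_days$date)]
  ks <- suppressWarnings(stats::ks.test(fld$grid$pm25[sm],
                                        fld$grid$pm25[!sm]))
  expect_gt(ks$p.value, 1e-3)
})

test_that("vanishing noise makes smoke-day values exactly baseline median plus elevation", {
  cfg <- tiny_config(seed = 6, baseline_sdlog = 0)
  cal <- gen_smoke_calendar(cfg)
  fld <- gen_pollutant_fields(cfg, cal$smoke_days)
  gt <- fld$ground_truth
  expect_equal(gt$baseline_pm25, rep(cfg$baseline_pm25_median, nrow(gt)))
  sm_rows <- gt$smoke_pm25_true > 0
  expect_equal(fld$grid$pm25[sm_rows],
               cfg$baseline_pm25_median + gt$smoke_pm25_true[sm_rows])
})

test_that("cohort marginals, bounds, and identifiability guards hold", {
  cfg <- sim_config(seed = 8)
  coh <- gen_cohort(cfg)
  expect_equal(nrow(coh), 747)
  p <- 0.5127
  expect_lt(abs(mean(coh$female) - p), 3 * sqrt(p * (1 - p) / 747))
  expect_true(all(coh$age >= 40 & coh$age <= 75))
  expect_true(all(coh$pack_years >= 10))
  sa <- study_area_default()
  expect_true(all(point_in_ring(coh$x_km, coh$y_km, sa$ring)))
  expect_error(gen_cohort(sim_config(n_subjects = 0)), "nothing to simulate")
  expect_error(gen_cohort(sim_config(n_subjects = 8)), "unidentifiable")
})

test_that("outcome generation is exact in the noiseless limit and rejects unknown exposures", {
  cfg <- tiny_config(seed = 2, noise_sd_sgrq = 0, noise_sd_factor = 0,
                     covariate_effects = list(
                       sgrq = c(intercept = 50, age = 0, female = 0,
                                hispanic = 0, bmi = 0, some_college = 0,
                                current_smoker = 0, pack_years = 0,
                                airway_obstruction = 0, comorbidity = 0),
                       factor = c(intercept = 0, age = 0, female = 0,
                                  hispanic = 0, bmi = 0, some_college = 0,
                                  current_smoker = 0, pack_years = 0,
                                  airway_obstruction = 0, comorbidity = 0)))
  st <- simulate_study(cfg, windows = 7L)
  tab <- st$rows
  w7 <- tab[tab$window == 7, ]
  expect_equal(w7$sgrq_total, 50 + 4.68 * w7$mean_smoke_pm25)
  expect_equal(w7$sf36_physical, -0.214 * w7$mean_smoke_pm25)
  # planted beta that points at a metric absent from the exposures
  cfg_bad <- tiny_config(planted_betas = tibble::tibble(
    outcome = "sgrq_total", metric = "mean_smoke_pm25", window = 15L,
    beta = 1))
  expect_error(gen_outcomes(st$cohort, w7, cfg_bad), "window 15")
})

test_that("score clamping is counted and loud when excessive", {
  cfg <- tiny_config(
    seed = 2, noise_sd_sgrq = 60,
    covariate_effects = list(
      sgrq = c(intercept = 0, age = 0, female = 0, hispanic = 0, bmi = 0,
               some_college = 0, current_smoker = 0, pack_years = 0,
               airway_obstruction = 0, comorbidity = 0),
      factor = default_covariate_effects()$factor))
  st_parts <- local({
    cal <- gen_smoke_calendar(cfg)
    fld <- gen_pollutant_fields(cfg, cal$smoke_days)
    reg <- regional_series(fld$grid, smoke_days = cal$smoke_days)
    att <- suppressWarnings(
      attribute_series(reg[, c("date", "pm25", "bc")], cal$smoke_days))
    att$cell_id <- 1L
    g1 <- reg[, c("date", "pm25", "bc")]
    g1$cell_id <- 1L
    coh <- gen_cohort(cfg)
    list(coh = coh,
         tab = build_analysis_table(coh, att, g1, cal$smoke_days,
                                    windows = 7L))
  })
  expect_warning(
    out <- gen_outcomes(st_parts$coh, st_parts$tab, cfg),
    "clamped"
  )
  cl <- attr(out, "clamped")
  expect_true(sum(cl) > 0)
  pre <- attr(out, "pre_clamp")
  expect_equal(sum(cl),
               sum(pre$sgrq_total < 0 | pre$sgrq_total > 100) +
                 sum(pre$sgrq_activity < 0 | pre$sgrq_activity > 100) +
                 sum(pre$sgrq_impacts < 0 | pre$sgrq_impacts > 100) +
                 sum(pre$sgrq_symptom < 0 | pre$sgrq_symptom > 100))
  expect_true(all(out$sgrq_total >= 0 & out$sgrq_total <= 100))
})
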