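test_that("adjusted OLS equals the closed-form normal-equation solution", {
  rows <- make_assoc_rows(n = 200, beta = 3, seed = 41)
  sp <- model_spec("sgrq_total", "mean_smoke_pm25", 7L, "per1")
  fit <- fit_main(rows, sp)
  X <- cbind(1, rows$mean_smoke_pm25, rows$age, rows$female, rows$hispanic,
             rows$bmi, rows$some_college, rows$current_smoker,
             rows$pack_years, rows$airway_obstruction)
  bh <- solve(t(X) %*% X, t(X) %*% rows$sgrq_total)
  expect_equal(fit$beta, bh[2], tolerance = 1e-8)
  resid <- rows$sgrq_total - X %*% bh
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(fit$se, se, tolerance = 1e-8)
  # ModelResult internal consistency
  tc <- qt(0.975, nrow(X) - ncol(X))
  expect_equal(fit$ci_hi - fit$beta, tc * fit$se, tolerance = 1e-10)
  expect_equal(fit$p, 2 * pt(-abs(fit$beta / fit$se), nrow(X) - ncol(X)),
               tolerance = 1e-12)
  expect_true(fit$ci_lo <= fit$beta && fit$beta <= fit$ci_hi)
})

test_that("unit rescaling is a pure reparameterization", {
  rows <- make_assoc_rows(n = 400, beta = 4.68, seed = 5, noise_sd = 15)
  f1 <- fit_main(rows, model_spec("sgrq_total", "mean_smoke_pm25", 7L,
                                  "per1"))
  f05 <- fit_main(rows, model_spec("sgrq_total", "mean_smoke_pm25", 7L,
                                   "per0.05"))
  expect_equal(f05$beta, 0.05 * f1$beta, tolerance = 1e-12)
  expect_equal(f05$ci_lo, 0.05 * f1$ci_lo, tolerance = 1e-12)
  expect_equal(f05$p, f1$p, tolerance = 1e-12)
  # per-IQR
  fiqr <- fit_main(rows, model_spec("sgrq_total", "mean_smoke_pm25", 7L,
                                    "per_iqr"))
  iqr <- unname(diff(quantile(rows$mean_smoke_pm25, c(0.25, 0.75))))
  expect_equal(fiqr$beta, iqr * f1$beta, tolerance = 1e-10)
  expect_error(rescale_exposure(rep(1, 10), "per_iqr"), "IQR")
})

test_that("a noiseless affine outcome is fitted exactly", {
  rows <- make_assoc_rows(n = 100, beta = 0, seed = 2, noise_sd = 10)
  rows$sgrq_total <- 10 + 2.5 * rows$mean_smoke_pm25 + 0.3 * rows$age
  fit <- suppressWarnings(  # summary.lm warns on an essentially perfect fit
    fit_main(rows, model_spec("sgrq_total", "mean_smoke_pm25", 7L, "per1")))
  expect_equal(fit$beta, 2.5, tolerance = 1e-10)
  expect_lt(fit$resid_sd, 1e-8)
})

test_that("type-I error at a null exposure effect is nominal", {
  reps <- 300
  sp <- model_spec("sgrq_total", "mean_smoke_pm25", 7L, "per1")
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    rows <- make_assoc_rows(n = 250, beta = 0, seed = 5000 + r)
    rej[r] <- fit_main(rows, sp)$p < 0.05
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("rank-deficient designs and missing columns are loud errors", {
  rows <- make_assoc_rows(n = 100, seed = 3)
  rows$airway_obstruction <- rows$female   # exact collinearity
  expect_error(
    fit_main(rows, model_spec("sgrq_total", "mean_smoke_pm25", 7L, "per1")),
    "collinear")
  rows2 <- make_assoc_rows(n = 100, seed = 3)
  rows2$bmi <- NULL
  expect_error(
    fit_main(rows2, model_spec("sgrq_total", "mean_smoke_pm25", 7L, "per1")),
    "missing column")
  # too few rows for the parameter count
  expect_error(
    fit_main(make_assoc_rows(n = 25, seed = 3),
             model_spec("sgrq_total", "mean_smoke_pm25", 7L, "per1")),
    "complete rows")
})

test_that("interaction analysis flags planted effect modification and rejects degenerate strata", {
  sp <- model_spec("sgrq_total", "mean_smoke_pm25", 7L, "per1")
  # constant modifier
  rows <- make_assoc_rows(n = 200, seed = 7)
  rows$woodsmoke_ever <- 1
  expect_error(fit_interaction(rows, sp, "woodsmoke_ever"), "constant")
  # null interaction: flag rate near the 10% threshold level
  set.seed(88)
  flags <- vapply(1:150, function(r) {
    d <- make_assoc_rows(n = 250, beta = 3, seed = 9000 + r)
    fit_interaction(d, sp, "woodsmoke_ever")$meaningful
  }, logical(1))
  expect_lt(abs(mean(flags) - 0.10), 3 * sqrt(0.1 * 0.9 / 150) + 0.02)
  # doubled slope in the exposed stratum at large n: high power
  hits <- vapply(1:30, function(r) {
    d <- make_assoc_rows(n = 3000, beta = 4.68, seed = 700 + r, noise_sd = 15)
    d$sgrq_total <- d$sgrq_total + 4.68 * d$mean_smoke_pm25 * d$woodsmoke_ever
    res <- fit_interaction(d, sp, "woodsmoke_ever")
    res$meaningful
  }, logical(1))
  expect_gt(mean(hits), 0.8)
  # stratum slopes decompose as main + interaction
  d <- make_assoc_rows(n = 500, beta = 2, seed = 123)
  res <- fit_interaction(d, sp, "cmh")
  expect_equal(res$slope_stratum1 - res$slope_stratum0,
               res$beta_interaction, tolerance = 1e-10)
  expect_equal(res$meaningful, res$p_interaction < 0.1)
})

test_that("winter exclusion drops exactly the winter visits", {
  rows <- make_assoc_rows(n = 747, seed = 11)
  # force exactly 66 winter visits
  rows$visit_date <- as.Date("2011-06-15")
  rows$visit_date[1:66] <- as.Date("2011-01-15")
  out <- sensitivity_winter(rows)
  expect_equal(out$n_excluded, 66)
  expect_equal(nrow(out$rows), 681)
  # no winter visits: untouched
  rows2 <- make_assoc_rows(n = 50, seed = 12)
  rows2$visit_date <- as.Date("2011-07-01")
  expect_equal(nrow(sensitivity_winter(rows2)$rows), 50)
  rows2$visit_date <- as.Date("2011-12-25")
  expect_error(sensitivity_winter(rows2), "winter")
})

test_that("the full grid covers every outcome x exposure x window and survives single failures", {
  cfg <- tiny_config(seed = 30, n_subjects = 400L)
  st <- simulate_study(cfg)
  res <- run_full_grid(st$rows)
  expect_equal(nrow(res), 6 * 5 * 4)
  expect_true(all(table(res$outcome) == 20))
  expect_true(all(table(res$window) == 30))
  # deterministic re-run
  res2 <- run_full_grid(st$rows)
  expect_identical(res, res2)
  # degenerate exposure column: recorded, not fatal
  rows_bad <- st$rows
  rows_bad$cum_overlap_area <- 0
  res3 <- run_full_grid(rows_bad)
  bad <- res3[res3$metric == "cum_overlap_area", ]
  expect_true(all(!is.na(bad$error)))
  expect_true(all(is.na(bad$beta)))
  good <- res3[res3$metric != "cum_overlap_area", ]
  expect_true(all(is.na(good$error)))
  # rendered table has one row per exposure x window
  wide <- render_results_table(res)
  expect_equal(nrow(wide), 20)
})
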