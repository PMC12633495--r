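# Adjusted linear association models, effect modification, and sensitivity
# analyses over the outcome x exposure-metric x window grid. SGRQ outcomes
# adjust for age, sex, ethnicity, BMI, education, current smoking, pack-years
# and airway obstruction; SF-36 factor outcomes swap airway obstruction for
# baseline comorbidity. Nominal P values only — no multiplicity correction.

SGRQ_ADJUSTMENT <- c("age", "female", "hispanic", "bmi", "some_college",
                     "current_smoker", "pack_years", "airway_obstruction")
SF36_ADJUSTMENT <- c("age", "female", "hispanic", "bmi", "some_college",
                     "current_smoker", "pack_years", "comorbidity")

EXPOSURE_UNITS <- c(per1 = 1, per0.05 = 0.05, per_day = 1, per_iqr = NA)

#' Specify one association model
#'
#' @param outcome outcome column (`sgrq_*` or `sf36_*`); picks the adjustment
#'   set (airway obstruction for SGRQ, comorbidity for SF-36).
#' @param metric exposure metric column (e.g. `mean_smoke_pm25`).
#' @param window window length in days the metric was computed over.
#' @param unit reporting unit: `"per1"` (per 1 ug/m3 or per unit),
#'   `"per0.05"` (per 0.05 ug/m3), `"per_day"`, `"per_iqr"` (IQR computed on
#'   the analysis sample and recorded).
#' @return a `model_spec` list.
#' @export
model_spec <- function(outcome, metric, window = 7L,
                       unit = c("per1", "per0.05", "per_day", "per_iqr")) {
  unit <- match.arg(unit)
  adj <- if (startsWith(outcome, "sgrq")) SGRQ_ADJUSTMENT else SF36_ADJUSTMENT
  structure(list(outcome = outcome, metric = metric,
                 window = as.integer(window), unit = unit, adjustment = adj),
            class = "model_spec")
}

#' Rescale an exposure for reporting
#'
#' Pure reparameterization: the coefficient per `u` units is `u` times the
#' coefficient per 1 unit, so the exposure is divided by the unit value before
#' fitting. `"per_iqr"` uses the interquartile range of the supplied
#' (non-missing) values, which is recorded in the label.
#'
#' @param values exposure values on the analysis sample.
#' @param unit as in [model_spec()].
#' @return list `values` (scaled), `unit_value`, `label`.
#' @export
rescale_exposure <- function(values,
                             unit = c("per1", "per0.05", "per_day",
                                      "per_iqr")) {
  unit <- match.arg(unit)
  if (unit == "per_iqr") {
    u <- unname(diff(quantile(values, c(0.25, 0.75), na.rm = TRUE)))
    if (u == 0) stop("rescale_exposure(): IQR of the exposure is zero")
    label <- sprintf("per IQR (%.4g)", u)
  } else {
    u <- EXPOSURE_UNITS[[unit]]
    label <- c(per1 = "per 1", per0.05 = "per 0.05",
               per_day = "per 1 day")[[unit]]
  }
  list(values = values / u, unit_value = u, label = label)
}

#' Fit one adjusted linear association model
#'
#' Ordinary least squares of the outcome on the (unit-rescaled) exposure plus
#' the spec's adjustment set. Rows with any missing modelled value are dropped
#' and counted. Reports the exposure coefficient with its t-based 95% CI and
#' two-sided P value.
#'
#' @param rows analysis table (long over `window`): outcome columns, exposure
#'   metrics, covariates.
#' @param spec a [model_spec()].
#' @return one-row tibble: identifiers, `beta`, `ci_lo`, `ci_hi`, `se`, `p`,
#'   `n`, `n_dropped`, `unit_value`, `r2`, `resid_sd`.
#' @export
fit_main <- function(rows, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- rows[rows$window == spec$window, , drop = FALSE]
  need <- c(spec$outcome, spec$metric, spec$adjustment)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("fit_main(): missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  cc <- complete.cases(d[, need])
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  p_par <- length(spec$adjustment) + 2L
  if (nrow(d) < p_par + 20L) {
    stop(sprintf("fit_main(): only %d complete rows for %d parameters",
                 nrow(d), p_par))
  }
  sc <- rescale_exposure(d[[spec$metric]], spec$unit)
  d$.exposure <- sc$values
  fml <- stats::reformulate(c(".exposure", spec$adjustment),
                            response = spec$outcome)
  fit <- lm(fml, data = d)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop(sprintf("fit_main(): rank-deficient design; collinear column(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  est <- cf[".exposure"]
  se <- sqrt(diag(vcov(fit)))[".exposure"]
  df <- fit$df.residual
  tcrit <- qt(0.975, df)
  tval <- est / se
  s <- summary(fit)
  tibble::tibble(
    outcome = spec$outcome, metric = spec$metric, window = spec$window,
    unit = sc$label,
    beta = unname(est), se = unname(se),
    ci_lo = unname(est - tcrit * se), ci_hi = unname(est + tcrit * se),
    p = unname(2 * pt(-abs(tval), df)),
    n = nrow(d), n_dropped = n_dropped, unit_value = sc$unit_value,
    r2 = s$r.squared, resid_sd = s$sigma
  )
}

INTERACTION_MODIFIERS <- c("female", "some_college", "current_smoker",
                           "woodsmoke_ever", "cmh", "hispanic")

#' Exposure-by-modifier interaction analysis
#'
#' Adds a modifier x exposure product to the main model and reports the
#' interaction coefficient, stratum-specific exposure slopes, and the
#' meaningful-interaction flag (interaction P < 0.1). By convention these are
#' run on the 7-day metrics, where associations are strongest.
#'
#' @inheritParams fit_main
#' @param modifier one of `r paste(INTERACTION_MODIFIERS, collapse = ", ")`
#'   (0/1-coded in the analysis table).
#' @param p_flag threshold for the meaningful flag (default 0.1).
#' @return one-row tibble with interaction estimate, stratum slopes and flag.
#' @export
fit_interaction <- function(rows, spec, modifier, p_flag = 0.1) {
  stopifnot(inherits(spec, "model_spec"),
            modifier %in% INTERACTION_MODIFIERS)
  d <- rows[rows$window == spec$window, , drop = FALSE]
  need <- c(spec$outcome, spec$metric, spec$adjustment, modifier)
  cc <- complete.cases(d[, unique(need)])
  d <- d[cc, , drop = FALSE]
  m <- d[[modifier]]
  if (length(unique(m)) < 2) {
    stop(sprintf("fit_interaction(): modifier '%s' is constant in the sample",
                 modifier))
  }
  sc <- rescale_exposure(d[[spec$metric]], spec$unit)
  d$.exposure <- sc$values
  covs <- setdiff(spec$adjustment, modifier)
  fml <- stats::reformulate(c(sprintf(".exposure * %s", modifier), covs),
                            response = spec$outcome)
  fit <- lm(fml, data = d)
  cf <- coef(fit)
  V <- vcov(fit)
  int_term <- sprintf(".exposure:%s", modifier)
  est <- cf[int_term]
  se <- sqrt(V[int_term, int_term])
  df <- fit$df.residual
  pval <- 2 * pt(-abs(est / se), df)
  slope0 <- cf[".exposure"]
  slope1 <- cf[".exposure"] + est
  se1 <- sqrt(V[".exposure", ".exposure"] + V[int_term, int_term] +
                2 * V[".exposure", int_term])
  tibble::tibble(
    outcome = spec$outcome, metric = spec$metric, window = spec$window,
    modifier = modifier,
    beta_interaction = unname(est), se_interaction = unname(se),
    p_interaction = unname(pval),
    slope_stratum0 = unname(slope0),
    se_stratum0 = sqrt(V[".exposure", ".exposure"]),
    slope_stratum1 = unname(slope1), se_stratum1 = unname(se1),
    meaningful = unname(pval < p_flag), n = nrow(d)
  )
}

#' Winter-exclusion sensitivity filter
#'
#' Drops visits in the configured winter months (default December-February,
#' when significant smoke events are rare) and reports the excluded count.
#'
#' @param rows analysis table with `visit_date`.
#' @param winter_months integer months treated as winter (default 12, 1, 2).
#' @return list `rows` (filtered), `n_excluded` (visits, not rows).
#' @export
sensitivity_winter <- function(rows, winter_months = c(12L, 1L, 2L)) {
  mon <- as.integer(format(as.Date(rows$visit_date), "%m"))
  keep <- !(mon %in% winter_months)
  if (!any(keep)) stop("sensitivity_winter(): all visits fall in winter")
  n_excluded <- length(unique(rows$subject_id[!keep]))
  list(rows = rows[keep, , drop = FALSE], n_excluded = n_excluded)
}

default_exposure_grid <- function() {
  tibble::tibble(
    metric = c("mean_total_pm25", "mean_smoke_pm25", "mean_smoke_bc",
               "n_smoke_days", "cum_overlap_area"),
    unit = c("per1", "per1", "per0.05", "per_day", "per_iqr")
  )
}

#' Fit the full outcome x exposure x window grid
#'
#' Iterates the six outcomes (four SGRQ scores, two SF-36 factors) over the
#' five exposure metrics and the four windows, each at its conventional
#' reporting unit. Single-model failures are recorded in an `error` column
#' rather than aborting the grid.
#'
#' @param rows analysis table (long over `window`) joined to outcomes.
#' @param outcomes outcome columns to fit.
#' @param exposures tibble `metric`, `unit` (default [default_exposure_grid()]).
#' @param windows window lengths present in `rows`.
#' @return tidy tibble, one row per model.
#' @export
run_full_grid <- function(rows,
                          outcomes = c("sgrq_activity", "sgrq_impacts",
                                       "sgrq_symptom", "sgrq_total",
                                       "sf36_mental", "sf36_physical"),
                          exposures = default_exposure_grid(),
                          windows = c(7L, 15L, 30L, 60L)) {
  res <- list()
  for (oc in outcomes) {
    for (i in seq_len(nrow(exposures))) {
      for (w in windows) {
        sp <- model_spec(oc, exposures$metric[i], w, exposures$unit[i])
        row <- tryCatch(
          cbind(fit_main(rows, sp), error = NA_character_),
          error = function(e) {
            tibble::tibble(outcome = oc, metric = exposures$metric[i],
                           window = as.integer(w), unit = exposures$unit[i],
                           beta = NA_real_, se = NA_real_, ci_lo = NA_real_,
                           ci_hi = NA_real_, p = NA_real_, n = NA_integer_,
                           n_dropped = NA_integer_, unit_value = NA_real_,
                           r2 = NA_real_, resid_sd = NA_real_,
                           error = conditionMessage(e))
          })
        res[[length(res) + 1L]] <- row
      }
    }
  }
  dplyr::bind_rows(res)
}

#' Render a results grid as association-table text
#'
#' Wide rendering with one row per exposure x window x unit and `beta
#' (95% CI)` / `P` columns per outcome, the conventional presentation of this
#' kind of analysis.
#'
#' @param results output of [run_full_grid()].
#' @param digits digits for estimates (default 2).
#' @return tibble of formatted strings.
#' @export
render_results_table <- function(results, digits = 2) {
  fmt <- function(b, lo, hi) {
    ifelse(is.na(b), "—",
           sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits,
                          "f)"), b, lo, hi))
  }
  res <- dplyr::mutate(results,
                       cell = fmt(.data$beta, .data$ci_lo, .data$ci_hi),
                       pval = ifelse(is.na(.data$p), "—",
                                     signif(.data$p, 2)))
  wide <- tidyr::pivot_wider(
    res[, c("outcome", "metric", "window", "unit", "cell", "pval")],
    names_from = "outcome", values_from = c("cell", "pval")
  )
  dplyr::arrange(wide, .data$metric, .data$window)
}
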