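# Deviation-based smoke attribution: smoke-day concentration minus the median
# of non-smoke-day concentrations from the same calendar month pooled over a
# three-year span (year before, index year, year after), truncated at zero.

#' Non-smoke-day monthly median baseline
#'
#' Median of the values observed on non-smoke days falling in the same
#' calendar month as `target_date`, pooled over the three years centred on it
#' (y-1, y, y+1). Even counts take the mean of the middle pair (standard
#' median). At the series boundary, missing neighbour years are simply not
#' pooled (a warning is raised). If the pool is empty, the `"widen"` fallback
#' retries with the adjacent calendar months included; `"missing"` returns NA.
#'
#' @param values numeric concentrations.
#' @param dates Date vector aligned with `values`.
#' @param is_smoke logical aligned with `values`.
#' @param target_date the day whose baseline is wanted.
#' @param fallback `"widen"` (default) or `"missing"`.
#' @return the baseline median (ug/m3), possibly NA under `"missing"`.
#' @export
nonsmoke_monthly_median <- function(values, dates, is_smoke, target_date,
                                    fallback = c("widen", "missing")) {
  fallback <- match.arg(fallback)
  target_date <- as.Date(target_date)
  m <- as.integer(format(target_date, "%m"))
  y <- as.integer(format(target_date, "%Y"))
  dm <- as.integer(format(dates, "%m"))
  dy <- as.integer(format(dates, "%Y"))
  have_years <- unique(dy)
  if (!all(c(y - 1, y + 1) %in% have_years)) {
    warning(sprintf(paste("baseline for %s pools only the years present in",
                          "the series (a neighbour year is missing)"),
                    format(target_date)))
  }
  pick <- function(months) {
    !is_smoke & dm %in% months & dy %in% (y - 1):(y + 1) & !is.na(values)
  }
  sel <- pick(m)
  if (!any(sel) && fallback == "widen") {
    months <- unique(c((m - 2) %% 12 + 1, m, m %% 12 + 1))
    sel <- pick(months)
  }
  if (!any(sel)) return(NA_real_)
  median(values[sel])
}

# per-(cell optional) baseline lookup for all (year, month) pairs in a series
baseline_by_year_month <- function(values, dates, is_smoke, fallback) {
  dm <- as.integer(format(dates, "%m"))
  dy <- as.integer(format(dates, "%Y"))
  years <- sort(unique(dy))
  ns <- !is_smoke & !is.na(values)
  key <- paste(dy, dm)
  pools <- split(ifelse(ns, values, NA_real_), key)
  pools <- lapply(pools, function(v) v[!is.na(v)])
  get_pool <- function(yy, mm) {
    out <- unlist(pools[paste(rep((yy - 1):(yy + 1), each = length(mm)),
                              mm)], use.names = FALSE)
    if (is.null(out)) numeric(0) else out
  }
  ym <- unique(data.frame(y = dy, m = dm))
  b <- numeric(nrow(ym))
  for (i in seq_len(nrow(ym))) {
    pool <- get_pool(ym$y[i], ym$m[i])
    if (!length(pool) && fallback == "widen") {
      mm <- unique(c((ym$m[i] - 2) %% 12 + 1, ym$m[i], ym$m[i] %% 12 + 1))
      pool <- get_pool(ym$y[i], mm)
    }
    b[i] <- if (length(pool)) median(pool) else NA_real_
  }
  b[match(key, paste(ym$y, ym$m))]
}

#' Attribute one day's concentration to smoke
#'
#' Non-smoke days get 0 by definition; smoke days get the deviation from
#' baseline, truncated at zero (negative deviations mean the plume did not
#' reach near-ground air quality).
#'
#' @param total_value observed concentration (ug/m3, >= 0).
#' @param baseline baseline median (ug/m3).
#' @param is_smoke logical.
#' @return smoke-attributed concentration (ug/m3); vectorised.
#' @export
attribute_day <- function(total_value, baseline, is_smoke) {
  ifelse(is_smoke, pmax(0, total_value - baseline), 0)
}

#' Smoke-attribute a daily pollutant grid
#'
#' Applies [nonsmoke_monthly_median()] + [attribute_day()] per cell and day to
#' both PM2.5 and BC. Baselines are stored alongside for audit. Missing
#' cell-days propagate as NA with a `missing_baseline` flag rather than being
#' silently zeroed.
#'
#' @param grid tibble `cell_id`, `date`, `pm25`, `bc` (long, one row per cell
#'   x day).
#' @param smoke_days smoke-day table (`date`, `is_smoke`).
#' @param fallback empty-pool fallback, see [nonsmoke_monthly_median()].
#' @return tibble `cell_id`, `date`, `is_smoke`, `smoke_pm25`, `smoke_bc`,
#'   `baseline_pm25`, `baseline_bc`, `missing_baseline`.
#' @export
attribute_grid <- function(grid, smoke_days,
                           fallback = c("widen", "missing")) {
  fallback <- match.arg(fallback)
  sm <- smoke_days$is_smoke[match(grid$date, smoke_days$date)]
  if (any(is.na(sm))) {
    stop("attribute_grid(): grid contains dates absent from the smoke-day table")
  }
  years <- as.integer(format(range(grid$date), "%Y"))
  if (diff(years) < 2) {
    warning("attribute_grid(): series spans fewer than three calendar years; baselines pool the years available")
  } else {
    warning(sprintf(paste("attribute_grid(): baselines for boundary years",
                          "%d and %d pool only the years present in the",
                          "series"), years[1], years[2]))
  }
  out <- grid
  out$is_smoke <- sm
  res <- dplyr::group_modify(
    dplyr::group_by(out, .data$cell_id),
    function(d, key) {
      bpm <- baseline_by_year_month(d$pm25, d$date, d$is_smoke, fallback)
      bbc <- baseline_by_year_month(d$bc, d$date, d$is_smoke, fallback)
      tibble::tibble(
        date = d$date, is_smoke = d$is_smoke,
        smoke_pm25 = attribute_day(d$pm25, bpm, d$is_smoke),
        smoke_bc = attribute_day(d$bc, bbc, d$is_smoke),
        baseline_pm25 = bpm, baseline_bc = bbc,
        missing_baseline = (is.na(bpm) | is.na(bbc)) & d$is_smoke
      )
    }
  )
  dplyr::ungroup(res)
}

#' Smoke-attribute a single daily series
#'
#' Region-level attribution operates on the area-mean daily series of the
#' member cells (see [regional_series()]); this applies the deviation method
#' to one such series.
#'
#' @param series tibble `date`, `pm25`, `bc`.
#' @inheritParams attribute_grid
#' @return tibble as [attribute_grid()] without `cell_id`.
#' @export
attribute_series <- function(series, smoke_days,
                             fallback = c("widen", "missing")) {
  fallback <- match.arg(fallback)
  s <- series
  s$cell_id <- 1L
  out <- attribute_grid(s, smoke_days, fallback = fallback)
  out$cell_id <- NULL
  out
}
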