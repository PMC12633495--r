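# Time-windowed exposure metrics: for each subject visit, summaries of the 7,
# 15, 30 and 60 days immediately preceding questionnaire completion (visit
# day excluded). Window means divide by the window length X, so non-smoke
# days contribute zeros; cumulative overlapped area sums daily overlaps
# without de-duplication (it can exceed the study-area size).

#' Dates covered by an exposure window
#'
#' The X consecutive days ending the day before `visit_date` (visit day
#' excluded).
#'
#' @param visit_date Date (or coercible).
#' @param X window length in days.
#' @return Date vector of length X.
#' @export
window_days <- function(visit_date, X) {
  visit_date <- as.Date(visit_date)
  stopifnot(length(visit_date) == 1, !is.na(visit_date), X >= 1)
  seq(visit_date - X, visit_date - 1, by = "day")
}

#' Locate the grid cell serving a point
#'
#' Nearest cell centre (equivalent to the containing cell on a regular grid);
#' ties broken deterministically by lowest `cell_id`. Errors for points
#' outside the grid's bounding box (padded by half the 1 km cell size).
#'
#' @param x,y point coordinates (planar km, same frame as the cells).
#' @param cells tibble `cell_id`, `x_km`, `y_km`.
#' @return the `cell_id` of the serving cell.
#' @export
locate_cell <- function(x, y, cells) {
  bb <- c(range(cells$x_km), range(cells$y_km))
  pad <- 0.5
  if (x < bb[1] - pad || x > bb[2] + pad || y < bb[3] - pad || y > bb[4] + pad) {
    stop(sprintf("locate_cell(): point (%.2f, %.2f) outside grid bounding box",
                 x, y))
  }
  d2 <- (cells$x_km - x)^2 + (cells$y_km - y)^2
  hit <- which(d2 <= min(d2) + 1e-9)
  cells$cell_id[hit][which.min(cells$cell_id[hit])]
}

#' Region-level daily series
#'
#' Area-mean over the member cells of the total concentrations and (when an
#' attribution table is supplied) the smoke-attributed concentrations, joined
#' to the smoke-day table.
#'
#' @param grid daily pollutant grid (`cell_id`, `date`, `pm25`, `bc`).
#' @param attribution output of [attribute_grid()] (optional).
#' @param smoke_days smoke-day table (`date`, `is_smoke`, `overlap_km2`).
#' @return tibble, one row per day: `date`, `pm25`, `bc`, `is_smoke`,
#'   `overlap_km2`, and `smoke_pm25`, `smoke_bc` when available.
#' @export
regional_series <- function(grid, attribution = NULL, smoke_days = NULL) {
  out <- dplyr::summarise(dplyr::group_by(grid, .data$date),
                          pm25 = mean(.data$pm25), bc = mean(.data$bc),
                          .groups = "drop")
  if (!is.null(attribution)) {
    att <- dplyr::summarise(dplyr::group_by(attribution, .data$date),
                            smoke_pm25 = mean(.data$smoke_pm25),
                            smoke_bc = mean(.data$smoke_bc),
                            .groups = "drop")
    out <- dplyr::left_join(out, att, by = "date")
  }
  if (!is.null(smoke_days)) {
    out <- dplyr::left_join(
      out, smoke_days[, intersect(c("date", "is_smoke", "overlap_km2"),
                                  names(smoke_days))], by = "date")
  }
  dplyr::arrange(out, .data$date)
}

window_sums <- function(values, dates, visit_dates, X) {
  # cumulative-sum lookup over a gap-free daily series
  idx_end <- match(as.Date(visit_dates) - 1, dates)
  idx_start <- match(as.Date(visit_dates) - X, dates)
  if (any(is.na(idx_end) | is.na(idx_start))) {
    bad <- which(is.na(idx_end) | is.na(idx_start))
    stop(sprintf(paste("exposure window extends outside the daily series for",
                       "visit date(s) %s"),
                 paste(format(as.Date(visit_dates)[head(bad, 5)]),
                       collapse = ", ")))
  }
  cs <- cumsum(c(0, values))
  cs[idx_end + 1] - cs[idx_start]
}

#' Exposure metrics for one visit and window
#'
#' @param visit one-row tibble with `visit_date` (and `x_km`, `y_km` for
#'   `level = "residence"`).
#' @param series region-level daily series from [regional_series()]
#'   (for `level = "region"`).
#' @param attribution,grid,cells cell-level inputs (for
#'   `level = "residence"`): [attribute_grid()] output, the pollutant grid and
#'   the cell layout.
#' @param smoke_days smoke-day table.
#' @param X window length in days.
#' @param level `"region"` or `"residence"`.
#' @return one-row tibble: `window`, `mean_smoke_pm25`, `mean_smoke_bc`,
#'   `mean_total_pm25`, `n_smoke_days`, `cum_overlap_area`.
#' @export
window_metrics <- function(visit, series = NULL, attribution = NULL,
                           grid = NULL, cells = NULL, smoke_days = NULL,
                           X = 7, level = c("region", "residence")) {
  level <- match.arg(level)
  if (level == "residence") {
    cid <- locate_cell(visit$x_km, visit$y_km, cells)
    g <- grid[grid$cell_id == cid, , drop = FALSE]
    a <- attribution[attribution$cell_id == cid, , drop = FALSE]
    series <- regional_series(g, a, smoke_days)
  }
  stopifnot(!is.null(series))
  wd <- window_days(visit$visit_date, X)
  outside <- wd[!wd %in% series$date]
  if (length(outside)) {
    stop(sprintf("window_metrics(): window for visit date(s) %s extends outside coverage; missing %s",
                 format(as.Date(visit$visit_date)),
                 paste(format(outside), collapse = ", ")))
  }
  if (any(is.na(series$smoke_pm25[match(wd, series$date)]))) {
    stop("window_metrics(): missing cell-days in the window; no imputation configured")
  }
  d <- series$date
  vd <- visit$visit_date
  tibble::tibble(
    window = as.integer(X),
    mean_smoke_pm25 = window_sums(series$smoke_pm25, d, vd, X) / X,
    mean_smoke_bc = window_sums(series$smoke_bc, d, vd, X) / X,
    mean_total_pm25 = window_sums(series$pm25, d, vd, X) / X,
    n_smoke_days = as.integer(window_sums(series$is_smoke, d, vd, X)),
    cum_overlap_area = window_sums(series$overlap_km2, d, vd, X)
  )
}

#' Analysis-ready visit-by-window exposure table
#'
#' One row per subject visit per window, carrying the five exposure metrics
#' plus the visit covariates. Region level uses the shared regional daily
#' series; residence level uses each visit's own grid cell.
#'
#' @param visits cohort tibble (from [gen_cohort()] or equivalent).
#' @param attribution [attribute_grid()] output.
#' @param grid daily pollutant grid.
#' @param smoke_days smoke-day table with `overlap_km2`.
#' @param windows integer vector of window lengths (default 7/15/30/60).
#' @param level `"region"` or `"residence"`.
#' @param cells cell layout (residence level).
#' @param series optional precomputed region-level daily series (from
#'   [regional_series()]); skips recomputation when the same exposure record
#'   serves many cohorts.
#' @return long tibble: covariates + `window` + metrics.
#' @export
build_analysis_table <- function(visits, attribution = NULL, grid = NULL,
                                 smoke_days = NULL,
                                 windows = c(7L, 15L, 30L, 60L),
                                 level = c("region", "residence"),
                                 cells = NULL, series = NULL) {
  level <- match.arg(level)
  batch <- function(s, ids, vdates) {
    dplyr::bind_rows(lapply(windows, function(X) {
      tibble::tibble(
        subject_id = ids,
        window = as.integer(X),
        mean_smoke_pm25 = window_sums(s$smoke_pm25, s$date, vdates, X) / X,
        mean_smoke_bc = window_sums(s$smoke_bc, s$date, vdates, X) / X,
        mean_total_pm25 = window_sums(s$pm25, s$date, vdates, X) / X,
        n_smoke_days = as.integer(window_sums(s$is_smoke, s$date, vdates, X)),
        cum_overlap_area = window_sums(s$overlap_km2, s$date, vdates, X)
      )
    }))
  }
  if (level == "region") {
    if (is.null(series)) {
      series <- regional_series(grid, attribution, smoke_days)
    }
    met <- batch(series, visits$subject_id, visits$visit_date)
  } else {
    stopifnot(!is.null(cells))
    cid <- vapply(seq_len(nrow(visits)), function(i) {
      locate_cell(visits$x_km[i], visits$y_km[i], cells)
    }, integer(1))
    met <- dplyr::bind_rows(lapply(split(seq_len(nrow(visits)), cid),
      function(ix) {
        cc <- cid[ix[1]]
        s <- regional_series(grid[grid$cell_id == cc, , drop = FALSE],
                             attribution[attribution$cell_id == cc, ,
                                         drop = FALSE],
                             smoke_days)
        batch(s, visits$subject_id[ix], visits$visit_date[ix])
      }))
  }
  out <- dplyr::left_join(met, visits, by = "subject_id")
  dplyr::arrange(out, .data$window, .data$subject_id)
}
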