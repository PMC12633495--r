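# Plain-text interchange: GeoJSON for geometries (minimal FeatureCollection
# subset, read/written with jsonlite), CSV for tabular stages.

#' Read plume polygons from GeoJSON
#'
#' Expects a FeatureCollection of Polygon (or MultiPolygon) features, each
#' with a `date` property (ISO-8601). Outer rings only; coordinates are
#' lon/lat and are projected to the equal-area km frame of `center`.
#'
#' @param path GeoJSON file.
#' @param center projection centre (lon, lat), typically the study area's
#'   `$center`.
#' @return tibble `date`, `plume_id`, `ring` (km vertex matrices).
#' @export
read_plumes_geojson <- function(path, center) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("read_plumes_geojson(): no features")
  rows <- list()
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    dt <- ft$properties$date
    if (is.null(dt)) {
      stop(sprintf("read_plumes_geojson(): feature %d lacks a date property",
                   i))
    }
    geom <- ft$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop(sprintf("feature %d: unsupported geometry type %s",
                                 i, geom$type)))
    for (p in polys) {
      ring_ll <- do.call(rbind, lapply(p[[1]], function(v) {
        c(v[[1]], v[[2]])
      }))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        date = as.Date(dt), plume_id = length(rows) + 1L,
        ring = list(laea_project(ring_ll, center))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write plume polygons to GeoJSON
#'
#' @param plumes tibble `date`, `ring` (km vertex matrices).
#' @param path output file.
#' @param center projection centre used to return to lon/lat.
#' @export
write_plumes_geojson <- function(plumes, path, center) {
  feats <- lapply(seq_len(nrow(plumes)), function(i) {
    ll <- laea_inverse(plumes$ring[[i]], center)
    ll <- rbind(ll, ll[1, ])  # close ring
    list(type = "Feature",
         properties = list(date = format(plumes$date[i])),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ll)),
                                                   function(j) {
                                                     as.numeric(ll[j, ])
                                                   }))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a study area polygon from GeoJSON
#'
#' First Polygon feature (outer ring) of a FeatureCollection, in lon/lat.
#'
#' @param path GeoJSON file.
#' @param name label for the area.
#' @return a [study_area()].
#' @export
read_study_area_geojson <- function(path, name = "study area") {
  gj <- jsonlite::read_json(path)
  ft <- if (!is.null(gj$features)) gj$features[[1]] else gj
  geom <- if (!is.null(ft$geometry)) ft$geometry else ft
  if (is.null(geom$type) || geom$type != "Polygon") {
    stop("read_study_area_geojson(): expected a Polygon feature")
  }
  ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(v) {
    c(v[[1]], v[[2]])
  }))
  study_area(ring, name = name, crs = "lonlat")
}

#' Smoke-day table CSV round trip
#'
#' Columns `date`, `is_smoke`, `overlap_km2`.
#'
#' @param smoke_days tibble to write.
#' @param path CSV file.
#' @export
write_smoke_days_csv <- function(smoke_days, path) {
  write.csv(smoke_days, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_smoke_days_csv
#' @export
read_smoke_days_csv <- function(path) {
  d <- read.csv(path)
  tibble::tibble(date = as.Date(d$date), is_smoke = as.logical(d$is_smoke),
                 overlap_km2 = as.numeric(d$overlap_km2))
}

#' Pollutant grid CSV round trip
#'
#' Long daily grid: `cell_id`, `x_km`, `y_km`, `date`, `pm25`, `bc`.
#'
#' @param grid tibble to write.
#' @param path CSV file.
#' @export
write_grid_csv <- function(grid, path) {
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  d <- read.csv(path)
  d$date <- as.Date(d$date)
  tibble::as_tibble(d)
}

#' Read an SGRQ weight table from YAML
#'
#' The official instrument weights are licensed and are not shipped; users
#' supply their own table as YAML of the form
#' `domain: {item_key: weight, ...}` with domains `symptom`, `activity`,
#' `impacts`.
#'
#' @param path YAML file.
#' @return data frame `item`, `domain`, `weight` suitable for [score_sgrq()].
#' @export
read_sgrq_weights_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_sgrq_weights_yaml() needs the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("symptom", "activity", "impacts"))
  if (length(bad)) {
    stop(sprintf("unknown SGRQ domain(s) in weight file: %s",
                 paste(bad, collapse = ", ")))
  }
  dplyr::bind_rows(lapply(names(y), function(d) {
    tibble::tibble(item = names(y[[d]]), domain = d,
                   weight = as.numeric(unlist(y[[d]])))
  }))
}

#' Read a pre-computed county-level daily smoke-PM2.5 series
#'
#' Alternate exposure input (e.g. the published machine-learning county-level
#' smoke-PM2.5 product) for sensitivity analyses: columns `date`, `county`,
#' `smoke_pm25`. Counties are averaged into one regional daily series that can
#' replace the deviation-method `smoke_pm25` in [build_analysis_table()]
#' inputs.
#'
#' @param path CSV file.
#' @return tibble `date`, `smoke_pm25` (county-averaged).
#' @export
read_county_smoke_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("date", "county", "smoke_pm25") %in% names(d)))
  d$date <- as.Date(d$date)
  out <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(d), .data$date),
                          smoke_pm25 = mean(.data$smoke_pm25),
                          .groups = "drop")
  dplyr::arrange(out, .data$date)
}
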