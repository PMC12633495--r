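# Plume / study-area geometry: smoke-day classification from polygon overlap.
#
# All area arithmetic happens in a planar equal-area frame (km). Geographic
# input (lon/lat degrees) is projected with a spherical Lambert azimuthal
# equal-area projection centred on the study area, so km^2 read off the plane
# are true areas to well under the tolerances used anywhere downstream.

EARTH_RADIUS_KM <- 6371.0088

#' Project lon/lat coordinates to an equal-area plane
#'
#' Spherical Lambert azimuthal equal-area projection centred at `center`.
#' Output coordinates are kilometres east/north of the centre; the projection
#' preserves areas exactly on the sphere, which is what the overlap
#' computations need (the study region spans ~2 degrees, so sphere-vs-ellipsoid
#' area differences are far below any threshold used here).
#'
#' @param lonlat two-column matrix (lon, lat) in decimal degrees.
#' @param center length-2 numeric, the projection centre (lon, lat).
#' @return two-column matrix of planar coordinates in km.
#' @export
laea_project <- function(lonlat, center) {
  lonlat <- as.matrix(lonlat)
  stopifnot(ncol(lonlat) == 2, length(center) == 2)
  lam <- lonlat[, 1] * pi / 180
  phi <- lonlat[, 2] * pi / 180
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  dlam <- lam - lam0
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  if (any(denom <= 1e-12)) {
    stop("laea_project(): point antipodal to projection centre")
  }
  k <- sqrt(2 / denom)
  cbind(
    x = EARTH_RADIUS_KM * k * cos(phi) * sin(dlam),
    y = EARTH_RADIUS_KM * k *
      (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  )
}

# Signed shoelace area of a ring (open: last vertex != first).
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a polygon ring
#'
#' @param ring two-column matrix of vertices (planar km), open or closed.
#' @return absolute area (km^2 when coordinates are km).
#' @export
ring_area <- function(ring) abs(ring_area_signed(validate_ring(ring)))

#' Validate (and lightly normalise) a polygon ring
#'
#' Checks finiteness, drops a duplicated closing vertex, and requires at least
#' three distinct vertices with nonzero area. Degenerate geometry is a hard
#' error naming the offending feature; there is no silver-polygon repair beyond
#' this (self-touching rings are still handled consistently downstream by the
#' even-odd fill rule).
#'
#' @param ring two-column numeric matrix.
#' @param what label used in error messages.
#' @return the normalised open ring.
#' @export
validate_ring <- function(ring, what = "polygon") {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2 || !is.numeric(ring)) {
    stop(sprintf("%s: ring must be a numeric two-column matrix", what))
  }
  if (any(!is.finite(ring))) {
    stop(sprintf("%s: non-finite vertex coordinates", what))
  }
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3) {
    stop(sprintf("%s: fewer than three distinct vertices", what))
  }
  if (abs(ring_area_signed(ring)) < 1e-12) {
    stop(sprintf("%s: degenerate (zero-area) ring", what))
  }
  ring
}

# y-coordinates at which edges of different rings cross; these are the only
# places where the interval structure of a horizontal slice can change.
edge_crossing_ys <- function(edges) {
  m <- nrow(edges)
  if (m < 2) return(numeric(0))
  out <- numeric(0)
  for (i in seq_len(m - 1)) {
    p1 <- edges[i, 1:2]; p2 <- edges[i, 3:4]
    d1 <- p2 - p1
    for (j in (i + 1):m) {
      q1 <- edges[j, 1:2]; q2 <- edges[j, 3:4]
      d2 <- q2 - q1
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < 1e-14) next
      w <- q1 - p1
      t <- (w[1] * d2[2] - w[2] * d2[1]) / den
      u <- (w[1] * d1[2] - w[2] * d1[1]) / den
      if (t > 0 && t < 1 && u > 0 && u < 1) {
        out <- c(out, p1[2] + t * d1[2])
      }
    }
  }
  out
}

# Sorted x-crossings of ring edges with the horizontal line y = y0,
# paired into filled intervals by the even-odd rule.
ring_slice <- function(ring, y0) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  hit <- (y > y0) != (y[j] > y0)
  if (!any(hit)) return(NULL)
  xs <- x[hit] + (y0 - y[hit]) * (x[j][hit] - x[hit]) / (y[j][hit] - y[hit])
  xs <- sort(xs)
  matrix(xs, ncol = 2, byrow = TRUE)
}

#' Area of the union of polygon rings
#'
#' Exact (to floating point) scanline integration: the plane is cut into
#' horizontal strips at every vertex y and every pairwise edge crossing; inside
#' a strip the union of the rings' slice intervals has constant combinatorial
#' structure and linearly moving endpoints, so its length at the strip midpoint
#' times the strip height integrates the union area exactly. Self-intersecting
#' rings are interpreted by the even-odd fill rule.
#'
#' @param rings list of two-column vertex matrices (planar km).
#' @return total area covered by at least one ring (km^2).
#' @export
poly_union_area <- function(rings) {
  if (length(rings) == 0) return(0)
  rings <- lapply(seq_along(rings), function(i) {
    validate_ring(rings[[i]], what = sprintf("polygon %d", i))
  })
  edges <- do.call(rbind, lapply(rings, function(r) {
    n <- nrow(r)
    j <- c(2:n, 1)
    cbind(r[, 1], r[, 2], r[j, 1], r[j, 2])
  }))
  ys <- c(unlist(lapply(rings, function(r) r[, 2])), edge_crossing_ys(edges))
  ys <- sort(unique(ys))
  if (length(ys) < 2) return(0)
  area <- 0
  for (k in seq_len(length(ys) - 1)) {
    h <- ys[k + 1] - ys[k]
    if (h <= 0) next
    ym <- (ys[k] + ys[k + 1]) / 2
    iv <- do.call(rbind, lapply(rings, ring_slice, y0 = ym))
    if (is.null(iv) || nrow(iv) == 0) next
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    len <- 0
    cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
    if (nrow(iv) > 1) {
      for (r in 2:nrow(iv)) {
        if (iv[r, 1] <= cur_hi) {
          cur_hi <- max(cur_hi, iv[r, 2])
        } else {
          len <- len + (cur_hi - cur_lo)
          cur_lo <- iv[r, 1]; cur_hi <- iv[r, 2]
        }
      }
    }
    len <- len + (cur_hi - cur_lo)
    area <- area + len * h
  }
  area
}

#' Construct a study area
#'
#' @param ring polygon ring; lon/lat degrees when `crs = "lonlat"` (projected
#'   internally), planar km when `crs = "km"`.
#' @param name label.
#' @param crs `"lonlat"` or `"km"`.
#' @param center projection centre for `crs = "lonlat"`; defaults to the ring's
#'   vertex centroid.
#' @return a `study_area` object: projected ring (km), `area_km2`, `name`,
#'   `center` (lon/lat used for projection, if any).
#' @export
study_area <- function(ring, name = "study area", crs = c("lonlat", "km"),
                       center = NULL) {
  crs <- match.arg(crs)
  ring <- as.matrix(ring)
  if (crs == "lonlat") {
    if (is.null(center)) center <- colMeans(ring)
    ring_km <- laea_project(ring, center)
  } else {
    ring_km <- ring
  }
  ring_km <- validate_ring(ring_km, what = name)
  structure(
    list(ring = ring_km, area_km2 = abs(ring_area_signed(ring_km)),
         name = name, center = center),
    class = "study_area"
  )
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf("<study_area> %s: %d vertices, %.0f km2\n",
              x$name, nrow(x$ring), x$area_km2))
  invisible(x)
}

#' Default four-county study area
#'
#' A convex polygon over the greater Albuquerque four-county region
#' (Bernalillo, Sandoval, Valencia, Torrance), rescaled about its centroid in
#' the equal-area plane so that its area equals the published 18,719 km2
#' catchment exactly. The vertex outline is schematic (county borders are not
#' reproduced); the location, extent and area are what matter for exposure
#' work.
#'
#' @param area_km2 target area; default 18719.
#' @return a [study_area()] object.
#' @export
study_area_default <- function(area_km2 = 18719) {
  outline <- cbind(
    lon = c(-107.20, -106.90, -106.20, -105.30, -105.15, -105.35,
            -106.10, -106.95),
    lat = c(34.75, 35.75, 36.05, 35.70, 35.00, 34.40, 34.25, 34.35)
  )
  sa <- study_area(outline, name = "greater Albuquerque (4 counties)")
  s <- sqrt(area_km2 / sa$area_km2)
  ctr <- colMeans(sa$ring)
  sa$ring <- sweep(sweep(sa$ring, 2, ctr) * s, 2, ctr, `+`)
  sa$area_km2 <- abs(ring_area_signed(sa$ring))
  sa
}

#' Daily plume / study-area overlap area
#'
#' Area of (union of the day's plume polygons) intersected with the study
#' area, in km^2. Plumes are unioned first so overlapping plumes within a day
#' are not double-counted; the intersection is obtained from union areas via
#' area(A int S) = area(A) + area(S) - area(A un S), all three terms computed
#' by the same scanline engine.
#'
#' @param plume_rings list of plume rings (planar km, same frame as `area`).
#' @param area a [study_area()].
#' @return overlap area in km^2 (0 for an empty plume set).
#' @export
overlap_area <- function(plume_rings, area) {
  stopifnot(inherits(area, "study_area"))
  if (length(plume_rings) == 0) return(0)
  a_p <- poly_union_area(plume_rings)
  a_s <- poly_union_area(list(area$ring))
  a_ps <- poly_union_area(c(plume_rings, list(area$ring)))
  ov <- a_p + a_s - a_ps
  min(max(ov, 0), area$area_km2)
}

#' Classify smoke days from plume polygons
#'
#' A calendar day is a smoke day when the union of its plumes overlaps the
#' study area by at least `threshold_km2` (boundary inclusive). Days in the
#' range with no plume record are non-smoke with overlap 0.
#'
#' @param plumes tibble with columns `date` (Date) and `ring` (list of planar
#'   km vertex matrices); several rows per day allowed.
#' @param area a [study_area()].
#' @param start,end analysis date range (inclusive).
#' @param threshold_km2 smoke-day threshold, default 1 km^2.
#' @return tibble `date`, `is_smoke`, `overlap_km2` — one row per day.
#' @export
detect_smoke_days <- function(plumes, area, start, end, threshold_km2 = 1) {
  stopifnot(inherits(area, "study_area"), threshold_km2 > 0)
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start) {
    stop("detect_smoke_days(): empty or invalid date range")
  }
  dates <- seq(start, end, by = "day")
  ov <- numeric(length(dates))
  if (!is.null(plumes) && nrow(plumes) > 0) {
    pd <- as.Date(plumes$date)
    idx <- split(seq_len(nrow(plumes)), as.character(pd))
    for (d in names(idx)) {
      k <- match(as.Date(d), dates)
      if (is.na(k)) next
      ov[k] <- overlap_area(plumes$ring[idx[[d]]], area)
    }
  }
  # absolute slack absorbs scanline round-off so the "at least" boundary
  # stays inclusive for exactly-threshold constructions
  tibble::tibble(
    date = dates,
    is_smoke = ov >= threshold_km2 - 1e-6,
    overlap_km2 = ov
  )
}

#' Point-in-polygon test
#'
#' Even-odd ray casting, vectorised over points. Used for drawing residence
#' coordinates inside the study area and available for ad-hoc checks.
#'
#' @param x,y point coordinates (planar km).
#' @param ring polygon ring.
#' @return logical vector.
#' @export
point_in_ring <- function(x, y, ring) {
  ring <- validate_ring(ring)
  rx <- ring[, 1]; ry <- ring[, 2]
  n <- length(rx)
  j <- c(2:n, 1)
  inside <- rep(FALSE, length(x))
  for (e in seq_len(n)) {
    x1 <- rx[e]; y1 <- ry[e]; x2 <- rx[j[e]]; y2 <- ry[j[e]]
    if (y1 == y2) next
    hit <- ((y1 > y) != (y2 > y)) &
      (x < x1 + (y - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, hit)
  }
  inside
}
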