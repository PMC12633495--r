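# Shared fixtures: small geometries, a short simulated study, and
# independent oracle implementations used across tests.

sq_ring <- function(x0, y0, w, h = w) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# a small, fast configuration: 3-year record, few cells, small cohort
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_subjects = 120L, n_cells = 4L,
               date_range = c("2010-01-01", "2012-12-31"))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Monte-Carlo point-sampling area oracle (independent of the scanline
# engine): fraction of uniform bounding-box points inside any plume AND the
# study area, times the box area. Returns estimate and standard error.
mc_overlap_oracle <- function(rings, area, n_pts = 2e5) {
  all_rings <- c(rings, list(area$ring))
  xs <- range(unlist(lapply(all_rings, function(r) r[, 1])))
  ys <- range(unlist(lapply(all_rings, function(r) r[, 2])))
  px <- runif(n_pts, xs[1], xs[2])
  py <- runif(n_pts, ys[1], ys[2])
  in_plume <- rep(FALSE, n_pts)
  for (r in rings) in_plume <- in_plume | point_in_ring(px, py, r)
  hit <- in_plume & point_in_ring(px, py, area$ring)
  box <- diff(xs) * diff(ys)
  p <- mean(hit)
  list(est = p * box, se = sqrt(p * (1 - p) / n_pts) * box)
}

# naive double-loop deviation-method implementation (oracle for
# attribute_grid): recomputes every baseline by explicit enumeration
naive_attribution <- function(grid, smoke_days, value_col = "pm25") {
  sm <- smoke_days$is_smoke[match(grid$date, smoke_days$date)]
  out <- numeric(nrow(grid))
  base <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (!sm[i]) { out[i] <- 0; base[i] <- NA; next }
    d <- grid$date[i]
    m <- as.integer(format(d, "%m"))
    y <- as.integer(format(d, "%Y"))
    sel <- which(grid$cell_id == grid$cell_id[i] &
                   as.integer(format(grid$date, "%m")) == m &
                   as.integer(format(grid$date, "%Y")) %in% (y - 1):(y + 1) &
                   !sm)
    b <- median(grid[[value_col]][sel])
    base[i] <- b
    out[i] <- max(0, grid[[value_col]][i] - b)
  }
  list(smoke = out, baseline = base)
}

# toy SGRQ weight table for scoring tests
toy_sgrq_weights <- function() {
  data.frame(
    item = c("s1", "s2", "s3", "a1", "a2", "a3", "i1", "i2", "i3"),
    domain = rep(c("symptom", "activity", "impacts"), each = 3),
    weight = c(10, 20, 70, 10, 20, 70, 10, 20, 70)
  )
}

# simulate SF-36 domain scores from an exact two-factor model
simulate_two_factor <- function(n, lam_p, lam_m, rho, seed = 1) {
  set.seed(seed)
  ph <- matrix(c(1, rho, rho, 1), 2)
  f <- matrix(rnorm(n * 2), n) %*% chol(ph)
  doms <- c("physical_functioning", "role_physical", "bodily_pain",
            "general_health", "mental_health", "role_emotional",
            "social_functioning", "vitality")
  x <- matrix(NA_real_, n, 8, dimnames = list(NULL, doms))
  for (i in 1:4) {
    x[, i] <- lam_p[i] * f[, 1] + rnorm(n, 0, sqrt(1 - lam_p[i]^2))
  }
  for (i in 1:4) {
    x[, 4 + i] <- lam_m[i] * f[, 2] + rnorm(n, 0, sqrt(1 - lam_m[i]^2))
  }
  list(domains = as.data.frame(x), factors = f)
}

# small analysis table with outcomes, generated directly (no geometry),
# for association-model tests
make_assoc_rows <- function(n = 300, beta = 0, seed = 1, noise_sd = 10,
                            window = 7L) {
  set.seed(seed)
  x <- rexp(n, 2) * rbinom(n, 1, 0.6)
  visits <- tibble::tibble(
    subject_id = seq_len(n),
    visit_date = as.Date("2011-06-01") + sample(0:364, n, TRUE),
    age = rnorm(n, 57, 9), female = rbinom(n, 1, 0.5),
    bmi = rnorm(n, 29, 6), hispanic = rbinom(n, 1, 0.25),
    some_college = rbinom(n, 1, 0.64), current_smoker = rbinom(n, 1, 0.6),
    pack_years = pmax(10, rnorm(n, 41, 20)),
    woodsmoke_ever = rbinom(n, 1, 0.32), cmh = rbinom(n, 1, 0.31),
    airway_obstruction = rbinom(n, 1, 0.4), comorbidity = rbinom(n, 1, 0.5)
  )
  y <- 40 + 0.1 * (visits$age - 57) + 4 * visits$current_smoker +
    8 * visits$airway_obstruction + beta * x + rnorm(n, 0, noise_sd)
  dplyr::mutate(visits, window = window, mean_smoke_pm25 = x,
                sgrq_total = y,
                sf36_physical = -0.2 * x + rnorm(n, 0, 1) +
                  -0.35 * visits$comorbidity)
}
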