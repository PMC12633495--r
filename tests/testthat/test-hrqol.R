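test_that("SGRQ weighted scoring matches hand arithmetic and handles extremes", {
  w <- toy_sgrq_weights()
  # 3-item domain with weights {10, 20, 70}, first two endorsed -> 30.0
  resp <- c(s1 = 1, s2 = 1, s3 = 0, a1 = 0, a2 = 0, a3 = 0,
            i1 = 0, i2 = 0, i3 = 0)
  sc <- score_sgrq(resp, w)
  expect_equal(sc$symptom, 30)
  expect_equal(sc$activity, 0)
  expect_equal(sc$total, 100 * 30 / 300)
  # nothing endorsed -> 0; everything endorsed -> 100
  expect_equal(unlist(score_sgrq(setNames(rep(0, 9), w$item), w)),
               c(activity = 0, impacts = 0, symptom = 0, total = 0))
  expect_equal(unlist(score_sgrq(setNames(rep(1, 9), w$item), w)),
               c(activity = 100, impacts = 100, symptom = 100, total = 100))
})

test_that("SGRQ scoring renormalises tolerable missingness and rejects unknown items", {
  w <- toy_sgrq_weights()
  resp <- c(s1 = NA, s2 = 1, s3 = 0, a1 = 1, a2 = 1, a3 = 1,
            i1 = 0, i2 = 0, i3 = 0)
  sc <- score_sgrq(resp, w, missing_cap = 0.4)
  expect_equal(sc$symptom, 100 * 20 / 90)   # s1 dropped from both sums
  # above the cap the score is missing
  sc2 <- score_sgrq(c(s1 = NA, s2 = NA, s3 = 1), w, missing_cap = 0.25)
  expect_true(is.na(sc2$symptom))
  expect_error(score_sgrq(c(zz = 1), w), "zz")
})

test_that("SF-36 domain scoring hits the floor, ceiling, and mid-range recodes", {
  # reverse-keyed items (1, 2, 20-23, 26, 27, 30, 34, 36) are best at code 1
  best <- c(1, 1, rep(3, 10), rep(2, 7),
            1, 1, 1, 1, 6, 6, 1, 1, 6, 6, 1, 6, 5, 5, 1, 5, 1)
  worst <- c(5, 5, rep(1, 10), rep(1, 7),
             5, 6, 5, 6, 1, 1, 6, 6, 1, 1, 6, 1, 1, 1, 5, 1, 5)
  sb <- score_sf36(best)
  sw <- score_sf36(worst)
  expect_true(all(unlist(sb) == 100))
  expect_true(all(unlist(sw) == 0))
  # a domain whose item recodes are {0, 50, 100} averages to 50:
  # physical functioning items are 3-point (1->0, 2->50, 3->100)
  items <- best
  items[3:12] <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 2)
  expect_equal(score_sf36(items)$physical_functioning, 50)
  bad <- best; bad[21] <- 9
  expect_error(score_sf36(bad), "item 21")
})

test_that("two-factor ML fit recovers planted loadings and correlation", {
  lam_p <- c(0.85, 0.78, 0.70, 0.66)
  lam_m <- c(0.84, 0.74, 0.72, 0.68)
  sim <- simulate_two_factor(5000, lam_p, lam_m, rho = 0.45, seed = 42)
  fit <- fit_two_factor(sim$domains)
  phys_doms <- c("physical_functioning", "role_physical", "bodily_pain",
                 "general_health")
  ment_doms <- c("mental_health", "role_emotional", "social_functioning",
                 "vitality")
  expect_true(all(abs(fit$loadings[phys_doms, "physical"] - lam_p) < 0.05))
  expect_true(all(abs(fit$loadings[ment_doms, "mental"] - lam_m) < 0.05))
  expect_lt(abs(fit$phi - 0.45), 0.05)
  # factor scores are standardized and track the true factors
  expect_equal(mean(fit$scores$physical), 0, tolerance = 1e-8)
  expect_equal(sd(fit$scores$mental), 1, tolerance = 1e-8)
  expect_gt(cor(fit$scores$physical, sim$factors[, 1]), 0.85)
})

test_that("orthogonal factors are estimated as uncorrelated", {
  sim <- simulate_two_factor(4000, rep(0.75, 4), rep(0.75, 4), rho = 0,
                             seed = 9)
  fit <- fit_two_factor(sim$domains)
  expect_lt(abs(fit$phi), 0.05)
})

test_that("duplicated rows receive identical factor scores", {
  sim <- simulate_two_factor(300, rep(0.8, 4), rep(0.7, 4), rho = 0.4,
                             seed = 3)
  d2 <- rbind(sim$domains, sim$domains[1:10, ])
  fit <- fit_two_factor(d2)
  expect_equal(fit$scores$physical[301:310], fit$scores$physical[1:10])
  expect_equal(fit$scores$mental[301:310], fit$scores$mental[1:10])
})

test_that("reported log-likelihood matches a brute-force multivariate-normal evaluation", {
  sim <- simulate_two_factor(400, rep(0.8, 4), rep(0.75, 4), rho = 0.45,
                             seed = 11)
  fit <- fit_two_factor(sim$domains)
  doms <- rownames(fit$loadings)
  z <- scale(as.matrix(sim$domains[, doms]))
  n <- nrow(z)
  sigma <- fit$loadings %*% matrix(c(1, fit$phi, fit$phi, 1), 2) %*%
    t(fit$loadings) + diag(fit$uniqueness)
  # per-row Gaussian log-density via Cholesky (independent of the fit's
  # trace-form shortcut)
  ch <- chol(sigma)
  q <- colSums(backsolve(ch, t(z), transpose = TRUE)^2)
  ll <- sum(-0.5 * (8 * log(2 * pi) + 2 * sum(log(diag(ch))) + q))
  # the fit evaluates at S with divisor n; align the cross term
  expect_equal(fit$logLik, ll, tolerance = 1e-6)
})

test_that("factor scores are invariant to affine rescaling of a domain", {
  sim <- simulate_two_factor(800, rep(0.8, 4), rep(0.7, 4), rho = 0.4,
                             seed = 13)
  fit1 <- fit_two_factor(sim$domains)
  d2 <- sim$domains
  d2$vitality <- 10 * d2$vitality + 5
  fit2 <- fit_two_factor(d2)
  expect_equal(fit2$scores$physical, fit1$scores$physical, tolerance = 1e-4)
  expect_equal(fit2$scores$mental, fit1$scores$mental, tolerance = 1e-4)
})

test_that("SGRQ weight tables round-trip through YAML configuration", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("symptom:", "  s1: 10", "  s2: 20", "  s3: 70",
               "activity:", "  a1: 50", "impacts:", "  i1: 50"), f)
  w <- read_sgrq_weights_yaml(f)
  expect_equal(nrow(w), 5)
  sc <- score_sgrq(c(s1 = 1, s2 = 1, s3 = 0, a1 = 0, i1 = 1), w)
  expect_equal(sc$symptom, 30)
  writeLines(c("bogus:", "  x: 1"), f)
  expect_error(read_sgrq_weights_yaml(f), "bogus")
})

test_that("scores stay inside instrument bounds on random valid input", {
  set.seed(77)
  w <- toy_sgrq_weights()
  rec_len <- c(5, 5, rep(3, 10), rep(2, 7),
               5, 6, 5, 6, 6, 6, 6, 6, 6, 6, 6, 6, 5, 5, 5, 5, 5)
  for (i in 1:25) {
    resp <- setNames(rbinom(9, 1, 0.5), w$item)
    sc <- unlist(score_sgrq(resp, w))
    expect_true(all(sc >= 0 & sc <= 100))
    items <- vapply(rec_len, function(k) sample.int(k, 1), integer(1))
    sf <- unlist(score_sf36(items))
    expect_true(all(sf >= 0 & sf <= 100))
  }
})
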