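# HRQoL instruments. SGRQ: weighted endorsement scoring against a
# user-supplied weight table (the official item weights are licensed and are
# NOT shipped); four scores 0-100, higher = worse. SF-36: standard 0-100 item
# recoding and per-domain means, higher = better; the eight domains are then
# reduced to physical / mental factor scores via a fixed simple-structure
# two-correlated-factor model fitted by maximum likelihood.

SF36_DOMAINS <- c("physical_functioning", "role_physical", "role_emotional",
                  "social_functioning", "mental_health", "vitality",
                  "general_health", "bodily_pain")

PHYSICAL_DOMAINS <- c("physical_functioning", "role_physical", "bodily_pain",
                      "general_health")
MENTAL_DOMAINS <- c("mental_health", "role_emotional", "social_functioning",
                    "vitality")

#' Score the SGRQ from item endorsements
#'
#' Each score is 100 x (sum of the weights of endorsed items in the domain) /
#' (maximum possible weight sum for that domain); the total score pools all
#' items. Missing responses are removed from both numerator and denominator
#' provided the missing fraction of a domain's items stays at or below
#' `missing_cap`; otherwise the score is NA.
#'
#' @param items named logical/0-1 vector of endorsements (names are item
#'   keys), or a data frame / matrix with item-key columns for many subjects.
#' @param weights data frame `item`, `domain` (one of `symptom`, `activity`,
#'   `impacts`), `weight` (positive).
#' @param missing_cap maximum tolerated fraction of missing items per domain
#'   (default 0.25).
#' @return tibble with `activity`, `impacts`, `symptom`, `total` in `[0,100]`.
#' @export
score_sgrq <- function(items, weights, missing_cap = 0.25) {
  stopifnot(all(c("item", "domain", "weight") %in% names(weights)),
            all(weights$domain %in% c("symptom", "activity", "impacts")),
            all(weights$weight > 0))
  if (is.null(dim(items))) items <- t(as.matrix(items))
  items <- as.matrix(items)
  unknown <- setdiff(colnames(items), weights$item)
  if (length(unknown)) {
    stop(sprintf("score_sgrq(): response key(s) absent from weight table: %s",
                 paste(unknown, collapse = ", ")))
  }
  one <- function(resp, dom_items) {
    w <- weights$weight[match(dom_items, weights$item)]
    r <- resp[dom_items]
    miss <- is.na(r)
    if (mean(miss) > missing_cap) return(NA_real_)
    100 * sum(w[!miss] * as.numeric(r[!miss])) / sum(w[!miss])
  }
  doms <- list(symptom = weights$item[weights$domain == "symptom"],
               activity = weights$item[weights$domain == "activity"],
               impacts = weights$item[weights$domain == "impacts"],
               total = weights$item)
  res <- t(apply(items, 1, function(resp) {
    full <- rep(NA, nrow(weights))
    names(full) <- weights$item
    full[colnames(items)] <- resp
    vapply(doms, function(di) one(full, di), numeric(1))
  }))
  tibble::tibble(activity = unname(res[, "activity"]),
                 impacts = unname(res[, "impacts"]),
                 symptom = unname(res[, "symptom"]),
                 total = unname(res[, "total"]))
}

sf36_recode_table <- function() {
  rec <- vector("list", 36)
  rev5 <- c(100, 75, 50, 25, 0)
  fwd5 <- c(0, 25, 50, 75, 100)
  rev6 <- c(100, 80, 60, 40, 20, 0)
  fwd6 <- c(0, 20, 40, 60, 80, 100)
  for (i in c(1, 2, 20, 22, 34, 36)) rec[[i]] <- rev5
  for (i in 3:12) rec[[i]] <- c(0, 50, 100)
  for (i in 13:19) rec[[i]] <- c(0, 100)
  for (i in c(21, 23, 26, 27, 30)) rec[[i]] <- rev6
  for (i in c(24, 25, 28, 29, 31)) rec[[i]] <- fwd6
  for (i in c(32, 33, 35)) rec[[i]] <- fwd5
  rec
}

sf36_domain_items <- function() {
  list(physical_functioning = 3:12, role_physical = 13:16,
       role_emotional = 17:19, social_functioning = c(20, 32),
       mental_health = c(24, 25, 26, 28, 30), vitality = c(23, 27, 29, 31),
       general_health = c(1, 33, 34, 35, 36), bodily_pain = c(21, 22))
}

#' Score the SF-36 domains from raw item responses
#'
#' Standard public-domain 36-item scoring: each raw response (1..k) is
#' recoded to 0-100 (reverse-keyed items flipped), then each domain is the
#' mean of its answered items; a domain is NA only when all of its items are
#' missing.
#'
#' @param items numeric vector of length 36 (raw codes, item order 1..36), or
#'   a matrix / data frame with 36 columns for many subjects.
#' @return tibble with the eight domain scores in `[0,100]` (higher =
#'   better HRQoL).
#' @export
score_sf36 <- function(items) {
  if (is.null(dim(items))) items <- t(as.matrix(items))
  items <- as.matrix(items)
  if (ncol(items) != 36) stop("score_sf36(): expected 36 item columns")
  rec <- sf36_recode_table()
  scored <- matrix(NA_real_, nrow(items), 36)
  for (j in 1:36) {
    raw <- items[, j]
    ok <- is.na(raw) | (raw >= 1 & raw <= length(rec[[j]]) & raw == round(raw))
    if (!all(ok)) {
      stop(sprintf("score_sf36(): out-of-range raw code for item %d", j))
    }
    scored[, j] <- rec[[j]][raw]
  }
  di <- sf36_domain_items()
  out <- lapply(di, function(ix) {
    rowMeans(scored[, ix, drop = FALSE], na.rm = TRUE)
  })
  out <- lapply(out, function(v) ifelse(is.nan(v), NA_real_, v))
  tibble::as_tibble(out)[, SF36_DOMAINS]
}

two_factor_lambda <- function(par) {
  lam <- matrix(0, 8, 2, dimnames = list(SF36_DOMAINS, c("physical",
                                                         "mental")))
  lam[PHYSICAL_DOMAINS, 1] <- par[match(PHYSICAL_DOMAINS, SF36_DOMAINS)]
  lam[MENTAL_DOMAINS, 2] <- par[match(MENTAL_DOMAINS, SF36_DOMAINS)]
  lam
}

#' Fit the fixed-structure two-factor model to SF-36 domain scores
#'
#' Confirmatory two-correlated-factor model with simple structure (physical:
#' physical functioning, role physical, bodily pain, general health; mental:
#' mental health, role emotional, social functioning, vitality), fitted by
#' maximum likelihood on the 8x8 covariance of the standardized domains
#' (i.e., the correlation matrix, so the returned loadings are standardized).
#' Per-subject factor scores use the regression (Thomson) method and are
#' standardized to mean 0, SD 1 on the fitting sample.
#'
#' @param domains data frame / matrix with the eight domain columns (named as
#'   in `score_sf36()` output); rows with any missing domain are dropped for
#'   fitting and receive NA scores.
#' @param max_iter optimiser iteration cap (default 1000).
#' @return object of class `two_factor_fit`: `loadings` (8x2), `phi` (factor
#'   correlation), `uniqueness`, `scores` (n x 2 tibble `physical`,
#'   `mental`), `logLik`, `n`, `heywood` flag, `converged`.
#' @export
fit_two_factor <- function(domains, max_iter = 1000) {
  domains <- as.data.frame(domains)[, SF36_DOMAINS]
  cc <- complete.cases(domains)
  x <- as.matrix(domains[cc, ])
  n <- nrow(x)
  if (n < 50) stop("fit_two_factor(): need at least 50 complete rows")
  if (any(apply(x, 2, sd) == 0)) {
    stop("fit_two_factor(): a domain is constant; model not estimable")
  }
  z <- scale(x)
  S <- crossprod(z) / n  # MLE covariance of standardized domains
  psi_floor <- 1e-3
  unpack <- function(par) {
    lam <- two_factor_lambda(par[1:8])
    psi <- exp(par[9:16]) + psi_floor
    rho <- tanh(par[17])
    phi <- matrix(c(1, rho, rho, 1), 2, 2)
    sigma <- lam %*% phi %*% t(lam) + diag(psi)
    list(lam = lam, psi = psi, rho = rho, sigma = sigma)
  }
  fml <- function(par) {
    p <- unpack(par)
    ev <- eigen(p$sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) return(1e10)
    as.numeric(determinant(p$sigma)$modulus -
                 determinant(S)$modulus +
                 sum(diag(solve(p$sigma, S))) - 8)
  }
  start <- c(rep(0.7, 8), rep(log(0.5), 8), atanh(0.4))
  opt <- optim(start, fml, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop(sprintf(paste("fit_two_factor(): ML optimisation did not converge",
                       "(code %d, discrepancy %.4g); inspect the domain",
                       "covariance for near-singularity"),
                 opt$convergence, opt$value))
  }
  p <- unpack(opt$par)
  # sign convention: loadings positive on their own factor (flipping a
  # factor's sign requires flipping its correlation with the other factor)
  sgn <- ifelse(colSums(p$lam) < 0, -1, 1)
  p$lam <- sweep(p$lam, 2, sgn, `*`)
  p$rho <- p$rho * sgn[1] * sgn[2]
  heywood <- any(p$psi <= psi_floor + 1e-6)
  if (heywood) {
    warning("fit_two_factor(): Heywood case; uniqueness floored at 0.001")
  }
  ll <- -n / 2 * (8 * log(2 * pi) +
                    as.numeric(determinant(p$sigma)$modulus) +
                    sum(diag(solve(p$sigma, S))))
  # regression-method factor scores on the fitting sample
  phi <- matrix(c(1, p$rho, p$rho, 1), 2, 2)
  B <- solve(p$sigma, p$lam %*% phi)   # 8 x 2
  f <- z %*% B
  f <- scale(f)
  scores <- tibble::tibble(physical = rep(NA_real_, nrow(domains)),
                           mental = NA_real_)
  scores$physical[cc] <- f[, 1]
  scores$mental[cc] <- f[, 2]
  structure(
    list(loadings = p$lam, phi = p$rho, uniqueness = setNames(p$psi,
                                                              SF36_DOMAINS),
         scores = scores, logLik = ll, n = n, discrepancy = opt$value,
         heywood = heywood, converged = TRUE,
         center = attr(z, "scaled:center"), scale = attr(z, "scaled:scale")),
    class = "two_factor_fit"
  )
}

#' @export
print.two_factor_fit <- function(x, ...) {
  cat(sprintf("<two_factor_fit> n = %d, factor correlation = %.3f%s\n",
              x$n, x$phi, if (x$heywood) " [Heywood]" else ""))
  print(round(x$loadings, 3))
  invisible(x)
}
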