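# Independent oracle implementations used to cross-check the package.
# These deliberately take different computational routes than the package
# code (loops, closed forms, generic optimizers) so agreement is evidence,
# not tautology.

# Brute-force weighted quantile: scan the cumulative weight distribution.
oracle_weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  total <- sum(w)
  acc <- 0
  for (i in seq_along(x)) {
    acc <- acc + w[i]
    if (acc / total >= p - 1e-12) return(x[i])
  }
  x[length(x)]
}

# Hand Taylor linearization for the SRS special case: each child its own
# cluster, single stratum.
oracle_srs_ratio_se <- function(y, w) {
  W <- sum(w)
  p <- sum(w * y) / W
  z <- w * (y - p)
  n <- length(y)
  sqrt(n / (n - 1) * sum((z - mean(z))^2)) / W * 100
}

# Weighted logistic maximum likelihood via a generic optimizer (BFGS with
# analytic gradient), reported on the SII scale.
oracle_sii_ml <- function(y, r, w = rep(1, length(y))) {
  nll <- function(b) {
    eta <- b[1] + b[2] * r
    -sum(w * (y * eta - log1p(exp(eta))))
  }
  grad <- function(b) {
    mu <- plogis(b[1] + b[2] * r)
    -c(sum(w * (y - mu)), sum(w * r * (y - mu)))
  }
  fit <- optim(c(0, 0), nll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  p0 <- plogis(fit$par[1]); p1 <- plogis(sum(fit$par))
  100 * (p1 - p0)
}

# Closed-form OLS slope from the normal equations.
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Brute-force Spearman rho: all-pairs covariance of average ranks.
oracle_spearman <- function(a, b) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  ra <- avg_rank(a); rb <- avg_rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Build an individual-level child table from grouped quintile counts.
# cases[g] of n[g] children in quintile g are stunted; one cluster per
# child unless cluster ids are supplied.
grouped_children <- function(n, cases, weights = NULL, survey_id = "S1") {
  stopifnot(length(n) == 5, length(cases) == 5, all(cases <= n))
  q <- rep(1:5, n)
  y <- unlist(lapply(1:5, function(g) rep(c(TRUE, FALSE), c(cases[g], n[g] - cases[g]))))
  total <- sum(n)
  data.frame(
    child_id = sprintf("k%04d", seq_len(total)),
    survey_id = survey_id,
    cluster_id = sprintf("c%04d", seq_len(total)),
    household_id = sprintf("h%04d", seq_len(total)),
    age_months = 24L, sex = "female",
    haz = ifelse(y, -2.5, 0),
    weight = if (is.null(weights)) rep(1, total) else rep(weights, n),
    stunted = y,
    wealth_quintile = q,
    haz_missing = FALSE, haz_implausible = FALSE,
    stringsAsFactors = FALSE
  )
}

# Minimal valid survey metadata table.
make_surveys <- function(ids, iso, years, ceiling = 60L, source = "DHS") {
  data.frame(survey_id = ids, country_iso3 = iso, year = years,
             source = source, age_ceiling_months = ceiling,
             stringsAsFactors = FALSE)
}
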