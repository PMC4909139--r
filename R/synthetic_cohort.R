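# Synthetic multi-country survey generator with closed-form ground truth.
#
# Each survey is a two-stage clustered sample: clusters (primary sampling
# units) carry a shared random intercept on height-for-age, households carry
# a latent wealth variable that drives both asset ownership and HAZ, and
# sampling weights differ by stratum. Wealth enters HAZ through its
# within-survey fractional rank, so the true prevalence-versus-rank curve --
# and hence the true SII and CIX -- has closed form:
#
#   HAZ = beta0 + beta1 * F(w) + gamma * (year - year0) + b_cluster + eps
#   p(r) = Phi((-2 - mu(r)) / sqrt(sigma^2 + tau^2)),  mu(r) = beta0 + beta1*r + gamma*dt
#
# The shared cluster effect makes naive (independence) standard errors
# anticonservative on purpose: it gives the design-based variance code a
# real signal to detect.

#' Specification of one synthetic country
#'
#' @param iso3 three-letter label for the synthetic country.
#' @param years numeric vector of survey midpoint years.
#' @param n_clusters clusters (primary sampling units) per survey.
#' @param hh_per_cluster households sampled per cluster.
#' @param kids_per_hh mean number of measured children per household
#'   (1 plus a Poisson overage).
#' @param beta0 HAZ intercept at rank 0 in the base year (z units).
#' @param beta1 wealth gradient: HAZ difference between rank 1 and rank 0
#'   (z units); positive means wealthier children are taller.
#' @param gamma secular trend in HAZ (z units per year).
#' @param tau SD of the shared cluster random intercept (z units).
#' @param sigma residual SD (z units).
#' @param age_ceiling_months 60 (under-5) or 36 (under-3) analysis range.
#' @param source survey program label, "DHS" or "MICS".
#' @return a `country_spec` list.
#' @export
country_spec <- function(iso3, years, n_clusters = 40L, hh_per_cluster = 12L,
                         kids_per_hh = 1.6, beta0 = -1.4, beta1 = 0.9,
                         gamma = 0.02, tau = 0.25, sigma = 0.95,
                         age_ceiling_months = 60L, source = "DHS") {
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  if (kids_per_hh < 1) stop("kids_per_hh must be >= 1")
  if (!age_ceiling_months %in% c(36L, 60L)) stop("age_ceiling_months must be 36 or 60")
  structure(list(iso3 = iso3, years = sort(years), n_clusters = as.integer(n_clusters),
                 hh_per_cluster = as.integer(hh_per_cluster), kids_per_hh = kids_per_hh,
                 beta0 = beta0, beta1 = beta1, gamma = gamma, tau = tau, sigma = sigma,
                 age_ceiling_months = as.integer(age_ceiling_months), source = source),
            class = "country_spec")
}

#' Default simulation configuration
#'
#' Four synthetic countries with three to four surveys each, every country
#' spanning at least a decade, national stunting prevalence in roughly the
#' 10-60% band typical of repeated DHS/MICS series, and one under-3 country
#' mirroring the restricted age range some survey series analyse. Asset
#' loadings and stratum sampling fractions are shared across countries.
#'
#' @param seed integer seed governing all randomness downstream.
#' @return a `sim_config` list with elements `seed`, `year0`, `loadings`
#'   (asset-model loadings, one per indicator), `strata_weights` (sampling
#'   weight attached to each stratum) and `countries`.
#' @export
default_sim_config <- function(seed = 1L) {
  sim_config(
    seed = seed,
    countries = list(
      country_spec("SYA", c(1998, 2003, 2008, 2012), beta0 = -1.7, beta1 = 1.1, gamma = 0.025),
      country_spec("SYB", c(2000, 2006, 2011), beta0 = -1.3, beta1 = 0.8, gamma = 0.015),
      country_spec("SYC", c(1997, 2002, 2012), beta0 = -1.0, beta1 = 0.6, gamma = 0.010,
                   age_ceiling_months = 36L, source = "MICS"),
      country_spec("SYD", c(2000, 2010), beta0 = -1.5, beta1 = 1.3, gamma = 0.030)
    )
  )
}

#' Build a simulation configuration
#'
#' @param seed integer seed.
#' @param countries list of [country_spec()] objects.
#' @param year0 base year for the secular HAZ trend.
#' @param loadings logistic loadings of the binary asset indicators on the
#'   latent household wealth.
#' @param strata_weights sampling weights by stratum (inverse sampling
#'   fractions); clusters alternate between strata.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, countries, year0 = 2000,
                       loadings = c(2.0, 1.6, 1.4, 1.2, 1.0, 0.9, 0.8, 0.7, 0.6, 0.5),
                       strata_weights = c(1.0, 2.5)) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is required")
  if (any(strata_weights <= 0)) stop("strata_weights must be positive")
  structure(list(seed = as.integer(seed), year0 = year0, loadings = loadings,
                 strata_weights = strata_weights, countries = countries),
            class = "sim_config")
}

#' Simulate one national survey
#'
#' @param config a [sim_config()].
#' @param country a [country_spec()] (usually an element of
#'   `config$countries`).
#' @param year survey midpoint year.
#' @param seed integer seed for this survey.
#' @return list with `children`, `households`, `survey` (one-row metadata)
#'   and `truth` (one-row ground-truth table, see [true_inequality()]).
#' @export
simulate_survey <- function(config, country, year, seed) {
  set.seed(seed)
  sid <- sprintf("%s%d", country$iso3, round(year))
  n_cl <- country$n_clusters
  n_hh <- n_cl * country$hh_per_cluster
  hh_cluster <- rep(seq_len(n_cl), each = country$hh_per_cluster)
  # clusters alternate between two sampling strata with unequal weights
  stratum <- rep_len(c(1L, 2L), n_cl)[hh_cluster]

  w_latent <- rnorm(n_hh)
  rank_w <- (rank(w_latent, ties.method = "first") - 0.5) / n_hh
  K <- length(config$loadings)
  assets <- vapply(seq_len(K), function(k) {
    rbinom(n_hh, 1L, plogis(config$loadings[k] * w_latent))
  }, integer(n_hh))
  colnames(assets) <- sprintf("asset_%02d", seq_len(K))
  hh_id <- sprintf("h%05d", seq_len(n_hh))
  households <- data.frame(household_id = hh_id, survey_id = sid,
                           assets, latent_wealth = w_latent,
                           stringsAsFactors = FALSE)

  n_kids <- 1L + rpois(n_hh, country$kids_per_hh - 1)
  child_hh <- rep(seq_len(n_hh), n_kids)
  n_child <- length(child_hh)
  cluster_effect <- rnorm(n_cl, 0, country$tau)
  dt <- year - config$year0
  haz <- country$beta0 + country$beta1 * rank_w[child_hh] + country$gamma * dt +
    cluster_effect[hh_cluster[child_hh]] + rnorm(n_child, 0, country$sigma)
  children <- data.frame(
    child_id = sprintf("%s_k%06d", sid, seq_len(n_child)),
    survey_id = sid,
    cluster_id = sprintf("%s_c%03d", sid, hh_cluster[child_hh]),
    household_id = hh_id[child_hh],
    age_months = sample.int(country$age_ceiling_months, n_child, replace = TRUE) - 1L,
    sex = sample(c("male", "female"), n_child, replace = TRUE),
    haz = round(haz, 4),
    weight = config$strata_weights[stratum[child_hh]],
    stringsAsFactors = FALSE
  )
  survey <- data.frame(survey_id = sid, country_iso3 = country$iso3, year = year,
                       source = country$source,
                       age_ceiling_months = country$age_ceiling_months,
                       stringsAsFactors = FALSE)
  truth <- true_inequality(country, years_from_base = dt)
  truth <- data.frame(survey_id = sid, country_iso3 = country$iso3, year = year,
                      t(unlist(truth)), stringsAsFactors = FALSE)
  list(children = children, households = households, survey = survey, truth = truth)
}

#' Simulate the full multi-country cohort
#'
#' Runs [simulate_survey()] for every (country, year) in the configuration
#' with a per-survey seed derived deterministically from `config$seed`, so
#' the output tables are reproduced byte-for-byte under the same
#' configuration.
#'
#' @param config a [sim_config()].
#' @return list of four data.frames: `children`, `households`, `surveys`,
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  out <- list(children = list(), households = list(), surveys = list(), truth = list())
  i <- 0L
  for (country in config$countries) {
    for (year in country$years) {
      i <- i + 1L
      sv <- simulate_survey(config, country, year, seed = derive_seed(config$seed, i))
      out$children[[i]] <- sv$children
      out$households[[i]] <- sv$households
      out$surveys[[i]] <- sv$survey
      out$truth[[i]] <- sv$truth
    }
  }
  lapply(out, function(x) do.call(rbind, x))
}

#' Ground-truth prevalence and inequality for a simulated survey
#'
#' Evaluates the closed-form prevalence-versus-rank curve
#' p(r) = Phi((-2 - mu(r)) / sqrt(sigma^2 + tau^2)) implied by the HAZ model
#' and derives from it the national prevalence (its integral over rank), the
#' true SII (100 times the endpoint difference p(1) - p(0)) and the true CIX
#' (from the concentration integral, via [cix_quadrature()]).
#'
#' @param country a [country_spec()] holding the HAZ model parameters.
#' @param years_from_base years elapsed since the trend base year.
#' @return list with `national`, `p_rank0`, `p_rank1` (proportions in
#'   percent), `sii` (percentage points) and `cix` (-100..100).
#' @export
true_inequality <- function(country, years_from_base = 0) {
  s_tot <- sqrt(country$sigma^2 + country$tau^2)
  p_of_rank <- function(r) {
    mu <- country$beta0 + country$beta1 * r + country$gamma * years_from_base
    pnorm((-2 - mu) / s_tot)
  }
  p0 <- p_of_rank(0); p1 <- p_of_rank(1)
  national <- integrate(p_of_rank, 0, 1, rel.tol = 1e-10)$value
  list(national = 100 * national,
       p_rank0 = 100 * p0,
       p_rank1 = 100 * p1,
       sii = 100 * (p1 - p0),
       cix = cix_quadrature(p_of_rank))
}

#' Concentration index of a prevalence-versus-rank curve by quadrature
#'
#' For a prevalence curve p(r) over the fractional wealth rank r in \[0,1\],
#' the relative concentration index is 2 cov(p, r) / mean(p), i.e.
#' 100 * (2 * int r p(r) dr / int p(r) dr - 1) since the mean rank is 1/2.
#' Negative values mean the burden concentrates among the poor.
#'
#' @param p_of_rank vectorized function of rank returning prevalence as a
#'   proportion.
#' @return CIX on the -100..100 scale.
#' @export
#' @examples
#' cix_quadrature(function(r) rep(0.2, length(r)))  # 0: flat curve
cix_quadrature <- function(p_of_rank) {
  den <- integrate(p_of_rank, 0, 1, rel.tol = 1e-10)$value
  if (den <= 0) stop("prevalence curve integrates to zero; CIX undefined")
  num <- integrate(function(r) r * p_of_rank(r), 0, 1, rel.tol = 1e-10)$value
  100 * (2 * num / den - 1)
}
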