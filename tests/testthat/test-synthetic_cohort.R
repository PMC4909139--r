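test_that("simulation is byte-identical under a fixed seed", {
  cfg <- default_sim_config(123L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(default_sim_config(124L))
  expect_false(identical(a$children$haz, c2$children$haz))
})

test_that("invalid model parameters are rejected", {
  expect_error(country_spec("XXX", c(2000, 2010), sigma = 0), "sigma")
  expect_error(country_spec("XXX", c(2000, 2010), tau = -1), "tau")
  expect_error(country_spec("XXX", c(2000, 2010), kids_per_hh = 0.5), "kids_per_hh")
  expect_error(sim_config(seed = 1, countries = list(), strata_weights = c(0, 1)),
               "positive")
})

test_that("closed-form ground truth matches the normal-CDF oracle", {
  # mu(r) = -1.20 + 1.05 r with total SD 1 puts the stunting threshold at
  # -2: p(0) = Phi(-0.80), p(1) = Phi(-1.85)
  spec <- country_spec("XXX", c(2000, 2010), beta0 = -1.20, beta1 = 1.05,
                       gamma = 0, tau = 0.6, sigma = 0.8)
  truth <- true_inequality(spec)
  expect_equal(truth$p_rank0, 100 * pnorm(-0.80), tolerance = 1e-10)
  expect_equal(truth$p_rank1, 100 * pnorm(-1.85), tolerance = 1e-10)
  expect_equal(truth$sii, 100 * (pnorm(-1.85) - pnorm(-0.80)), tolerance = 1e-10)
  # positive wealth gradient in HAZ => negative stunting SII
  expect_lt(truth$sii, 0)
})

test_that("quadrature CIX reproduces flat and linear prevalence curves", {
  expect_equal(cix_quadrature(function(r) rep(0.2, length(r))), 0, tolerance = 1e-8)
  # linear p(r) = 0.5 - 0.4 r: 2*(int r p)/int p - 1 = 2*(7/60)/0.3 - 1
  expect_equal(cix_quadrature(function(r) 0.5 - 0.4 * r),
               100 * (2 * (7 / 60) / 0.3 - 1), tolerance = 1e-8)
  expect_equal(cix_quadrature(function(r) 0.5 - 0.4 * r), -22.2222, tolerance = 1e-4)
})

test_that("simulated prevalence converges to the configured truth at large n", {
  spec <- country_spec("BIG", 2000, n_clusters = 500L, hh_per_cluster = 80L,
                       kids_per_hh = 1.5, beta0 = -1.20, beta1 = 1.05,
                       gamma = 0, tau = 0.6, sigma = 0.8)
  cfg <- sim_config(seed = 77L, countries = list(spec))
  sv <- simulate_survey(cfg, spec, 2000, seed = 77L)
  ch <- sv$children
  n <- nrow(ch)
  expect_gt(n, 5e4)
  r <- rep(NA_real_, n)
  hh_rank <- (rank(sv$households$latent_wealth, ties.method = "first") - 0.5) /
    nrow(sv$households)
  r <- hh_rank[match(ch$household_id, sv$households$household_id)]
  # bottom and top fifths of the rank distribution vs the oracle CDF values
  p_lo <- mean(ch$haz[r < 0.2] < -2)
  p_hi <- mean(ch$haz[r > 0.8] < -2)
  oracle_lo <- integrate(function(x) pnorm(-2, -1.20 + 1.05 * x, 1), 0, 0.2)$value / 0.2
  oracle_hi <- integrate(function(x) pnorm(-2, -1.20 + 1.05 * x, 1), 0.8, 1)$value / 0.2
  mc_se <- function(p, m) sqrt(p * (1 - p) / m)
  # 3 MC SEs plus slack for the shared cluster effects
  expect_lt(abs(p_lo - oracle_lo), 4 * mc_se(oracle_lo, sum(r < 0.2)) + 0.01)
  expect_lt(abs(p_hi - oracle_hi), 4 * mc_se(oracle_hi, sum(r > 0.8)) + 0.01)
  # configured moments within 3 MC SEs; the shared cluster effects dominate
  # the uncertainty of the mean (500 effective draws, not 60k)
  se_mean <- sqrt(0.6^2 / 500 + (0.8^2 + 1.05^2 / 12) / n)
  expect_lt(abs(mean(ch$haz) - (-1.20 + 1.05 * 0.5)), 3 * se_mean)
  expect_equal(sd(ch$haz), sqrt(1.05^2 / 12 + 0.6^2 + 0.8^2), tolerance = 0.03)
})

test_that("degenerate gradients behave as expected", {
  # no wealth gradient, no clustering: quintile prevalences near-equal, CIX near 0
  spec <- country_spec("FLA", 2000, n_clusters = 200L, hh_per_cluster = 30L,
                       beta0 = -1.5, beta1 = 0, gamma = 0, tau = 0, sigma = 1)
  cfg <- sim_config(seed = 31L, countries = list(spec))
  sv <- simulate_survey(cfg, spec, 2000, seed = 31L)
  truth <- true_inequality(spec)
  expect_equal(truth$sii, 0, tolerance = 1e-12)
  expect_equal(truth$cix, 0, tolerance = 1e-8)
  hh <- score_households(sv$households, use_precomputed = FALSE)
  ch <- validate_children(sv$children)
  ch <- assign_quintiles(ch, hh)
  est <- cix(ch$stunted, fractional_ranks(ch), ch$weight)
  expect_lt(abs(est$value), 4)  # ~3 MC SEs at this n
  # mass far below the threshold: everyone stunted
  spec2 <- country_spec("ALL", 2000, n_clusters = 20L, beta0 = -2 - 5, beta1 = 0,
                        gamma = 0, tau = 0, sigma = 1)
  sv2 <- simulate_survey(cfg, spec2, 2000, seed = 32L)
  expect_true(all(sv2$children$haz < -2))
})
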