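test_that("midpoint ranks follow the cumulative-share construction", {
  expect_equal(midpoint_ranks(rep(0.2, 5)), c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(midpoint_ranks(c(0.5, 0.5)), c(0.25, 0.75))
  expect_equal(midpoint_ranks(c(0.1, 0.2, 0.3, 0.4)), c(0.05, 0.20, 0.45, 0.80))
  expect_error(midpoint_ranks(c(-0.1, 1.1)), "non-negative")
})

test_that("fractional ranks have weighted mean 1/2 and respect the wealth order", {
  set.seed(3)
  ch <- grouped_children(c(30, 25, 20, 15, 10), c(9, 6, 4, 2, 1),
                         weights = c(2, 1.5, 1, 1, 0.5))
  r <- fractional_ranks(ch)
  expect_equal(weighted.mean(r, ch$weight), 0.5, tolerance = 1e-9)
  expect_true(all(diff(r[order(ch$wealth_quintile)]) >= 0))
  # continuous mode on distinct scores gives per-child midpoints
  ch$wealth_score <- seq_len(nrow(ch))
  rc <- fractional_ranks(ch, mode = "continuous")
  expect_equal(weighted.mean(rc, ch$weight), 0.5, tolerance = 1e-9)
  expect_true(all(diff(rc[order(ch$wealth_score)]) > 0))
})

test_that("CIX: flat quintiles give exactly zero; textbook gradient gives -26.67", {
  flat <- grouped_children(rep(20, 5), rep(4, 5))
  est <- cix(flat$stunted, fractional_ranks(flat), flat$weight)
  expect_equal(est$value, 0, tolerance = 1e-12)
  grad <- grouped_children(rep(100, 5), c(50, 40, 30, 20, 10))
  est2 <- cix(grad$stunted, fractional_ranks(grad), grad$weight)
  expect_equal(est2$value, -26.6667, tolerance = 1e-4)
  expect_equal(est2$value, cix_trapezoid(rep(0.2, 5), c(50, 40, 30, 20, 10)),
               tolerance = 1e-10)
})

test_that("covariance and trapezoid CIX formulations agree to 1e-10 on grouped data", {
  set.seed(8)
  for (i in 1:20) {
    shares <- as.vector(rmultinom(1, 200, runif(5, 0.5, 1.5))) / 200
    prev <- runif(5, 0.05, 0.6)
    n <- round(shares * 400) + 1
    cases <- round(prev * n)
    ch <- grouped_children(n, cases, weights = rep(1, 5))
    est <- cix(ch$stunted, fractional_ranks(ch), ch$weight)
    expect_equal(est$value, cix_trapezoid(n / sum(n), cases / n), tolerance = 1e-10)
  }
})

test_that("CIX approaches -100 when all cases sit in the poorest sliver", {
  n <- 10000
  y <- c(rep(TRUE, 5), rep(FALSE, n - 5))
  score <- seq_len(n)
  ch <- data.frame(survey_id = "S1", weight = 1, wealth_score = score,
                   stunted = y)
  r <- fractional_ranks(ch, mode = "continuous")
  est <- cix(ch$stunted, r, ch$weight)
  expect_lt(est$value, -99.8)
  expect_gte(est$value, -100)
})

test_that("CIX invariances and degenerate input handling", {
  ch <- grouped_children(rep(50, 5), c(20, 15, 10, 8, 2))
  r <- fractional_ranks(ch)
  base <- cix(ch$stunted, r, ch$weight)$value
  expect_equal(cix(ch$stunted, r, ch$weight * 12)$value, base, tolerance = 1e-12)
  # sign equals the sign of the outcome-rank covariance
  expect_equal(sign(base), sign(cov(as.numeric(ch$stunted), r)))
  # zero prevalence is flagged undefined
  none <- grouped_children(rep(5, 5), rep(0, 5))
  est0 <- cix(none$stunted, fractional_ranks(none), none$weight)
  expect_true(is.na(est0$value))
  expect_match(est0$flags, "zero_prevalence")
})

test_that("logistic SII equals an independent ML-oracle fit on grouped data", {
  ch <- grouped_children(n = rep(100, 5), cases = c(30, 24, 18, 12, 6))
  r <- fractional_ranks(ch)
  est <- sii_logistic(ch$stunted, r, ch$weight)
  expect_equal(est$value, oracle_sii_ml(as.numeric(ch$stunted), r), tolerance = 1e-6)
  expect_lt(est$value, 0)
  # weighted case against the weighted oracle
  chw <- grouped_children(rep(60, 5), c(20, 12, 9, 5, 2),
                          weights = c(2, 1.5, 1, 1, 0.5))
  rw <- fractional_ranks(chw)
  estw <- sii_logistic(chw$stunted, rw, chw$weight)
  expect_equal(estw$value,
               oracle_sii_ml(as.numeric(chw$stunted), rw, chw$weight / mean(chw$weight)),
               tolerance = 1e-6)
})

test_that("SII edge cases: flat gradient, constant outcome, separation", {
  flat <- grouped_children(rep(40, 5), rep(8, 5))
  est <- sii_logistic(flat$stunted, fractional_ranks(flat), flat$weight)
  expect_equal(est$value, 0, tolerance = 1e-8)
  const <- grouped_children(rep(10, 5), rep(0, 5))
  estc <- sii_logistic(const$stunted, fractional_ranks(const), const$weight)
  expect_equal(estc$value, 0)
  expect_true(is.na(estc$se))
  expect_match(estc$flags, "constant_outcome")
  # perfect separation: poorest all stunted, others none
  sep <- grouped_children(rep(20, 5), c(20, 0, 0, 0, 0))
  ests <- sii_logistic(sep$stunted, fractional_ranks(sep), sep$weight)
  expect_match(ests$flags, "separation_penalized")
  expect_true(is.finite(ests$value))
})

test_that("logistic and linear SII agree within 1 pp on linear-in-rank data", {
  set.seed(14)
  n <- 20000
  r <- runif(n)
  y <- rbinom(n, 1, 0.35 - 0.2 * r)
  est <- sii_logistic(y, r)
  linear <- 100 * unname(coef(lm(y ~ r))[2])
  expect_lt(abs(est$value - linear), 1)
})

test_that("SII/CIX recover simulator ground truth within Monte-Carlo error", {
  spec <- country_spec("REC", 2000, n_clusters = 150L, hh_per_cluster = 15L,
                       beta0 = -1.3, beta1 = 1.0, gamma = 0, tau = 0.2, sigma = 0.98)
  cfg <- sim_config(seed = 17L, countries = list(spec))
  sv <- simulate_survey(cfg, spec, 2000, seed = 17L)
  truth <- true_inequality(spec)
  ch <- validate_children(sv$children)
  hh <- score_households(sv$households, use_precomputed = FALSE)
  ch <- assign_quintiles(ch, hh)
  r <- fractional_ranks(ch)
  sii_est <- sii_logistic(ch$stunted, r, ch$weight, ch$cluster_id)
  cix_est <- cix(ch$stunted, r, ch$weight, ch$cluster_id)
  expect_lt(abs(sii_est$value - truth$sii), 3 * sii_est$se)
  expect_lt(abs(cix_est$value - truth$cix), 3 * cix_est$se)
})

test_that("simple and change measures reproduce the canonical worked numbers", {
  sm_early <- simple_measures(50, 10)
  expect_equal(sm_early$value[sm_early$metric == "Q1_Q5_DIFF"], 40)
  expect_equal(sm_early$value[sm_early$metric == "Q1_Q5_RATIO"], 5)
  sm_late <- simple_measures(30, 5)
  expect_equal(sm_late$value[sm_late$metric == "Q1_Q5_RATIO"], 6)
  expect_equal(simple_measures(25, 25)$value, c(0, 1))
  zero <- simple_measures(25, 0)
  expect_true(is.na(zero$value[zero$metric == "Q1_Q5_RATIO"]))
  expect_match(zero$flags[2], "undefined_ratio")

  poor <- change_measures(50, 30)
  expect_equal(poor$absolute_pp, -20)
  expect_equal(poor$relative_pct, -40)
  rich <- change_measures(10, 5)
  expect_equal(rich$absolute_pp, -5)
  expect_equal(rich$relative_pct, -50)
  expect_equal(change_measures(17, 17), list(absolute_pp = 0, relative_pct = 0, flags = ""))
  expect_match(change_measures(0, 5)$flags, "undefined_relative_change")
})
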