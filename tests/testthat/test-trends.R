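test_that("decade change matches closed-form OLS and two-point slopes", {
  expect_equal(decade_change(c(2000, 2010), c(40, 30))$change_per_decade, -10)
  expect_equal(decade_change(c(2000, 2005, 2010), c(40, 35, 30))$change_per_decade,
               -10, tolerance = 1e-12)
  yrs <- c(2000, 2004, 2010); vals <- c(44, 40, 29)
  dc <- decade_change(yrs, vals)
  expect_equal(dc$change_per_decade, 10 * oracle_ols_slope(yrs, vals), tolerance = 1e-10)
  expect_equal(dc$n_surveys, 3)
  expect_error(decade_change(2005, 30), "at least two")
  expect_error(decade_change(c(2005, 2005), c(30, 31)), "distinct")
  # exactly two points: slope p undefined, left to the extremes test
  expect_true(is.na(decade_change(c(2000, 2010), c(40, 30))$p_slope))
})

test_that("decade change is shift-equivariant in year and scale-equivariant in value", {
  set.seed(2)
  yrs <- c(1997, 2002, 2006, 2011)
  vals <- c(48, 41, 43, 33)
  base <- decade_change(yrs, vals)
  shifted <- decade_change(yrs + 13, vals)
  expect_equal(shifted$change_per_decade, base$change_per_decade, tolerance = 1e-10)
  scaled <- decade_change(yrs, vals * 2.5)
  expect_equal(scaled$change_per_decade, 2.5 * base$change_per_decade, tolerance = 1e-10)
})

test_that("earliest-vs-latest test has the documented normal-reference behaviour", {
  expect_equal(extremes_ttest(30, 2, 30, 3)$p_value, 1)
  ses <- c(2, 3)
  diff <- 1.96 * sqrt(sum(ses^2))
  expect_equal(extremes_ttest(30, 2, 30 + diff, 3)$p_value, 0.05, tolerance = 1e-3)
  tt <- extremes_ttest(40, 2, 30, 2)
  expect_equal(tt$statistic, -10 / sqrt(8), tolerance = 1e-3)
  expect_equal(tt$statistic, -3.536, tolerance = 1e-3)
  expect_equal(tt$p_value, 2 * pnorm(-10 / sqrt(8)), tolerance = 1e-12)
  # sign symmetry
  rev <- extremes_ttest(30, 2, 40, 2)
  expect_equal(rev$statistic, -tt$statistic)
  expect_equal(rev$p_value, tt$p_value)
  expect_error(extremes_ttest(30, 0, 40, 0), "undefined")
  expect_equal(extremes_ttest(30, 0, 30, 0)$p_value, 1)
})

test_that("Spearman decline correlations match a brute-force rank oracle", {
  d <- data.frame(a = 1:5, b = c(2, 4, 6, 8, 10))
  out <- decline_correlations(d)
  expect_equal(out$rho, 1)
  d2 <- data.frame(a = 1:5, b = rev(1:5))
  expect_equal(decline_correlations(d2)$rho, -1)
  # 6 countries with a tie in one column
  d3 <- data.frame(a = c(3.1, -2, 0.5, 0.5, 4, -1), b = c(2, -1, 1, 0, 5, -3))
  out3 <- decline_correlations(d3)
  expect_equal(out3$rho, oracle_spearman(d3$a, d3$b), tolerance = 1e-12)
  n <- 6; rho <- out3$rho
  expect_equal(out3$p_value, 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2),
               tolerance = 1e-12)
  # constant column flagged, not errored
  d4 <- data.frame(a = rep(1, 4), b = 1:4)
  out4 <- decline_correlations(d4)
  expect_true(is.na(out4$rho))
  expect_match(out4$flags, "undefined_correlation")
  expect_error(decline_correlations(data.frame(a = 1:2, b = 2:1)), "three")
})

test_that("country trends assemble per-indicator series with stars from the extremes test", {
  surveys <- make_surveys(c("X2000", "X2006", "X2011"), "XXA", c(2000, 2006, 2011))
  prevalence <- do.call(rbind, lapply(seq_along(surveys$survey_id), function(i) {
    data.frame(survey_id = surveys$survey_id[i],
               group = c("national", paste0("Q", 1:5)),
               prevalence = c(40, 55, 48, 40, 32, 22) - 6 * (i - 1),
               se = 1.2, n_children = 1000, n_clusters = 40, flags = "")
  }))
  inequality <- do.call(rbind, lapply(seq_along(surveys$survey_id), function(i) {
    data.frame(survey_id = surveys$survey_id[i],
               metric = c("SII", "CIX"),
               value = c(-30 + 4 * (i - 1), -20 + 2 * (i - 1)),
               se = 2, scale = "", flags = "")
  }))
  tr <- country_trends(prevalence, inequality, surveys)
  expect_setequal(unique(tr$indicator),
                  c("PREVALENCE_NATIONAL", "PREVALENCE_Q1", "PREVALENCE_Q5", "SII", "CIX"))
  nat <- tr[tr$indicator == "PREVALENCE_NATIONAL", ]
  # values fall 6 points per ~5.5 years: about -11 pp per decade
  expect_equal(nat$change_per_decade, 10 * oracle_ols_slope(surveys$year, c(40, 34, 28)),
               tolerance = 1e-10)
  expect_equal(nat$stars, "***")  # 12-point drop against se 1.2 on both ends
  sii <- tr[tr$indicator == "SII", ]
  expect_gt(sii$change_per_decade, 0)  # inequality narrowing
  # reporting layer: CIX sign flipped only in the scatter table
  sc <- sii_cix_change_table(tr)
  expect_equal(sc$d_cix_reported, -sc$d_cix)
  wide <- trend_table(tr)
  expect_equal(nrow(wide), 1)
  expect_match(wide$PREVALENCE_NATIONAL, "\\*\\*\\*$")
})

test_that("ineligible countries are dropped from trend estimation", {
  surveys <- rbind(
    make_surveys(c("A2000", "A2011"), "AAA", c(2000, 2011)),
    make_surveys(c("B2000", "B2007"), "BBB", c(2000, 2007)))
  prevalence <- data.frame(survey_id = surveys$survey_id, group = "national",
                           prevalence = c(40, 30, 35, 33), se = 2,
                           n_children = 500, n_clusters = 30, flags = "")
  inequality <- data.frame(survey_id = character(0), metric = character(0),
                           value = numeric(0), se = numeric(0),
                           scale = character(0), flags = character(0))
  tr <- country_trends(prevalence, inequality, surveys)
  expect_setequal(unique(tr$country_iso3), "AAA")
})
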