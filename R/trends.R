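# Decade-scale trends across repeated surveys: OLS of each indicator on
# survey year (one point per survey), slope expressed per 10-year interval,
# significance from a t test contrasting the earliest and latest surveys,
# and Spearman correlations between countries' rates of decline.

#' Change per decade of an indicator from repeated surveys
#'
#' Ordinary (unweighted) least-squares regression of the per-survey values
#' on survey year; the change per decade is 10 times the annual slope. With
#' exactly two surveys the slope is the two-point difference quotient and no
#' residual degrees of freedom remain, so the slope p-value is undefined --
#' significance then rests on the earliest-versus-latest test
#' ([extremes_ttest()]).
#'
#' @param year survey midpoint years (distinct).
#' @param value indicator value at each survey.
#' @return list: `change_per_decade`, `slope_se` (per decade), `p_slope`,
#'   `n_surveys`.
#' @export
#' @examples
#' decade_change(c(2000, 2010), c(40, 30))$change_per_decade  # -10
decade_change <- function(year, value) {
  if (length(year) < 2) stop("at least two surveys are required for a trend")
  if (anyDuplicated(year)) stop("survey years must be distinct")
  fit <- lm(value ~ year)
  sm <- summary(fit)$coefficients
  slope <- sm["year", "Estimate"]
  se <- if (length(year) > 2) sm["year", "Std. Error"] else NA_real_
  p <- if (length(year) > 2) sm["year", "Pr(>|t|)"] else NA_real_
  list(change_per_decade = 10 * slope,
       slope_se = 10 * se,
       p_slope = p,
       n_surveys = length(year))
}

#' Earliest-versus-latest significance test
#'
#' Two-sided test of the difference between the earliest and latest survey
#' estimates using their design-based standard errors:
#' z = (late - early) / sqrt(se_early^2 + se_late^2), referred to the
#' standard normal (survey standard errors carry large effective degrees of
#' freedom).
#'
#' @param early,late indicator values for the earliest and latest surveys.
#' @param se_early,se_late their standard errors.
#' @return list: `statistic`, `p_value`.
#' @export
extremes_ttest <- function(early, se_early, late, se_late) {
  if (!is.finite(se_early) || !is.finite(se_late) || se_early < 0 || se_late < 0) {
    stop("standard errors must be non-negative and finite")
  }
  if (se_early == 0 && se_late == 0) {
    if (early == late) return(list(statistic = 0, p_value = 1))
    stop("zero standard errors with unequal values: test undefined")
  }
  z <- (late - early) / sqrt(se_early^2 + se_late^2)
  list(statistic = z, p_value = 2 * pnorm(-abs(z)))
}

#' Spearman correlations among countries' rates of decline
#'
#' All pairwise Spearman rank correlations (average ranks for ties) among
#' the indicator-change columns, with p-values from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#'
#' @param changes data.frame of per-country changes; every numeric column is
#'   treated as an indicator.
#' @return data.frame: `indicator_a`, `indicator_b`, `rho`, `p_value`, `n`,
#'   `flags` (constant columns yield `NA` rho, flagged).
#' @export
decline_correlations <- function(changes) {
  num <- names(changes)[vapply(changes, is.numeric, logical(1))]
  if (nrow(changes) < 3) stop("at least three countries are required")
  pairs <- utils::combn(num, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- changes[[pairs[1, j]]]; b <- changes[[pairs[2, j]]]
    keep <- is.finite(a) & is.finite(b)
    a <- a[keep]; b <- b[keep]
    n <- length(a)
    if (n < 3 || length(unique(a)) < 2 || length(unique(b)) < 2) {
      return(data.frame(indicator_a = pairs[1, j], indicator_b = pairs[2, j],
                        rho = NA_real_, p_value = NA_real_, n = n,
                        flags = "undefined_correlation", stringsAsFactors = FALSE))
    }
    rho <- cor(rank(a), rank(b))
    p <- if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
    data.frame(indicator_a = pairs[1, j], indicator_b = pairs[2, j],
               rho = rho, p_value = p, n = n, flags = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-country decade trends in prevalence and inequality
#'
#' Assembles, for every eligible country, the per-survey series of national
#' prevalence, Q1 and Q5 prevalence, SII and CIX, and summarizes each as a
#' change per decade ([decade_change()]) with earliest-versus-latest
#' significance ([extremes_ttest()]).
#'
#' @param prevalence output of [prevalence_by_quintile()].
#' @param inequality output of [survey_inequality()].
#' @param surveys survey metadata table.
#' @param min_surveys,min_span eligibility rule passed to
#'   [select_eligible_countries()].
#' @return data.frame: `country_iso3`, `indicator`, `change_per_decade`,
#'   `slope_se`, `p_slope`, `p_extremes`, `n_surveys`, `stars` (from the
#'   earliest-versus-latest test).
#' @export
country_trends <- function(prevalence, inequality, surveys,
                           min_surveys = 2L, min_span = 10) {
  eligible <- select_eligible_countries(surveys, min_surveys, min_span)
  indicators <- c(PREVALENCE_NATIONAL = "national", PREVALENCE_Q1 = "Q1",
                  PREVALENCE_Q5 = "Q5", SII = "SII", CIX = "CIX")
  rows <- list()
  for (iso in eligible) {
    svy <- surveys[surveys$country_iso3 == iso, , drop = FALSE]
    svy <- svy[order(svy$year), , drop = FALSE]
    for (ind in names(indicators)) {
      key <- indicators[[ind]]
      if (ind %in% c("SII", "CIX")) {
        sub <- inequality[inequality$metric == key, , drop = FALSE]
      } else {
        sub <- prevalence[prevalence$group == key, , drop = FALSE]
        names(sub)[names(sub) == "prevalence"] <- "value"
      }
      m <- match(svy$survey_id, sub$survey_id)
      pts <- data.frame(year = svy$year, value = sub$value[m], se = sub$se[m])
      pts <- pts[is.finite(pts$value), , drop = FALSE]
      if (nrow(pts) < 2) next
      dc <- decade_change(pts$year, pts$value)
      first <- pts[1, ]; last <- pts[nrow(pts), ]
      p_ext <- if (is.finite(first$se) && is.finite(last$se) &&
                   (first$se > 0 || last$se > 0)) {
        extremes_ttest(first$value, first$se, last$value, last$se)$p_value
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        country_iso3 = iso, indicator = ind,
        change_per_decade = dc$change_per_decade, slope_se = dc$slope_se,
        p_slope = dc$p_slope, p_extremes = p_ext, n_surveys = dc$n_surveys,
        stars = signif_stars(p_ext), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render trends as a wide country-by-indicator table
#'
#' One row per country; per indicator the change per decade with
#' significance stars from the earliest-versus-latest test (* p<0.05,
#' ** p<0.01, *** p<0.001).
#'
#' @param trends output of [country_trends()].
#' @param digits rounding for display.
#' @return wide data.frame of formatted strings.
#' @export
trend_table <- function(trends, digits = 1) {
  countries <- unique(trends$country_iso3)
  inds <- unique(trends$indicator)
  out <- data.frame(country_iso3 = countries, stringsAsFactors = FALSE)
  for (ind in inds) {
    sub <- trends[trends$indicator == ind, , drop = FALSE]
    m <- match(countries, sub$country_iso3)
    out[[ind]] <- ifelse(is.na(m), "",
                         paste0(formatC(round(sub$change_per_decade[m], digits),
                                        format = "f", digits = digits),
                                sub$stars[m]))
  }
  out
}

#' Paired changes in absolute and relative inequality
#'
#' Scatter-style table of (change in SII, change in CIX) per country. For
#' readability the CIX change is also reported multiplied by -1 (stunting
#' CIX values are negative, so a positive sign then means equity improved);
#' this sign flip lives only here, in the reporting layer.
#'
#' @param trends output of [country_trends()].
#' @return data.frame: `country_iso3`, `d_sii`, `d_cix`, `d_cix_reported`.
#' @export
sii_cix_change_table <- function(trends) {
  sii <- trends[trends$indicator == "SII", , drop = FALSE]
  cx <- trends[trends$indicator == "CIX", , drop = FALSE]
  countries <- union(sii$country_iso3, cx$country_iso3)
  data.frame(
    country_iso3 = countries,
    d_sii = sii$change_per_decade[match(countries, sii$country_iso3)],
    d_cix = cx$change_per_decade[match(countries, cx$country_iso3)],
    d_cix_reported = -cx$change_per_decade[match(countries, cx$country_iso3)],
    stringsAsFactors = FALSE
  )
}
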