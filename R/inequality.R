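# Summary measures of wealth-related inequality in stunting.
#
# Two whole-distribution measures:
#   SII -- slope index of inequality: predicted prevalence difference between
#          the top (rank 1) and bottom (rank 0) of the wealth scale, from a
#          weighted logistic regression of the stunting indicator on the
#          fractional wealth rank. Logistic rather than linear so predicted
#          prevalences cannot leave [0, 1]. Percentage points; negative when
#          the poor fare worse.
#   CIX -- concentration index in its relative, uncorrected formulation:
#          twice the weighted covariance between the indicator and the rank,
#          divided by mean prevalence, times 100 (scale -100..100). Equals
#          twice the area between the concentration curve and the diagonal.
# Plus the simple extreme-quintile contrasts (Q1 - Q5 difference, Q1/Q5
# ratio) and absolute/relative change helpers.

#' Midpoint fractional ranks from ordered group shares
#'
#' For groups ordered poorest to richest with population shares s_g, each
#' group's rank is the midpoint of its span of the cumulative distribution:
#' r_g = C_{g-1} + s_g / 2.
#'
#' @param shares non-negative shares summing to 1 (renormalized otherwise).
#' @return numeric vector of midpoint ranks in (0, 1).
#' @export
#' @examples
#' midpoint_ranks(rep(0.2, 5))  # 0.1 0.3 0.5 0.7 0.9
midpoint_ranks <- function(shares) {
  if (any(shares < 0) || sum(shares) <= 0) stop("shares must be non-negative with positive sum")
  s <- shares / sum(shares)
  cumsum(s) - s / 2
}

#' Weighted fractional wealth ranks for children
#'
#' Computed within each survey over children with a defined wealth position
#' and positive weight. In `"grouped"` mode (the default, matching
#' quintile-based practice) all children of a wealth quintile share the
#' quintile's weighted midpoint rank; in `"continuous"` mode each distinct
#' wealth score forms its own group, giving per-child midpoint ranks.
#' The weighted mean rank is 1/2 by construction.
#'
#' @param children child table with `wealth_quintile` (grouped mode) or
#'   `wealth_score` (continuous mode) and `weight`.
#' @param mode "grouped" or "continuous".
#' @return numeric vector of ranks aligned with `children` rows (`NA` where
#'   the wealth position is missing).
#' @export
fractional_ranks <- function(children, mode = c("grouped", "continuous")) {
  mode <- match.arg(mode)
  key_col <- if (mode == "grouped") "wealth_quintile" else "wealth_score"
  if (!key_col %in% names(children)) stop("children lack column ", key_col)
  out <- rep(NA_real_, nrow(children))
  for (sid in unique(children$survey_id)) {
    rows <- which(children$survey_id == sid & !is.na(children[[key_col]]))
    if (!length(rows)) next
    w <- children$weight[rows]
    if (sum(w) <= 0) stop("zero total weight in survey ", sid)
    g <- children[[key_col]][rows]
    f <- factor(g, levels = sort(unique(g)))
    shares <- drop(rowsum(w, f)) / sum(w)   # weight totals in wealth order
    ranks_g <- midpoint_ranks(shares)
    out[rows] <- ranks_g[as.integer(f)]
  }
  out
}

# Ridge-penalized weighted logistic fit by IRLS; fallback under separation.
ridge_logistic <- function(y, r, w, lambda = 1e-6, tol = 1e-10, max_iter = 200L) {
  X <- cbind(1, r)
  beta <- c(qlogis(max(min(wtd_mean(y, w), 1 - 1e-6), 1e-6)), 0)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * (w * v)) + diag(lambda, 2)
    g <- crossprod(X, w * (y - mu)) - lambda * beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Slope index of inequality via weighted logistic regression
#'
#' Fits stunted ~ fractional rank by weighted logistic regression and
#' reports SII = 100 * (expit(a + b) - expit(a)): the model-predicted
#' prevalence at the top of the wealth distribution minus the bottom, in
#' percentage points. An SII of -20 means prevalence among the wealthiest is
#' 20 points lower than among the poorest. The standard error comes from a
#' cluster-robust sandwich covariance of (a, b) pushed through the delta
#' method. A constant outcome yields SII 0 with undefined SE; complete
#' separation triggers a lightly ridge-penalized refit, flagged.
#'
#' @param stunted logical/0-1 outcome (NA dropped).
#' @param rank fractional wealth ranks in \[0, 1\].
#' @param weight sampling weights (default equal).
#' @param cluster optional cluster ids for the robust covariance; when
#'   omitted each observation is its own cluster (heteroskedasticity-robust).
#' @return one-row data.frame: `metric`, `value`, `se`, `scale`, `flags`.
#' @export
sii_logistic <- function(stunted, rank, weight = NULL, cluster = NULL) {
  keep <- !is.na(stunted) & !is.na(rank)
  y <- as.numeric(stunted[keep])
  r <- rank[keep]
  w <- if (is.null(weight)) rep(1, length(y)) else weight[keep]
  cl <- if (is.null(cluster)) NULL else cluster[keep]
  flags <- character(0)
  if (length(unique(y)) < 2) {
    return(data.frame(metric = "SII", value = 0, se = NA_real_,
                      scale = "percentage points", flags = "constant_outcome",
                      stringsAsFactors = FALSE))
  }
  dat <- data.frame(y = y, r = r)
  wn <- w / mean(w)  # normalization leaves the fit invariant, keeps glm quiet
  fit <- withCallingHandlers(
    glm(y ~ r, family = quasibinomial(), data = dat, weights = wn),
    warning = function(wr) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(wr))) {
        flags <<- c(flags, "separation_penalized")
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- coef(fit)
  if ("separation_penalized" %in% flags || any(abs(beta) > 30)) {
    flags <- unique(c(flags, "separation_penalized"))
    beta <- ridge_logistic(y, r, wn)
  }
  a <- beta[1]; b <- beta[2]
  p0 <- plogis(a); p1 <- plogis(a + b)
  value <- 100 * (p1 - p0)
  V <- if ("separation_penalized" %in% flags) {
    NULL  # sandwich on a penalized fit is not meaningful at this scale
  } else if (is.null(cl)) {
    sandwich::vcovCL(fit)
  } else {
    sandwich::vcovCL(fit, cluster = cl)
  }
  se <- if (is.null(V)) NA_real_ else {
    grad <- 100 * c(p1 * (1 - p1) - p0 * (1 - p0), p1 * (1 - p1))
    sqrt(drop(t(grad) %*% V %*% grad))
  }
  out <- data.frame(metric = "SII", value = unname(value), se = unname(se),
                    scale = "percentage points",
                    flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  attr(out, "coefficients") <- c(intercept = unname(a), slope = unname(b))
  out
}

#' Relative concentration index (covariance formulation)
#'
#' CIX = 100 * 2 * cov_w(stunted, rank) / mean_w(stunted): twice the
#' weighted covariance between the outcome and the fractional wealth rank
#' over the weighted mean outcome, on the -100..100 scale, with no
#' normalization corrections. Negative values mean stunting concentrates
#' among the poor; 0 is perfect equality. The standard error, when cluster
#' ids are supplied, is a delete-one-cluster jackknife.
#'
#' @inheritParams sii_logistic
#' @return one-row data.frame: `metric`, `value`, `se`, `scale`, `flags`.
#' @export
cix <- function(stunted, rank, weight = NULL, cluster = NULL) {
  keep <- !is.na(stunted) & !is.na(rank)
  y <- as.numeric(stunted[keep])
  r <- rank[keep]
  w <- if (is.null(weight)) rep(1, length(y)) else weight[keep]
  cl <- if (is.null(cluster)) NULL else cluster[keep]
  point <- function(y, r, w) {
    mu <- wtd_mean(y, w)
    if (mu <= 0) return(NA_real_)
    100 * 2 * wtd_cov(y, r, w) / mu
  }
  value <- point(y, r, w)
  if (is.na(value)) {
    return(data.frame(metric = "CIX", value = NA_real_, se = NA_real_,
                      scale = "-100..100", flags = "zero_prevalence",
                      stringsAsFactors = FALSE))
  }
  se <- NA_real_
  if (!is.null(cl) && length(unique(cl)) > 1) {
    gs <- unique(cl)
    G <- length(gs)
    theta <- vapply(gs, function(g) point(y[cl != g], r[cl != g], w[cl != g]),
                    numeric(1))
    theta <- theta[!is.na(theta)]
    if (length(theta) > 1) {
      se <- sqrt((length(theta) - 1) / length(theta) *
                   sum((theta - mean(theta))^2))
    }
  }
  data.frame(metric = "CIX", value = value, se = se, scale = "-100..100",
             flags = "", stringsAsFactors = FALSE)
}

#' Concentration index from the concentration curve (trapezoid area)
#'
#' Grouped formulation used as an internal cross-check of [cix()]: plot the
#' cumulative share of cases against the cumulative population share,
#' groups ordered poorest to richest, and take twice the (signed) area
#' between the diagonal and the curve. With midpoint ranks the covariance
#' and trapezoid formulations agree exactly.
#'
#' @param group_share population shares of the ordered groups.
#' @param group_prev prevalence (proportion or percent) in each group.
#' @return CIX on the -100..100 scale.
#' @export
#' @examples
#' cix_trapezoid(rep(.2, 5), c(50, 40, 30, 20, 10))  # -26.67
cix_trapezoid <- function(group_share, group_prev) {
  stopifnot(length(group_share) == length(group_prev))
  s <- group_share / sum(group_share)
  cases <- s * group_prev
  if (sum(cases) <= 0) stop("zero total prevalence; CIX undefined")
  x <- c(0, cumsum(s))
  yy <- c(0, cumsum(cases) / sum(cases))
  area_under <- sum(diff(x) * (head(yy, -1) + tail(yy, -1)) / 2)
  100 * (1 - 2 * area_under)
}

#' Simple extreme-quintile inequality measures
#'
#' Absolute inequality is the arithmetic difference between the poorest and
#' wealthiest quintile prevalences (Q1 - Q5, percentage points); relative
#' inequality is their rate ratio (Q1 / Q5, undefined when Q5 is 0).
#'
#' @param q1 prevalence (percent) in the poorest quintile.
#' @param q5 prevalence (percent) in the wealthiest quintile.
#' @return two-row data.frame with metrics `Q1_Q5_DIFF` and `Q1_Q5_RATIO`.
#' @export
#' @examples
#' simple_measures(50, 10)  # difference 40 pp, ratio 5
simple_measures <- function(q1, q5) {
  stopifnot(q1 >= 0, q1 <= 100, q5 >= 0, q5 <= 100)
  ratio <- if (q5 == 0) NA_real_ else q1 / q5
  data.frame(
    metric = c("Q1_Q5_DIFF", "Q1_Q5_RATIO"),
    value = c(q1 - q5, ratio),
    se = NA_real_,
    scale = c("percentage points", "ratio"),
    flags = c("", if (q5 == 0) "undefined_ratio" else ""),
    stringsAsFactors = FALSE
  )
}

#' Absolute and relative change between two prevalences
#'
#' Absolute change is late - early in percentage points; relative change is
#' 100 * (late - early) / early, percent of baseline. Declines are negative:
#' a fall from 50% to 30% is -20 points absolute and -40% relative.
#'
#' @param early baseline prevalence (percent).
#' @param late follow-up prevalence (percent).
#' @return list with `absolute_pp`, `relative_pct` and `flags`.
#' @export
#' @examples
#' change_measures(50, 30)  # absolute -20, relative -40
change_measures <- function(early, late) {
  stopifnot(early >= 0, early <= 100, late >= 0, late <= 100)
  rel <- if (early == 0) NA_real_ else 100 * (late - early) / early
  list(absolute_pp = late - early, relative_pct = rel,
       flags = if (early == 0) "undefined_relative_change" else "")
}

#' All inequality measures for every survey
#'
#' Computes, per survey: logistic SII and relative CIX on weighted
#' fractional ranks (grouped by quintile by default) with design-based
#' uncertainty, and the simple Q1/Q5 contrasts from the design-based
#' quintile prevalences.
#'
#' @param children child table with `stunted`, `wealth_quintile` (and
#'   `wealth_score` in continuous mode).
#' @param design a [design_spec()].
#' @param mode rank mode for [fractional_ranks()].
#' @return long data.frame: `survey_id`, `metric`, `value`, `se`, `scale`,
#'   `flags`.
#' @export
survey_inequality <- function(children, design = design_spec(),
                              mode = c("grouped", "continuous")) {
  mode <- match.arg(mode)
  ranks <- fractional_ranks(children, mode = mode)
  rows <- list()
  for (sid in unique(children$survey_id)) {
    sel <- children$survey_id == sid
    ch <- children[sel, , drop = FALSE]
    r <- ranks[sel]
    sii_row <- sii_logistic(ch$stunted, r, ch[[design$weight]], ch[[design$cluster]])
    cix_row <- cix(ch$stunted, r, ch[[design$weight]], ch[[design$cluster]])
    q1 <- weighted_prevalence(ch, design, quintile = 1)
    q5 <- weighted_prevalence(ch, design, quintile = 5)
    simple <- simple_measures(q1$prevalence, q5$prevalence)
    out <- rbind(sii_row, cix_row, simple)
    rows[[length(rows) + 1L]] <- cbind(survey_id = sid, out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
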