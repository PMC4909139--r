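# Asset-based wealth index: first principal component of the standardized
# household asset matrix, then weighted quintiles of the score.

#' Score households by the first principal component of their assets
#'
#' Reproduces the usual asset-index construction: indicators are centered
#' and scaled by their standard deviation, the first principal component is
#' extracted per survey, and each household's score is its projection onto
#' that component. The sign of the component is chosen so that the score
#' correlates positively with the simple sum of asset indicators, making
#' higher score mean wealthier deterministically. Constant indicators carry
#' no information and are dropped with a warning.
#'
#' If the table already holds a `wealth_score` column (e.g. the original
#' survey team's scores) and `use_precomputed = TRUE`, scoring is skipped.
#'
#' @param households household table from [read_households()] or
#'   [simulate_cohort()].
#' @param asset_prefix prefix identifying asset indicator columns.
#' @param use_precomputed keep an existing `wealth_score` column untouched.
#' @return the household table with a `wealth_score` column; per-survey
#'   loadings and explained-variance shares are attached as attribute
#'   `"scoring"`.
#' @export
score_households <- function(households, asset_prefix = "asset_",
                             use_precomputed = TRUE) {
  if (use_precomputed && "wealth_score" %in% names(households) &&
      all(is.finite(households$wealth_score))) {
    return(households)
  }
  assets <- grep(paste0("^", asset_prefix), names(households), value = TRUE)
  if (!length(assets)) stop("no asset indicator columns found")
  households$wealth_score <- NA_real_
  scoring <- list()
  for (sid in unique(households$survey_id)) {
    rows <- households$survey_id == sid
    X <- as.matrix(households[rows, assets, drop = FALSE])
    sds <- apply(X, 2, sd)
    keep <- sds > 0
    if (!any(keep)) stop("degenerate asset matrix: all indicators constant in survey ", sid)
    if (any(!keep)) {
      warning(sprintf("survey %s: dropping %d constant asset indicator(s)", sid, sum(!keep)))
    }
    X <- X[, keep, drop = FALSE]
    if (nrow(unique(X)) < 2) stop("degenerate asset matrix: all households identical in survey ", sid)
    pc <- prcomp(X, center = TRUE, scale. = TRUE)
    score <- pc$x[, 1]
    loadings <- pc$rotation[, 1]
    # orient: richer (more assets) => higher score
    if (cor(score, rowSums(X)) < 0) {
      score <- -score
      loadings <- -loadings
    }
    households$wealth_score[rows] <- score
    scoring[[sid]] <- list(
      loadings = setNames(loadings, colnames(X)),
      explained_variance_share = unname(pc$sdev[1]^2 / sum(pc$sdev^2))
    )
  }
  attr(households, "scoring") <- scoring
  households
}

#' Assign wealth quintiles to children
#'
#' Joins each child to its household's wealth score and cuts the per-survey
#' score distribution at the 20/40/60/80 weighted percentiles. The reference
#' population for the cutpoints is, by default, children weighted by their
#' sampling weights (de facto population quintiles); `reference =
#' "household"` instead uses one observation per household with equal
#' weight. Ties at a cutpoint are assigned to the lower (poorer) quintile.
#' Children whose household has no score get `NA` and are excluded from
#' quintile-based analyses; if all scores in a survey are tied the quintiles
#' are undefined and the survey's children are all flagged `NA` with a
#' warning.
#'
#' @param children child table.
#' @param households household table carrying `wealth_score` (see
#'   [score_households()]).
#' @param reference "child" (weighted by child sampling weights, default) or
#'   "household" (equal household weights) for the cutpoint population.
#' @return the child table with columns `wealth_score` and `wealth_quintile`
#'   (integer 1..5, 1 = poorest).
#' @export
assign_quintiles <- function(children, households, reference = c("child", "household")) {
  reference <- match.arg(reference)
  if (!"wealth_score" %in% names(households)) {
    stop("households lack wealth_score; run score_households() first")
  }
  key <- paste(households$survey_id, households$household_id)
  idx <- match(paste(children$survey_id, children$household_id), key)
  children$wealth_score <- households$wealth_score[idx]
  children$wealth_quintile <- NA_integer_
  for (sid in unique(children$survey_id)) {
    rows <- which(children$survey_id == sid & is.finite(children$wealth_score))
    if (!length(rows)) next
    if (reference == "child") {
      ref_x <- children$wealth_score[rows]
      ref_w <- children$weight[rows]
    } else {
      hrows <- households$survey_id == sid & is.finite(households$wealth_score)
      ref_x <- households$wealth_score[hrows]
      ref_w <- rep(1, sum(hrows))
    }
    if (length(unique(ref_x)) == 1L) {
      warning("survey ", sid, ": all wealth scores tied; quintiles undefined")
      next
    }
    cuts <- weighted_quantile(ref_x, ref_w, c(.2, .4, .6, .8))
    # strict '>' sends scores equal to a cutpoint to the lower quintile
    children$wealth_quintile[rows] <-
      1L + rowSums(outer(children$wealth_score[rows], cuts, ">"))
  }
  children
}
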