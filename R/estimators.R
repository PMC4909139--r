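# Design-based prevalence estimation: weighted ratio estimator with Taylor
# linearization under the with-replacement-cluster approximation that is
# standard for DHS/MICS designs. No finite-population corrections.

#' Describe the survey design columns
#'
#' @param weight column holding sampling weights.
#' @param cluster column holding the primary sampling unit (cluster) id.
#' @param strata optional column holding stratum labels; clusters must nest
#'   within strata.
#' @return a `design_spec` list.
#' @export
design_spec <- function(weight = "weight", cluster = "cluster_id", strata = NULL) {
  structure(list(weight = weight, cluster = cluster, strata = strata),
            class = "design_spec")
}

# Core estimator on vectors. Returns prevalence/se in percent plus design
# bookkeeping. Strata containing a single cluster are collapsed into the
# preceding stratum (certainty units cannot contribute a variance term).
svy_prevalence <- function(y, w, cluster, strata = NULL) {
  stopifnot(length(y) == length(w), length(y) == length(cluster))
  keep <- !is.na(y)
  y <- as.numeric(y[keep]); w <- w[keep]; cluster <- cluster[keep]
  strata <- if (is.null(strata)) rep("_all", length(y)) else as.character(strata[keep])
  if (!length(y)) stop("no children with usable stunting status in subgroup")
  W <- sum(w)
  p <- sum(w * y) / W

  # collapse single-cluster strata into a neighbour
  tab <- table(strata, cluster)
  n_per_stratum <- rowSums(tab > 0)
  if (any(n_per_stratum < 2) && length(n_per_stratum) > 1) {
    lone <- names(n_per_stratum)[n_per_stratum < 2]
    warning("collapsing single-cluster strata into neighbour: ",
            paste(lone, collapse = ", "))
    levels_all <- names(n_per_stratum)
    for (h in lone) {
      pos <- match(h, levels_all)
      target <- if (pos > 1) levels_all[pos - 1] else levels_all[pos + 1]
      strata[strata == h] <- target
      levels_all[levels_all == h] <- target
    }
  }

  # Taylor linearization of the ratio estimator: per-cluster totals of
  # w * (y - p), between-cluster variance within strata, WR approximation.
  z <- w * (y - p)
  cl_tot <- tapply(z, list(strata, cluster), sum)
  n_clusters_total <- 0L
  v <- 0
  flags <- character(0)
  for (h in rownames(cl_tot)) {
    t_h <- cl_tot[h, ]
    t_h <- t_h[!is.na(t_h)]
    n_h <- length(t_h)
    n_clusters_total <- n_clusters_total + n_h
    if (n_h < 2) {
      flags <- c(flags, "single_cluster_se_unreliable")
      next
    }
    v <- v + n_h / (n_h - 1) * sum((t_h - mean(t_h))^2)
  }
  se <- if (n_clusters_total < 2) NA_real_ else sqrt(v) / W
  if (n_clusters_total < 2) flags <- c(flags, "single_cluster_se_unreliable")
  list(prevalence = 100 * p, se = 100 * se,
       n_children = length(y), n_clusters = n_clusters_total,
       flags = unique(flags))
}

#' Survey-weighted stunting prevalence with design-based standard error
#'
#' Point estimate is the weighted proportion stunted
#' (100 * sum(w * stunted) / sum(w)); the standard error comes from Taylor
#' linearization of this ratio estimator with between-cluster variance
#' (within strata when present), the with-replacement approximation used for
#' multistage health surveys. Children with missing or implausible HAZ
#' (`stunted` is `NA`) are excluded.
#'
#' @param children child table with a logical `stunted` column.
#' @param design a [design_spec()] naming weight/cluster/strata columns.
#' @param quintile optional integer 1..5 restricting to one wealth quintile.
#' @return one-row data.frame: `prevalence` and `se` in percent,
#'   `n_children`, `n_clusters`, `flags`.
#' @export
weighted_prevalence <- function(children, design = design_spec(), quintile = NULL) {
  if (!is.null(quintile)) {
    stopifnot(quintile %in% 1:5)
    children <- children[!is.na(children$wealth_quintile) &
                           children$wealth_quintile == quintile, , drop = FALSE]
  }
  est <- svy_prevalence(
    y = children$stunted,
    w = children[[design$weight]],
    cluster = children[[design$cluster]],
    strata = if (is.null(design$strata)) NULL else children[[design$strata]]
  )
  data.frame(prevalence = est$prevalence, se = est$se,
             n_children = est$n_children, n_clusters = est$n_clusters,
             flags = paste(est$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' National and quintile-specific prevalence for every survey
#'
#' @param children child table with derived `stunted` and `wealth_quintile`.
#' @param design a [design_spec()].
#' @return long data.frame: one row per survey for the national estimate and
#'   one per wealth quintile, with columns `survey_id`, `group`
#'   (`national`, `Q1`..`Q5`), `prevalence`, `se`, `n_children`,
#'   `n_clusters`, `flags`.
#' @export
prevalence_by_quintile <- function(children, design = design_spec()) {
  rows <- list()
  for (sid in unique(children$survey_id)) {
    ch <- children[children$survey_id == sid, , drop = FALSE]
    nat <- weighted_prevalence(ch, design)
    rows[[length(rows) + 1L]] <- cbind(survey_id = sid, group = "national", nat)
    for (q in 1:5) {
      est <- weighted_prevalence(ch, design, quintile = q)
      rows[[length(rows) + 1L]] <- cbind(survey_id = sid, group = paste0("Q", q), est)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
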