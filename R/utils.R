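# Small numeric helpers shared across modules.

#' Weighted quantiles by cumulative-weight scan
#'
#' Returns, for each probability `p`, the smallest observed value whose
#' cumulative weight share reaches `p`. This left-continuous inverse of the
#' weighted empirical CDF is the convention used for wealth-quintile
#' cutpoints: ties at a cutpoint fall in the lower group.
#'
#' @param x numeric values.
#' @param w positive weights, same length as `x`.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
#' @examples
#' weighted_quantile(1:100, rep(1, 100), c(.2, .4, .6, .8))
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs >= 0 & probs <= 1))
  keep <- is.finite(x)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) stop("no finite values to take quantiles of")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    # tolerance guards against cumulative rounding at exact cut shares
    x[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

# Weighted mean with NA guard; weights must be positive.
wtd_mean <- function(x, w) {
  sum(w * x) / sum(w)
}

# Weighted covariance about weighted means (population form, consistent with
# the concentration-index definition).
wtd_cov <- function(x, y, w) {
  mx <- wtd_mean(x, w)
  my <- wtd_mean(y, w)
  sum(w * (x - mx) * (y - my)) / sum(w)
}

# Significance stars at the conventional Table-1 thresholds.
signif_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + index * 104729) %% 2147483647)
}
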