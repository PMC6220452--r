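#' Two-sided Wilcoxon rank-sum p-value
#'
#' The test behind DMR seeding and extension. For group sizes up to
#' `exact_max` the p-value is computed by exhaustive enumeration of all
#' `choose(n1 + n2, n1)` group labelings of the pooled mid-ranks (so
#' ties are handled exactly, as a permutation test on the rank-sum
#' statistic); beyond that a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (per-site methylation levels of the two
#'   samples).
#' @param exact_max Largest group size for exhaustive enumeration.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum_p(c(.9, .95, 1, .85, .9), c(.1, .05, 0, .2, .1)) # 2/252
#' @export
wilcoxon_rank_sum_p <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 == 0) return(1)
    z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
    2 * stats::pnorm(z, lower.tail = FALSE)
  }
}
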