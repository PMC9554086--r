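# Shared statistical helpers: two-sample Mann-Whitney with a principled
# exact path, and effect/p utilities used by the enrichment and abundance
# modules.

# Two-sided Mann-Whitney U test.
# - No ties and both groups < 50: exact distribution (stats::wilcox.test).
# - Ties but <= `exact_max` total observations: exact permutation test on
#   midranks (all choose(n1+n2, n1) relabelings; two-sided p =
#   min(1, 2 * min(P(W <= w), P(W >= w)))).
# - Otherwise: normal approximation with midranks, tie correction and
#   continuity correction (stats::wilcox.test defaults); a fully tied
#   comparison yields p = 1.
.mwTest <- function(x, y, exact_max = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  has_ties <- anyDuplicated(v) > 0L
  if (!has_ties && n1 < 50 && n2 < 50) {
    return(wilcox.test(x, y, exact = TRUE)$p.value)
  }
  if (has_ties && n1 + n2 <= exact_max) {
    r <- rank(v)
    w_obs <- sum(r[seq_len(n1)])
    sums <- combn(n1 + n2, n1, function(i) sum(r[i]))
    eps <- 1e-9
    p_le <- mean(sums <= w_obs + eps)
    p_ge <- mean(sums >= w_obs - eps)
    return(min(1, 2 * min(p_le, p_ge)))
  }
  p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  if (is.nan(p) || is.na(p)) 1 else p
}

# Fast approximate-only Mann-Whitney p for family scans (large cohorts,
# heavy tie load from absent families). Matches stats::wilcox.test with
# exact = FALSE, correct = TRUE.
.mwApprox <- function(x, y) {
  p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  if (is.nan(p) || is.na(p)) 1 else p
}

# log2 ratio of means with a small pseudocount to keep zero means finite.
.log2Ratio <- function(a, b, eps = 1e-12) log2((a + eps) / (b + eps))
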