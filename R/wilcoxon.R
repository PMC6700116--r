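## Two-sided Wilcoxon rank-sum (Mann-Whitney) test used for marker
## detection. Exact by enumeration of all group assignments when both
## groups have <= `exact_max` observations (ties handled through average
## ranks of the observed pooled values), tie-corrected normal approximation
## otherwise. The two-sided p-value is defined symmetrically in both modes
## as P(|U - E[U]| >= |u - E[U]|).

#' Wilcoxon rank-sum test
#'
#' @param x,y numeric observations of the two groups.
#' @param exact_max exact enumeration is used when both groups have at most
#'   this many observations.
#' @return list with `statistic` (the Mann-Whitney U of `x`) and `p.value`
#'   (two-sided).
#' @export
wilcoxonRankSum <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- .wrs_exact_p(r, n1, u, mu)
  } else {
    n <- n1 + n2
    ties <- rle(sort(pooled))$lengths
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
  }
  list(statistic = u, p.value = min(1, p))
}

.wrs_exact_p <- function(r, n1, u, mu) {
  n <- length(r)
  offset <- n1 * (n1 + 1) / 2
  idx <- combn(n, n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - offset
  obs <- abs(u - mu)
  mean(abs(us - mu) >= obs - 1e-9)
}
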