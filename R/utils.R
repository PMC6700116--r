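#' Rank-based separation AUC
#'
#' Area under the ROC curve for separating two groups by a numeric score,
#' computed as the normalized Mann-Whitney U statistic (ties count one
#' half). 1 means perfect separation with `pos` above `neg`, 0.5 none.
#'
#' @param pos,neg numeric scores of the two groups.
#' @return AUC in \[0, 1\].
#' @export
rankAUC <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (!n1 || !n2) stop("both groups must be non-empty")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
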