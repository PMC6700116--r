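## Independent oracles and small fixture builders shared across tests.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(SingleCellExperiment)
})

## Build a SingleCellExperiment directly from a dense matrix of counts.
toy_counts <- function(m, species = "human") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  makeCountsSCE(m, cell_meta = data.frame(row.names = colnames(m),
                                          species = rep(species, ncol(m))))
}

## A SingleCellExperiment whose "lognorm" assay is set verbatim (for
## operations downstream of normalization).
toy_lognorm <- function(m) {
  sce <- toy_counts(matrix(1, nrow(m), ncol(m),
                           dimnames = dimnames(m)))
  assay(sce, "lognorm") <- m
  sce
}

## Brute-force two-sided Wilcoxon rank-sum p-value by full enumeration of
## group assignments, with the U statistic computed by direct pair
## counting (independent of the package's rank-sum formula).
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * length(y) / 2
  obs <- abs(u_of(x, y) - mu)
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= obs - 1e-9)
}

## Hypergeometric upper-tail P(X >= k) by explicit summation of binomial
## coefficients (independent of phyper).
hyper_tail <- function(k, nA, nB, N) {
  j <- k:min(nA, nB)
  sum(exp(lchoose(nA, j) + lchoose(N - nA, nB - j) - lchoose(N, nB)))
}

## Tie-aware Spearman rho from first principles: average ranks computed by
## hand, then the Pearson product-moment formula on them.
spearman_brute <- function(x, y) {
  avg_rank <- function(v) {
    sapply(v, function(a) mean(which(sort(v) == a)))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Naive CNV recomputation: per cell, loop over sliding windows within
## each chromosome and average; then center on the reference means.
cnv_brute <- function(expr, positions, reference, window) {
  pos <- positions[positions$gene_id %in% rownames(expr), ]
  pos <- pos[order(pos$chrom, pos$start, pos$gene_id), ]
  out <- NULL
  for (chr in unique(pos$chrom)) {
    genes <- pos$gene_id[pos$chrom == chr]
    if (length(genes) < window) {
      out <- rbind(out, colMeans(expr[genes, , drop = FALSE]))
    } else {
      for (s in 1:(length(genes) - window + 1)) {
        win <- genes[s:(s + window - 1)]
        out <- rbind(out, colMeans(expr[win, , drop = FALSE]))
      }
    }
  }
  out - rowMeans(out[, reference, drop = FALSE])
}

## Single default synthetic dataset reused by several test files (built
## once per test run).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateCells(generatorParams())
    cache
  }
})
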