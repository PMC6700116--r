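## Estimation of compartment contributions to bulk expression profiles
## from single-cell-derived compartment signatures.

#' Derive compartment marker signatures
#'
#' For each compartment (tumor, microglia, macrophage, T cell, ...) runs a
#' one-vs-rest Wilcoxon rank-sum test on log-normalized expression and keeps
#' the genes with Bonferroni-adjusted p < `q_max` and positive log fold
#' change. A compartment whose signature comes out empty is an error.
#'
#' @param sce a `SingleCellExperiment` with a `"lognorm"` assay.
#' @param labels named character vector: cell id -> compartment.
#' @param q_max Bonferroni-adjusted p cutoff.
#' @param max_genes optional cap on genes per signature (strongest first).
#' @return Named list of [GeneSignature-class], one per compartment.
#' @export
compartmentSignatures <- function(sce, labels, q_max = 0.05,
                                  max_genes = Inf) {
  comps <- sort(unique(labels))
  out <- list()
  for (cp in comps) {
    cells_in <- names(labels)[labels == cp]
    cells_out <- names(labels)[labels != cp]
    de <- clusterMarkers(sce, cells1 = cells_in, cells2 = cells_out)
    de <- de[de$p_bonferroni < q_max & de$log_fold_change > 0, ]
    if (!nrow(de))
      stop("compartment '", cp, "' yields an empty signature")
    genes <- head(de$gene, max_genes)
    out[[cp]] <- GeneSignature(cp, genes,
                               provenance = "compartment one-vs-rest DE")
  }
  out
}

#' Estimate compartment fractions in bulk expression profiles
#'
#' Deconvolutes each bulk sample into compartment contributions using the
#' compartment marker signatures: (i) signature genes absent from the bulk
#' platform universe are discarded and counted; (ii) each gene is z-scored
#' across the bulk samples; (iii) the raw score of compartment c in sample
#' s is the mean z-score over c's signature genes; (iv) negative raw scores
#' are clipped at zero; (v) fractions are the clipped scores normalized to
#' sum to one per sample. A sample with all-zero clipped scores receives
#' uniform fractions with a warning.
#'
#' With `negative = "shift"` the per-sample minimum raw score is subtracted
#' instead of clipping, which preserves the ordering of low-scoring samples
#' (clipping ties every below-average sample at fraction zero).
#'
#' @param bulk genes x samples numeric matrix (rownames = gene ids).
#' @param signatures named list of [GeneSignature-class] per compartment.
#' @param log_transform apply `log1p` to the bulk matrix before z-scoring.
#' @param negative how to handle negative compartment scores: `"clip"`
#'   (default) sets them to zero; `"shift"` subtracts the per-sample
#'   minimum score.
#' @return A [FractionEstimate-class].
#' @export
estimateFractions <- function(bulk, signatures, log_transform = FALSE,
                              negative = c("clip", "shift")) {
  negative <- match.arg(negative)
  bulk <- as.matrix(bulk)
  if (length(signatures) < 2) stop("need at least 2 compartments")
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, signatureName, character(1))
  if (log_transform) bulk <- log1p(bulk)
  mu <- rowMeans(bulk)
  sds <- apply(bulk, 1, sd)
  z <- sweep(bulk, 1, mu, "-")
  z <- sweep(z, 1, ifelse(sds > 0, sds, 1), "/")
  z[sds == 0, ] <- 0

  discarded <- 0L
  raw <- matrix(NA_real_, ncol(bulk), length(signatures),
                dimnames = list(colnames(bulk), names(signatures)))
  for (cp in names(signatures)) {
    genes <- geneIds(signatures[[cp]])
    present <- intersect(genes, rownames(bulk))
    discarded <- discarded + length(genes) - length(present)
    if (!length(present))
      stop("signature '", cp, "' has no genes on the bulk platform")
    raw[, cp] <- colMeans(z[present, , drop = FALSE])
  }
  clipped <- if (negative == "clip") pmax(raw, 0)
             else raw - apply(raw, 1, min)
  totals <- rowSums(clipped)
  frac <- clipped
  if (any(totals == 0)) {
    warning(sum(totals == 0), " sample(s) with all-zero compartment ",
            "scores; uniform fractions assigned")
    frac[totals == 0, ] <- 1 / ncol(frac)
    totals[totals == 0] <- 1
  }
  frac <- frac / rowSums(frac)
  new("FractionEstimate", fractions = frac, scores = raw,
      signatures = signatures, genesDiscarded = as.integer(discarded))
}

#' Score a bulk-derived gene set across single-cell compartments
#'
#' Computes the fold-enrichment score of a bulk-derived gene set (for
#' example genes upregulated in supratentorial versus infratentorial
#' tumors) in every cell, then tests each compartment versus the rest for a
#' score difference with a Wilcoxon rank-sum test (Bonferroni-adjusted over
#' compartments).
#'
#' @param sce a `SingleCellExperiment` with a `"lognorm"` assay.
#' @param gene_set a [GeneSignature-class] or character vector.
#' @param labels named character vector: cell id -> compartment.
#' @return data.frame with one row per compartment: `compartment`,
#'   `mean_score`, `mean_rest`, `p`, `p_bonferroni`.
#' @export
locationSignatureEnrichment <- function(sce, gene_set, labels) {
  if (!is(gene_set, "GeneSignature"))
    gene_set <- GeneSignature("bulk_derived", gene_set)
  sc <- scoreCells(sce, gene_set)[, 1]
  labels <- labels[intersect(names(labels), names(sc))]
  comps <- sort(unique(labels))
  res <- data.frame(compartment = comps, mean_score = NA_real_,
                    mean_rest = NA_real_, p = NA_real_)
  for (i in seq_along(comps)) {
    x <- sc[names(labels)[labels == comps[i]]]
    y <- sc[names(labels)[labels != comps[i]]]
    res$mean_score[i] <- mean(x)
    res$mean_rest[i] <- mean(y)
    res$p[i] <- wilcoxonRankSum(x, y)$p.value
  }
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res
}
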