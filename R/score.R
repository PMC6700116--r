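## Fold-enrichment signature scoring at cell, cluster, and tumor-type
## level; subpopulation thresholding; immune-atlas signature derivation and
## tumor-baseline normalization.

.expr_layer <- function(sce, layer) {
  if (is(sce, "SingleCellExperiment")) {
    if (!layer %in% assayNames(sce))
      stop("assay '", layer, "' not present; run logNormalize() first")
    as.matrix(assay(sce, layer))
  } else as.matrix(sce)
}

.score_matrix <- function(expr, signatures) {
  if (is(signatures, "GeneSignature")) signatures <- list(signatures)
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, signatureName, character(1))
  denom <- colMeans(expr)
  if (any(denom <= 0))
    stop("all-zero cell(s): ",
         paste(head(colnames(expr)[denom <= 0], 5), collapse = ", "))
  out <- matrix(NA_real_, ncol(expr), length(signatures),
                dimnames = list(colnames(expr), names(signatures)))
  for (s in names(signatures)) {
    genes <- intersect(geneIds(signatures[[s]]), rownames(expr))
    n_drop <- length(geneIds(signatures[[s]])) - length(genes)
    if (!length(genes))
      stop("signature '", s, "' has no genes in the expression universe")
    if (n_drop > 0)
      message("signature '", s, "': ", n_drop,
              " gene(s) absent from the universe, dropped")
    out[, s] <- colMeans(expr[genes, , drop = FALSE]) / denom
  }
  out
}

#' Fold-enrichment scores per cell
#'
#' For each cell and signature, the score is the mean expression of the
#' signature's genes divided by the mean expression of all genes in the
#' post-QC universe, computed on the (non-negative) log-normalized layer by
#' default. A score of 1 means no enrichment; the pipeline calls a cell a
#' subpopulation member when the score exceeds 2.5 (see
#' [assignSubpopulations()]). Signature genes absent from the universe are
#' dropped with a message.
#'
#' @param sce a `SingleCellExperiment` (or genes x cells matrix).
#' @param signatures a [GeneSignature-class] or list thereof.
#' @param layer assay to score on (default `"lognorm"`).
#' @return cells x signatures numeric matrix.
#' @export
scoreCells <- function(sce, signatures, layer = "lognorm") {
  .score_matrix(.expr_layer(sce, layer), signatures)
}

#' Fold-enrichment scores per cluster
#'
#' Same ratio as [scoreCells()], but computed on the per-cluster mean
#' expression vector: for each cluster the mean expression of every gene
#' across its cells replaces the single-cell expression.
#'
#' @param sce a `SingleCellExperiment` (or genes x cells matrix).
#' @param labels named cluster vector covering the cells.
#' @param signatures a [GeneSignature-class] or list thereof.
#' @param layer assay to score on.
#' @return clusters x signatures numeric matrix.
#' @export
scoreClusters <- function(sce, labels, signatures, layer = "lognorm") {
  expr <- .expr_layer(sce, layer)
  common <- intersect(colnames(expr), names(labels))
  if (!length(common)) stop("labels do not cover any cell")
  expr <- expr[, common, drop = FALSE]
  labels <- labels[common]
  clusters <- sort(unique(labels))
  means <- vapply(clusters, function(cl) {
    cells <- names(labels)[labels == cl]
    if (!length(cells)) stop("empty cluster: ", cl)
    rowMeans(expr[, cells, drop = FALSE])
  }, numeric(nrow(expr)))
  colnames(means) <- as.character(clusters)
  .score_matrix(means, signatures)
}

#' Threshold fold-enrichment scores into subpopulation labels
#'
#' A cell carries a programme label iff its fold-enrichment score for that
#' programme strictly exceeds the threshold (default 2.5). Cells may carry
#' zero, one, or several labels.
#'
#' @param scores cells x signatures matrix from [scoreCells()].
#' @param programmes programme (column) names to threshold.
#' @param threshold strict cutoff.
#' @return Named list: cell id -> character vector of programme names.
#' @export
assignSubpopulations <- function(scores, programmes = colnames(scores),
                                 threshold = 2.5) {
  scores <- as.matrix(scores)
  missing <- setdiff(programmes, colnames(scores))
  if (length(missing))
    stop("unknown programme(s): ", paste(missing, collapse = ", "))
  sub <- scores[, programmes, drop = FALSE] > threshold
  out <- apply(sub, 1, function(r) programmes[r], simplify = FALSE)
  names(out) <- rownames(scores)
  out
}

#' Derive cell-subtype signatures from reference differential-expression
#' tables
#'
#' For each subtype table (as produced by [clusterMarkers()] on a reference
#' atlas), the signature is the set of upregulated genes with fold change
#' strictly greater than `fc_min` (on the natural scale, i.e.
#' `exp(log_fold_change) > fc_min`) and Bonferroni-adjusted q-value below
#' `q_max`. Subtypes yielding fewer than `min_genes` usable genes are
#' skipped with a message (this happens in practice when a subtype has a
#' single upregulated gene without an expressed ortholog).
#'
#' @param reference_DE named list of data.frames with columns
#'   `gene`, `log_fold_change`, `p_bonferroni`.
#' @param fc_min fold-change cutoff (strict).
#' @param q_max adjusted-q cutoff (strict).
#' @param universe optional gene universe; genes outside it are dropped
#'   before the size check.
#' @param min_genes minimum usable genes per signature.
#' @return Named list of [GeneSignature-class]; skipped subtypes absent.
#' @export
deriveAtlasSignatures <- function(reference_DE, fc_min = 1.5, q_max = 0.05,
                                  universe = NULL, min_genes = 1L) {
  out <- list()
  for (nm in names(reference_DE)) {
    de <- reference_DE[[nm]]
    keep <- exp(de$log_fold_change) > fc_min & de$p_bonferroni < q_max
    genes <- de$gene[keep]
    if (!is.null(universe)) genes <- intersect(genes, universe)
    if (length(genes) < min_genes) {
      message("subtype '", nm, "' skipped: ", length(genes),
              " usable gene(s)")
      next
    }
    out[[nm]] <- GeneSignature(nm, genes,
                               provenance = "derived from reference DE")
  }
  out
}

#' Normalize signature scores to the tumor-cluster baseline
#'
#' Divides every score column by its mean over the cells of the tumor
#' clusters, so that a score of 1 equals the tumor baseline. Used for
#' immune-atlas signatures, whose raw fold-enrichment scale differs between
#' signatures.
#'
#' @param scores cells x signatures matrix from [scoreCells()].
#' @param tumor_cells cell ids belonging to the tumor clusters.
#' @return Rescaled score matrix.
#' @export
normalizeToTumor <- function(scores, tumor_cells) {
  scores <- as.matrix(scores)
  tumor_cells <- intersect(tumor_cells, rownames(scores))
  if (!length(tumor_cells)) stop("no tumor cells found in score table")
  base <- colMeans(scores[tumor_cells, , drop = FALSE])
  if (any(base == 0))
    stop("zero tumor-baseline mean for signature(s): ",
         paste(colnames(scores)[base == 0], collapse = ", "))
  sweep(scores, 2, base, "/")
}

#' Subsample cells per tumor type and average scores
#'
#' Draws a seeded uniform sample without replacement of up to `n` cells per
#' tumor type (all cells, with a warning, when a type has fewer), and
#' returns the mean score per signature per type over the sampled cells.
#' Used for cross-tumor-type signature comparisons so that types with many
#' cells do not dominate.
#'
#' @param scores cells x signatures matrix from [scoreCells()].
#' @param types named character vector: cell id -> tumor type.
#' @param n cells to sample per type.
#' @param seed integer seed.
#' @return list with `cells` (sampled ids) and `means`
#'   (types x signatures matrix).
#' @export
subsampleForComparison <- function(scores, types, n = 500L, seed = 1L) {
  scores <- as.matrix(scores)
  types <- types[intersect(names(types), rownames(scores))]
  set.seed(seed)
  picked <- character(0)
  for (ty in sort(unique(types))) {
    cells <- names(types)[types == ty]
    if (length(cells) <= n) {
      if (length(cells) < n)
        warning("type '", ty, "' has ", length(cells), " < ", n,
                " cells; all used")
      picked <- c(picked, cells)
    } else {
      picked <- c(picked, sample(cells, n))
    }
  }
  tys <- sort(unique(types))
  means <- matrix(NA_real_, length(tys), ncol(scores),
                  dimnames = list(tys, colnames(scores)))
  for (ty in tys) {
    cells <- intersect(picked, names(types)[types == ty])
    means[ty, ] <- colMeans(scores[cells, , drop = FALSE])
  }
  list(cells = picked, means = means)
}
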