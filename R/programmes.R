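## Gene-programme derivation from PC loadings, programme-score correlation
## analysis, and gene-list overlap statistics.

#' Derive top/bottom gene programmes from a principal component
#'
#' Takes the `n` genes with the largest (top) and smallest (bottom) signed
#' loadings on one principal component. With the sign convention of
#' [runPCA()] this yields two reproducible, disjoint gene programmes — in
#' pilocytic astrocytoma cancer cells, PC1's poles separate a MAPK-signaling
#' programme (immediate-early genes) from an astrocyte-like programme, and
#' PC2 isolates an oligodendrocyte-like programme. Ties are broken by
#' gene id.
#'
#' @param loadings named numeric vector of gene loadings for one component
#'   (a column of `runPCA()$loadings`).
#' @param n genes per pole.
#' @param names a length-2 character vector naming the top and bottom
#'   signatures.
#' @return list with `top` and `bottom` [GeneSignature-class] objects.
#' @export
deriveProgrammes <- function(loadings, n = 50L,
                             names = c("PC_top", "PC_bottom")) {
  if (is.null(base::names(loadings))) stop("loadings must be named by gene")
  if (length(loadings) < 2 * n)
    stop("need at least ", 2 * n, " genes with loadings, got ",
         length(loadings))
  ord <- order(-loadings, base::names(loadings))
  top <- base::names(loadings)[ord[seq_len(n)]]
  bottom <- rev(base::names(loadings)[ord[seq(length(loadings) - n + 1,
                                              length(loadings))]])
  list(top = GeneSignature(names[1], top, provenance = "PC loading top"),
       bottom = GeneSignature(names[2], bottom,
                              provenance = "PC loading bottom"))
}

#' Pairwise Spearman correlations between programme scores
#'
#' Computes all pairwise Spearman rank correlations (average ranks for
#' ties) between score columns and optional extra per-cell columns such as
#' single-gene expression, with two-sided p-values from the t
#' approximation and Bonferroni q-values over the pairs tested in the call.
#' Constant columns yield `NA` with a warning.
#'
#' @param scores cells x signatures matrix from [scoreCells()].
#' @param extra_columns optional cells x k matrix/data.frame of additional
#'   per-cell values (rownames matched to `scores`).
#' @return data.frame with `colA`, `colB`, `rho`, `p`, `q`, `n`.
#' @export
correlateProgrammes <- function(scores, extra_columns = NULL) {
  m <- as.matrix(scores)
  if (!is.null(extra_columns)) {
    e <- as.matrix(extra_columns)
    if (!is.null(rownames(e))) e <- e[rownames(m), , drop = FALSE]
    m <- cbind(m, e)
  }
  if (nrow(m) < 3) stop("need at least 3 cells")
  if (ncol(m) < 2) stop("need at least 2 columns")
  cols <- colnames(m)
  pairs <- combn(ncol(m), 2)
  n_pairs <- ncol(pairs)
  out <- data.frame(colA = cols[pairs[1, ]], colB = cols[pairs[2, ]],
                    rho = NA_real_, p = NA_real_, q = NA_real_,
                    n = nrow(m))
  for (i in seq_len(n_pairs)) {
    x <- m[, pairs[1, i]]; y <- m[, pairs[2, i]]
    if (sd(x) == 0 || sd(y) == 0) {
      warning("constant column in pair ", cols[pairs[1, i]], " ~ ",
              cols[pairs[2, i]], "; correlation undefined")
      next
    }
    rho <- cor(rank(x), rank(y))
    out$rho[i] <- rho
    out$p[i] <- .spearman_p(rho, nrow(m))
  }
  out$q <- pmin(1, out$p * n_pairs)
  out
}

.spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Gene-list overlap test
#'
#' One-sided Fisher's exact test (enrichment alternative) for the overlap
#' between two gene lists in a genome of `genome_size` genes (default
#' 18,000): with k shared genes the p-value is the hypergeometric upper
#' tail P(X >= k). A Bonferroni q over `n_tested` comparisons is reported.
#'
#' @param listA,listB [GeneSignature-class] objects or character vectors.
#' @param genome_size gene universe size.
#' @param n_tested number of list pairs tested in the family (Bonferroni
#'   multiplier; default 1).
#' @return list with `overlap`, `p`, `q`, and the sizes used.
#' @export
overlapTest <- function(listA, listB, genome_size = 18000L, n_tested = 1L) {
  a <- if (is(listA, "GeneSignature")) geneIds(listA) else unique(listA)
  b <- if (is(listB, "GeneSignature")) geneIds(listB) else unique(listB)
  if (length(a) > genome_size || length(b) > genome_size)
    stop("list larger than the genome universe")
  k <- length(intersect(a, b))
  if (length(a) + length(b) - k > genome_size)
    stop("union of lists exceeds the genome universe (inconsistent sizes)")
  p <- phyper(k - 1, length(a), genome_size - length(a), length(b),
              lower.tail = FALSE)
  list(overlap = k, p = p, q = min(1, p * n_tested),
       nA = length(a), nB = length(b), genome_size = genome_size)
}

#' Group-mean expression with per-gene z-scores
#'
#' Averages log-normalized expression of programme genes within each cell
#' group and standardizes each gene's means to z-scores across groups (the
#' usual heat-map scaling). A gene constant across groups maps to zeros.
#'
#' @param sce a `SingleCellExperiment` (or genes x cells matrix).
#' @param programmes a [GeneSignature-class] or list thereof; their union
#'   defines the gene rows.
#' @param groups named character vector: cell id -> group.
#' @param layer assay to use.
#' @return list with `means` and `z` (genes x groups matrices).
#' @export
meanExpressionHeatmap <- function(sce, programmes, groups,
                                  layer = "lognorm") {
  expr <- .expr_layer(sce, layer)
  if (is(programmes, "GeneSignature")) programmes <- list(programmes)
  genes <- unique(unlist(lapply(programmes, geneIds)))
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) stop("no programme genes in the expression universe")
  groups <- groups[intersect(names(groups), colnames(expr))]
  glev <- sort(unique(groups))
  means <- vapply(glev, function(g) {
    cells <- names(groups)[groups == g]
    if (!length(cells)) stop("empty group: ", g)
    rowMeans(expr[genes, cells, drop = FALSE])
  }, numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, glev))
  mu <- rowMeans(means)
  sds <- apply(means, 1, sd)
  z <- sweep(means, 1, mu, "-")
  z <- sweep(z, 1, ifelse(sds > 0, sds, 1), "/")
  z[sds == 0, ] <- 0
  list(means = means, z = z)
}
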