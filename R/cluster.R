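## PCA, shared-nearest-neighbor clustering, Wilcoxon marker detection, and
## compartment annotation.

#' Principal component analysis of scaled expression
#'
#' Runs PCA on the cells x genes matrix of scaled (covariate-regressed,
#' standardized) expression restricted to a gene set, typically the variable
#' genes. Loadings follow a deterministic sign convention: each component is
#' oriented so that its largest-magnitude loading is positive, making the
#' top/bottom poles of a component reproducible across runs and platforms.
#'
#' @param sce a `SingleCellExperiment` with a `"scaled"` assay, or a plain
#'   genes x cells numeric matrix.
#' @param genes gene ids to use (default: all rows).
#' @param n_pcs number of components to return.
#' @return list with `scores` (cells x n_pcs), `loadings` (genes x n_pcs),
#'   and `var_explained` (fraction of total variance per component).
#' @export
runPCA <- function(sce, genes = NULL, n_pcs = 7L) {
  m <- if (is(sce, "SingleCellExperiment")) as.matrix(assay(sce, "scaled"))
       else as.matrix(sce)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop("genes absent from matrix: ",
           paste(head(missing, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 cells")
  if (n_pcs > min(dim(m)) - 1)
    stop("n_pcs = ", n_pcs, " exceeds min(genes, cells) - 1 = ",
         min(dim(m)) - 1)
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE, rank. = n_pcs)
  loadings <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       var_explained = pc$sdev[seq_len(n_pcs)]^2 / total_var)
}

#' Shared-nearest-neighbor clustering
#'
#' Builds a k-nearest-neighbor graph in principal-component space (Euclidean
#' distance), weights edges by the Jaccard overlap of the two endpoints'
#' neighbor sets, and partitions the graph by modularity optimization
#' (Louvain) at the given resolution. Deterministic given `seed`.
#'
#' @param scores cells x PCs numeric matrix (rownames = cell ids).
#' @param k neighbors per cell; must be smaller than the number of cells.
#' @param resolution modularity resolution.
#' @param seed integer seed for the community detection.
#' @return Named integer vector of 0-based cluster indices (contiguous,
#'   relabeled by decreasing cluster size), with attributes `k`, `n_pcs`,
#'   `resolution`, `seed`.
#' @export
snnCluster <- function(scores, k = 150L, resolution = 0.8, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k >= n)
    stop("k = ", k, " must be smaller than the number of cells (", n,
         "); lower k")
  d <- as.matrix(stats::dist(scores))
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(d[i, -i])[seq_len(k)]
    nn[i, ] <- o + (o >= i)   # re-index past the removed self column
  }
  ## membership matrix: A[i, j] = 1 if j is one of i's k nearest neighbors
  A <- sparseMatrix(i = rep(seq_len(n), each = k), j = as.integer(t(nn)),
                    x = 1, dims = c(n, n))
  shared <- as.matrix(A %*% Matrix::t(A))
  union_nb <- as.matrix((A + Matrix::t(A)) > 0)
  jac <- shared / (2 * k - shared)
  jac[!union_nb] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  ## relabel by decreasing size for determinism
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- relab[as.character(memb)]
  names(out) <- rownames(scores)
  attr(out, "k") <- k
  attr(out, "n_pcs") <- ncol(scores)
  attr(out, "resolution") <- resolution
  attr(out, "seed") <- seed
  out
}

#' Differential expression by Wilcoxon rank-sum test
#'
#' Tests each gene for differential log-normalized expression between two
#' cell groups: either one cluster versus all other cells (`cluster` mode)
#' or an explicit pair of cell sets. P-values come from a two-sided Wilcoxon
#' rank-sum test (exact enumeration when both groups have <= 8 cells,
#' tie-corrected normal approximation otherwise); Bonferroni-adjusted
#' p-values and Benjamini-Hochberg q-values are both reported. The log fold
#' change is the difference of group means on the log-normalized scale
#' (natural-log units).
#'
#' @param sce a `SingleCellExperiment` with a `"lognorm"` assay.
#' @param labels named cluster vector as returned by [snnCluster()]
#'   (required for `cluster` mode).
#' @param cluster cluster index for one-vs-rest testing.
#' @param cells1,cells2 explicit cell-id sets for pairwise testing
#'   (overrides `cluster`).
#' @param genes gene ids to test (default: all).
#' @return data.frame with `gene`, `mean_in`, `mean_out`,
#'   `log_fold_change`, `p_value`, `p_bonferroni`, `q_bh`, ordered by
#'   increasing p-value.
#' @export
clusterMarkers <- function(sce, labels = NULL, cluster = NULL,
                           cells1 = NULL, cells2 = NULL, genes = NULL) {
  ln <- assay(sce, "lognorm")
  if (is.null(cells1)) {
    if (is.null(labels) || is.null(cluster))
      stop("supply either cells1/cells2 or labels + cluster")
    cells1 <- names(labels)[labels == cluster]
    cells2 <- names(labels)[labels != cluster]
  } else if (is.null(cells2)) {
    cells2 <- setdiff(colnames(ln), cells1)
  }
  cells1 <- intersect(cells1, colnames(ln))
  cells2 <- intersect(cells2, colnames(ln))
  if (!length(cells1) || !length(cells2))
    stop("both groups must be non-empty")
  if (length(cells1) < 3 || length(cells2) < 3)
    warning("group with fewer than 3 cells; exact test used")
  exact_max <- if (length(cells1) < 3 || length(cells2) < 3)
    max(length(cells1), length(cells2), 8L) else 8L
  if (is.null(genes)) genes <- rownames(ln)
  m1 <- as.matrix(ln[genes, cells1, drop = FALSE])
  m2 <- as.matrix(ln[genes, cells2, drop = FALSE])
  p <- numeric(length(genes))
  for (i in seq_along(genes))
    p[i] <- wilcoxonRankSum(m1[i, ], m2[i, ], exact_max = exact_max)$p.value
  mean_in <- rowMeans(m1)
  mean_out <- rowMeans(m2)
  res <- data.frame(gene = genes, mean_in = mean_in, mean_out = mean_out,
                    log_fold_change = mean_in - mean_out,
                    p_value = p,
                    p_bonferroni = pmin(1, p * length(genes)),
                    q_bh = p.adjust(p, method = "BH"),
                    row.names = NULL)
  res[order(res$p_value), ]
}

#' Assign clusters to cell compartments
#'
#' Each cluster is assigned the compartment (e.g. tumor, microglia,
#' macrophage, T cell) whose mean per-cell fold-enrichment score is maximal
#' within the cluster. Exact ties are broken by lexicographic compartment
#' name with a warning.
#'
#' @param labels named cluster vector as returned by [snnCluster()].
#' @param scores cells x signatures score matrix as returned by
#'   [scoreCells()]; columns are compartment signature names.
#' @return Named character vector: cluster index -> compartment name.
#' @export
annotateCompartments <- function(labels, scores) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("scores must have signature columns")
  common <- intersect(names(labels), rownames(scores))
  if (!length(common)) stop("no cells shared between labels and scores")
  labels <- labels[common]
  scores <- scores[common, , drop = FALSE]
  clusters <- sort(unique(labels))
  comp_names <- sort(colnames(scores))
  out <- character(length(clusters))
  names(out) <- as.character(clusters)
  for (cl in clusters) {
    mu <- colMeans(scores[labels == cl, , drop = FALSE])
    mu <- mu[comp_names]  # lexicographic tie-break: first max wins
    best <- which(mu == max(mu))
    if (length(best) > 1)
      warning("tie for cluster ", cl, "; lexicographic winner '",
              comp_names[best[1]], "' chosen")
    out[as.character(cl)] <- comp_names[best[1]]
  }
  out
}
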