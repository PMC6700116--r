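## Quality filtering, normalization, covariate regression/scaling,
## variable-gene selection, and the cancer-set immune purge.

.species_thresholds <- function(config, species) {
  min_genes <- ifelse(species == "mouse",
                      config@min_genes_mouse, config@min_genes_human)
  max_mito <- ifelse(species == "mouse",
                     config@max_mito_mouse, config@max_mito_human)
  list(min_genes = min_genes, max_mito = max_mito)
}

#' Quality-filter cells and genes
#'
#' Removes cells with too few expressed genes or too high a mitochondrial
#' count fraction, using species-specific thresholds from the config (human:
#' keep cells with >= 1000 expressed genes and <= 4% mitochondrial counts;
#' mouse: >= 3000 and <= 3%), then removes genes expressed in fewer than
#' `min_cells_per_gene` of the retained cells. "Expressed" means count > 0;
#' the mitochondrial fraction is computed on raw counts. Filtering order is
#' cells first, then genes. An attrition report (step, n_removed,
#' n_remaining) is stored in `metadata(result)$qc_report`.
#'
#' @param sce a `SingleCellExperiment` with a `"counts"` assay and a
#'   `species` column in `colData`.
#' @param config a [PipelineConfig-class].
#' @param mito_genes explicit mitochondrial gene ids; if `NULL`, genes whose
#'   id starts with one of `mito_prefixes` are used.
#' @param mito_prefixes prefixes identifying mitochondrial genes.
#' @return The filtered `SingleCellExperiment`.
#' @export
qcFilter <- function(sce, config = pipelineConfig(), mito_genes = NULL,
                     mito_prefixes = c("MT-", "mt-")) {
  counts <- assay(sce, "counts")
  species <- colData(sce)$species
  if (is.null(species)) stop("colData must carry a 'species' column")
  thr <- .species_thresholds(config, species)

  n_expressed <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  if (is.null(mito_genes)) {
    pat <- paste0("^(", paste(mito_prefixes, collapse = "|"), ")")
    mito_genes <- grep(pat, rownames(counts), value = TRUE)
  } else {
    mito_genes <- intersect(mito_genes, rownames(counts))
  }
  mito_frac <- if (length(mito_genes))
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) / pmax(totals, 1)
  else rep(0, ncol(counts))

  pass_genes <- n_expressed >= thr$min_genes
  pass_mito <- mito_frac <= thr$max_mito
  keep_cells <- pass_genes & pass_mito

  report <- data.frame(
    step = c("input", "low_gene_cells", "high_mito_cells", "rare_genes"),
    n_removed = c(0L, sum(!pass_genes), sum(pass_genes & !pass_mito), NA),
    n_remaining = c(ncol(counts), NA, sum(keep_cells), NA))

  if (!any(keep_cells))
    stop("no cells survive QC filtering\n",
         paste(utils::capture.output(print(report)), collapse = "\n"))

  kept <- sce[, keep_cells]
  prevalence <- Matrix::rowSums(assay(kept, "counts") > 0)
  keep_genes <- prevalence >= config@min_cells_per_gene
  report$n_removed[4] <- sum(!keep_genes)
  report$n_remaining[2] <- ncol(counts) - sum(!pass_genes)
  report$n_remaining[4] <- sum(keep_genes)
  if (!any(keep_genes))
    stop("no genes survive QC filtering\n",
         paste(utils::capture.output(print(report)), collapse = "\n"))

  out <- kept[keep_genes, ]
  metadata(out)$qc_report <- report
  out
}

#' Log-normalize counts
#'
#' Divides each cell's counts by the cell total, multiplies by
#' `scale_factor` (default 10,000) and applies the natural log with a
#' pseudocount of one: `value = ln(1 + count/total * scale_factor)`. The
#' result is stored as assay `"lognorm"`.
#'
#' @param sce a `SingleCellExperiment` with a `"counts"` assay.
#' @param scale_factor positive scale factor.
#' @return `sce` with an added `"lognorm"` assay.
#' @export
logNormalize <- function(sce, scale_factor = 10000) {
  counts <- assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0))
    stop("zero-total cell(s): ",
         paste(head(colnames(counts)[totals <= 0], 5), collapse = ", "))
  ln <- log1p(Matrix::t(Matrix::t(counts) / totals) * scale_factor)
  assay(sce, "lognorm") <- ln
  metadata(sce)$scale_factor <- scale_factor
  sce
}

#' Regress out covariates and scale per gene
#'
#' For every gene, takes ordinary-least-squares residuals of the
#' log-normalized expression against an intercept, the number of detected
#' genes, and tumor-of-origin indicator variables (any subset selectable via
#' `covariates`), then standardizes the residuals to mean 0 / SD 1.
#' Zero-variance genes map to all-zero rows. The result is stored as assay
#' `"scaled"`.
#'
#' @param sce a `SingleCellExperiment` with a `"lognorm"` assay.
#' @param covariates character vector among `"n_detected_genes"` and
#'   `"tumor_of_origin"`; use `character(0)` for a plain per-gene z-score.
#' @return `sce` with an added `"scaled"` assay;
#'   `metadata(sce)$regressed_covariates` records the covariates used.
#' @export
scaleAndRegress <- function(sce,
                            covariates = c("n_detected_genes",
                                           "tumor_of_origin")) {
  ln <- assay(sce, "lognorm")
  n <- ncol(ln)
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "intercept"))
  if ("n_detected_genes" %in% covariates) {
    nd <- colData(sce)$n_detected_genes
    if (is.null(nd)) nd <- Matrix::colSums(assay(sce, "counts") > 0)
    X <- cbind(X, n_detected_genes = as.numeric(nd))
  }
  if ("tumor_of_origin" %in% covariates) {
    tum <- factor(colData(sce)$tumor_of_origin)
    if (nlevels(tum) > 1) {
      ind <- stats::model.matrix(~tum)[, -1, drop = FALSE]
      X <- cbind(X, ind)
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("singular covariate design (rank ", qx$rank, " < ", ncol(X),
         " columns); consider dropping a covariate")
  res <- qr.resid(qx, as.matrix(Matrix::t(ln)))   # cells x genes
  sds <- apply(res, 2, sd)
  ## genes fully explained by the covariates leave numerically-tiny
  ## residuals; treat them as zero-variance rather than amplifying noise
  flat <- sds < 1e-10
  centered <- sweep(res, 2, colMeans(res), "-")
  scaled <- sweep(centered, 2, ifelse(flat, 1, sds), "/")
  scaled[, flat] <- 0
  assay(sce, "scaled") <- t(scaled)
  metadata(sce)$regressed_covariates <- covariates
  sce
}

#' Select variable genes
#'
#' Returns the genes whose mean log-normalized expression lies in the closed
#' interval `var_gene_mean_range` (default \[0.25, 5\]) and whose standard
#' deviation of log-normalized expression exceeds `var_gene_sd_min`
#' (default 1, strict).
#'
#' @param sce a `SingleCellExperiment` with a `"lognorm"` assay.
#' @param config a [PipelineConfig-class].
#' @return Character vector of gene ids.
#' @export
selectVariableGenes <- function(sce, config = pipelineConfig()) {
  ln <- assay(sce, "lognorm")
  mu <- Matrix::rowMeans(ln)
  n <- ncol(ln)
  ssq <- Matrix::rowSums(ln^2)
  sds <- sqrt(pmax(ssq - n * mu^2, 0) / (n - 1))
  r <- config@var_gene_mean_range
  keep <- mu >= r[1] & mu <= r[2] & sds > config@var_gene_sd_min
  genes <- rownames(ln)[keep]
  if (!length(genes))
    stop("no variable genes selected; consider relaxing ",
         "var_gene_mean_range / var_gene_sd_min")
  genes
}

#' Purge immune-like cells from a cancer cell set
#'
#' Removes from a candidate cancer cell set every cell expressing the purge
#' gene (GZMB by default, a cytotoxic-lymphocyte granzyme) above the
#' configured log-normalized cutoff (default > 1.5, strict). This mirrors
#' the removal of rare marker-positive cells that transcriptionally behave
#' as immune cells.
#'
#' @param cells character vector of candidate cancer cell ids.
#' @param sce a `SingleCellExperiment` with a `"lognorm"` assay.
#' @param config a [PipelineConfig-class]; `gzmb_filter` is the cutoff.
#' @param gene purge gene id.
#' @return The retained cell ids.
#' @export
purgeImmuneFromCancer <- function(cells, sce, config = pipelineConfig(),
                                  gene = "GZMB") {
  ln <- assay(sce, "lognorm")
  if (!gene %in% rownames(ln))
    stop("purge gene '", gene, "' absent from the gene universe")
  cells <- intersect(cells, colnames(ln))
  vals <- as.numeric(ln[gene, cells])
  cells[vals <= config@gzmb_filter]
}
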