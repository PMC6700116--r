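## Expression-based CNV inference: sliding 100-gene windowed averaging
## against an all-cancer-cell reference, plus an arm-level summary layer.

#' Infer copy-number changes from windowed expression
#'
#' Orders genes by genomic position, averages each cell's log-normalized
#' expression over sliding windows of `window` consecutive genes within
#' each chromosome (step 1; windows never span chromosomes), and centers
#' every window by subtracting its mean across the reference cell set —
#' conventionally all cancer cells, so each cell is compared to all other
#' cancer cells. Chromosomes with fewer than `window` genes contribute a
#' single truncated window, flagged in the window metadata (or an error if
#' `allow_truncated = FALSE` and no chromosome reaches the window size).
#' Genes without a position are dropped with a message; if they exceed 20%
#' of the expressed genes this is an error.
#'
#' @param sce a `SingleCellExperiment` with a `"lognorm"` assay (or a
#'   genes x cells matrix).
#' @param positions gene-position table from [readGenePositions()] /
#'   [genePositions()].
#' @param reference_cells cell ids of the reference set (default: all
#'   cells in `sce`).
#' @param window window width in genes.
#' @param allow_truncated keep truncated windows for short chromosomes.
#' @param layer assay to use.
#' @return A [CnvMatrix-class] (windows x cells).
#' @export
inferCnvWindows <- function(sce, positions, reference_cells = NULL,
                            window = 100L, allow_truncated = TRUE,
                            layer = "lognorm") {
  expr <- .expr_layer(sce, layer)
  if (is.null(reference_cells)) reference_cells <- colnames(expr)
  missing_ref <- setdiff(reference_cells, colnames(expr))
  if (length(missing_ref))
    stop("reference cells absent from the matrix: ",
         paste(head(missing_ref, 5), collapse = ", "))
  covered <- intersect(rownames(expr), positions$gene_id)
  n_drop <- nrow(expr) - length(covered)
  if (length(covered) < 0.8 * nrow(expr))
    stop("positions cover only ", length(covered), "/", nrow(expr),
         " expressed genes (>= 80% required)")
  if (n_drop > 0)
    message(n_drop, " gene(s) without positions dropped")
  pos <- positions[positions$gene_id %in% covered, ]
  pos <- pos[order(pos$chrom, pos$start, pos$gene_id), ]
  expr <- expr[pos$gene_id, , drop = FALSE]

  vals <- list(); meta <- list()
  for (chr in unique(pos$chrom)) {
    idx <- which(pos$chrom == chr)
    m <- expr[idx, , drop = FALSE]
    ng <- length(idx)
    if (ng < window) {
      vals[[chr]] <- matrix(colMeans(m), nrow = 1)
      meta[[chr]] <- data.frame(chrom = chr, first_gene = 1L,
                                last_gene = ng, truncated = TRUE)
    } else {
      cs <- apply(m, 2, cumsum)
      cs <- rbind(0, cs)
      starts <- seq_len(ng - window + 1L)
      vals[[chr]] <- (cs[starts + window, , drop = FALSE] -
                      cs[starts, , drop = FALSE]) / window
      meta[[chr]] <- data.frame(chrom = chr, first_gene = starts,
                                last_gene = starts + window - 1L,
                                truncated = FALSE)
    }
  }
  meta_df <- do.call(rbind, meta)
  if (!allow_truncated) {
    full <- !meta_df$truncated
    if (!any(full))
      stop("no chromosome reaches the window size of ", window, " genes")
    keep <- unlist(lapply(names(vals), function(chr)
      rep(!all(meta[[chr]]$truncated), nrow(meta[[chr]]))))
    vals <- vals[vapply(meta, function(m) !all(m$truncated), logical(1))]
    meta_df <- meta_df[keep, , drop = FALSE]
  }
  v <- do.call(rbind, vals)
  colnames(v) <- colnames(expr)
  rownames(v) <- rownames(meta_df) <-
    sprintf("%s_w%04d", meta_df$chrom, ave(seq_len(nrow(meta_df)),
                                           meta_df$chrom, FUN = seq_along))
  v <- v - rowMeans(v[, reference_cells, drop = FALSE])
  new("CnvMatrix", values = v, windows = meta_df,
      referenceCells = reference_cells, windowSize = as.integer(window))
}

#' Summarize windowed CNV values into arm-level calls
#'
#' Averages the reference-relative window values of each cell over
#' chromosome arms and flags a gain when the arm mean exceeds `cutoff`, a
#' loss when it falls below `-cutoff`. By default each chromosome is one
#' arm; supply `arm_map` (window id -> arm label) for finer maps. Arms with
#' zero windows are skipped with a warning.
#'
#' @param cnv a [CnvMatrix-class].
#' @param arm_map optional named character vector mapping window ids to arm
#'   labels.
#' @param cutoff non-negative flagging threshold on the arm mean.
#' @return data.frame with `cell`, `arm`, `mean`, `call`
#'   (gain / loss / neutral).
#' @export
summarizeArmCalls <- function(cnv, arm_map = NULL, cutoff = 0.1) {
  v <- cnvValues(cnv)
  w <- cnvWindows(cnv)
  if (is.null(arm_map)) {
    arm_map <- setNames(w$chrom, rownames(v))
  } else {
    missing <- setdiff(rownames(v), names(arm_map))
    if (length(missing)) {
      warning(length(missing), " window(s) without an arm skipped")
      v <- v[setdiff(rownames(v), missing), , drop = FALSE]
      arm_map <- arm_map[rownames(v)]
    }
  }
  arms <- sort(unique(arm_map))
  out <- do.call(rbind, lapply(arms, function(a) {
    rows <- names(arm_map)[arm_map == a]
    mu <- colMeans(v[rows, , drop = FALSE])
    data.frame(cell = names(mu), arm = a, mean = unname(mu),
               call = ifelse(mu > cutoff, "gain",
                             ifelse(mu < -cutoff, "loss", "neutral")))
  }))
  rownames(out) <- NULL
  out
}
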