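#' GeneSignature: a named gene set
#'
#' Immutable container for a named, non-empty set of gene identifiers with a
#' free-text provenance note. Gene identifiers are opaque, case-sensitive
#' strings; human/mouse harmonization is only ever performed through an
#' explicit mapping table (see [mapOrthologs()]).
#'
#' @slot name single character, the signature name.
#' @slot genes character vector of unique gene ids (non-empty).
#' @slot provenance single character describing where the set came from.
#'
#' @seealso [readSignatures()] to parse GMT files, [scoreCells()] to score.
#' @export
setClass("GeneSignature",
  representation(name = "character", genes = "character",
                 provenance = "character"),
  prototype(provenance = "unspecified"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "'genes' must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "'genes' must be unique")
  if (length(object@provenance) != 1L)
    msg <- c(msg, "'provenance' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param genes character vector of gene ids; duplicates are collapsed with
#'   a warning.
#' @param provenance free-text origin note.
#' @return A [GeneSignature-class] object.
#' @examples
#' sig <- GeneSignature("SENESCENCE", c("CDKN1A", "CDKN2A"))
#' geneIds(sig)
#' @export
GeneSignature <- function(name, genes, provenance = "unspecified") {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning("duplicate genes collapsed in signature '", name, "'")
    genes <- unique(genes)
  }
  new("GeneSignature", name = as.character(name), genes = genes,
      provenance = as.character(provenance))
}

#' CnvMatrix: windowed expression-based copy-number estimates
#'
#' Holds reference-centered mean expression over sliding genomic gene
#' windows (rows) for a set of cells (columns), as produced by
#' [inferCnvWindows()]. Window values are relative to the mean over the
#' reference cell set, so the per-window mean across reference cells is zero
#' by construction.
#'
#' @slot values numeric matrix, windows x cells.
#' @slot windows data.frame with one row per window: `chrom`, `first_gene`,
#'   `last_gene` (order indices within the gene ordering used), `truncated`.
#' @slot referenceCells character vector of cell ids used as reference.
#' @slot windowSize integer, nominal window width in genes.
#' @export
setClass("CnvMatrix",
  representation(values = "matrix", windows = "data.frame",
                 referenceCells = "character", windowSize = "integer"))

setValidity("CnvMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != nrow(object@windows))
    msg <- c(msg, "one metadata row per window required")
  need <- c("chrom", "first_gene", "last_gene", "truncated")
  if (!all(need %in% names(object@windows)))
    msg <- c(msg, paste("windows must have columns:",
                        paste(need, collapse = ", ")))
  ref <- intersect(object@referenceCells, colnames(object@values))
  if (length(ref) && nrow(object@values)) {
    m <- max(abs(rowMeans(object@values[, ref, drop = FALSE])))
    if (m > 1e-9)
      msg <- c(msg, "windows are not centered on the reference cells")
  }
  if (length(msg)) msg else TRUE
})

#' FractionEstimate: compartment fractions for bulk samples
#'
#' Per-sample estimated contribution of each cell compartment to a bulk
#' expression profile, as produced by [estimateFractions()]. Fractions are
#' non-negative and sum to one within each sample.
#'
#' @slot fractions numeric matrix, samples x compartments.
#' @slot scores numeric matrix, samples x compartments: the raw mean
#'   z-scores before clipping/shifting and normalization.
#' @slot signatures list of [GeneSignature-class] used for the estimate.
#' @slot genesDiscarded integer, signature genes absent from the bulk
#'   platform universe and therefore discarded.
#' @export
setClass("FractionEstimate",
  representation(fractions = "matrix", scores = "matrix",
                 signatures = "list", genesDiscarded = "integer"))

setValidity("FractionEstimate", function(object) {
  f <- object@fractions
  msg <- character()
  if (any(f < 0)) msg <- c(msg, "fractions must be non-negative")
  if (nrow(f) && max(abs(rowSums(f) - 1)) > 1e-9)
    msg <- c(msg, "fractions must sum to 1 per sample")
  if (is.null(colnames(f))) msg <- c(msg, "compartments must be named")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with the defaults used
#' throughout: species-specific QC cutoffs (human: at least 1000 expressed
#' genes and at most 4% mitochondrial counts; mouse: 3000 and 3%), the gene
#' prevalence filter (expressed in at least 10 retained cells), the
#' variable-gene window (mean log-normalized expression in \[0.25, 5\] and
#' SD > 1), the numbers of principal components (7 for the full dataset, 5
#' for the cancer-cell subset), the shared-nearest-neighbor parameter
#' (k = 150), the programme size (top/bottom 50 loading genes), the
#' fold-enrichment subpopulation threshold (> 2.5), the CNV window width
#' (100 genes), the gene-set overlap genome size (18,000), the GZMB purge
#' cutoff (> 1.5 log-normalized), the immune-atlas signature thresholds
#' (fold change > 1.5, Bonferroni-adjusted q < 0.05), and the 500-cell
#' subsample used for cross-tumor comparisons.
#'
#' @slot min_genes_human,min_genes_mouse minimum expressed genes per cell.
#' @slot max_mito_human,max_mito_mouse maximum mitochondrial count fraction.
#' @slot min_cells_per_gene gene prevalence filter on retained cells.
#' @slot var_gene_mean_range closed range for variable-gene mean expression.
#' @slot var_gene_sd_min strict lower bound on variable-gene SD.
#' @slot n_pcs_all,n_pcs_cancer principal components used.
#' @slot snn_k neighbors for the SNN graph.
#' @slot resolution modularity resolution for community detection.
#' @slot programme_size genes per programme pole.
#' @slot subpop_threshold fold-enrichment cutoff for subpopulation calls.
#' @slot cnv_window CNV window width in genes.
#' @slot overlap_genome_size gene universe for overlap tests.
#' @slot gzmb_filter log-normalized GZMB cutoff for the cancer-set purge.
#' @slot atlas_fc_min,atlas_q_max immune-atlas signature thresholds.
#' @slot heatmap_subsample cells sampled per tumor type for comparisons.
#' @slot scale_factor library-size scale factor for log-normalization.
#' @slot rng_seed seed recorded with any stochastic step.
#' @export
setClass("PipelineConfig",
  representation(
    min_genes_human = "integer", max_mito_human = "numeric",
    min_genes_mouse = "integer", max_mito_mouse = "numeric",
    min_cells_per_gene = "integer",
    var_gene_mean_range = "numeric", var_gene_sd_min = "numeric",
    n_pcs_all = "integer", n_pcs_cancer = "integer",
    snn_k = "integer", resolution = "numeric",
    programme_size = "integer", subpop_threshold = "numeric",
    cnv_window = "integer", overlap_genome_size = "integer",
    gzmb_filter = "numeric", atlas_fc_min = "numeric",
    atlas_q_max = "numeric", heatmap_subsample = "integer",
    scale_factor = "numeric", rng_seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  pos <- c("min_genes_human", "max_mito_human", "min_genes_mouse",
           "max_mito_mouse", "min_cells_per_gene", "var_gene_sd_min",
           "n_pcs_all", "n_pcs_cancer", "snn_k", "resolution",
           "programme_size", "subpop_threshold", "cnv_window",
           "overlap_genome_size", "gzmb_filter", "atlas_fc_min",
           "atlas_q_max", "heatmap_subsample", "scale_factor")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0)
      msg <- c(msg, paste0("'", s, "' must be a single positive value"))
  }
  r <- object@var_gene_mean_range
  if (length(r) != 2L || r[1] >= r[2])
    msg <- c(msg, "'var_gene_mean_range' must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' @describeIn PipelineConfig-class Constructor with pipeline defaults;
#'   any slot can be overridden by name.
#' @param ... named overrides for any slot.
#' @examples
#' cfg <- pipelineConfig(snn_k = 20L)
#' cfg@snn_k
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    min_genes_human = 1000L, max_mito_human = 0.04,
    min_genes_mouse = 3000L, max_mito_mouse = 0.03,
    min_cells_per_gene = 10L,
    var_gene_mean_range = c(0.25, 5), var_gene_sd_min = 1,
    n_pcs_all = 7L, n_pcs_cancer = 5L,
    snn_k = 150L, resolution = 0.8,
    programme_size = 50L, subpop_threshold = 2.5,
    cnv_window = 100L, overlap_genome_size = 18000L,
    gzmb_filter = 1.5, atlas_fc_min = 1.5, atlas_q_max = 0.05,
    heatmap_subsample = 500L, scale_factor = 10000, rng_seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  int_slots <- c("min_genes_human", "min_genes_mouse", "min_cells_per_gene",
                 "n_pcs_all", "n_pcs_cancer", "snn_k", "programme_size",
                 "cnv_window", "overlap_genome_size", "heatmap_subsample",
                 "rng_seed")
  for (s in int_slots) defaults[[s]] <- as.integer(defaults[[s]])
  do.call(new, c(list("PipelineConfig"), defaults))
}
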