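## Readers and writers for the standard interchange formats the pipeline
## touches: Matrix Market triplets with gene/cell TSV sidecars, dense TSV
## matrices, GMT gene sets, BED-like gene positions, and YAML configs.

.meta_defaults <- list(tumor_of_origin = "unknown",
                       marker_status = "unknown",
                       fusion_status = "not_assayed",
                       species = "human")

#' Assemble a count-matrix experiment
#'
#' Wraps a genes x cells count matrix and per-cell annotations into a
#' [SingleCellExperiment::SingleCellExperiment], validating the count-matrix
#' invariants: non-negative integral counts and unique gene/cell ids. Missing
#' annotation columns (`tumor_of_origin`, `marker_status`, `fusion_status`,
#' `species`) are filled with neutral defaults.
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts, with rownames (gene ids) and colnames (cell ids).
#' @param cell_meta optional data.frame of per-cell annotations, rownames or
#'   a `cell_id` column matching `colnames(counts)`.
#' @return A `SingleCellExperiment` with assay `"counts"`.
#' @export
makeCountsSCE <- function(counts, cell_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and cell ids as colnames")
  .check_ids(rownames(counts), "gene")
  .check_ids(colnames(counts), "cell")
  .check_count_values(counts)
  meta <- data.frame(row.names = colnames(counts))
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if ("cell_id" %in% names(cell_meta)) {
      rownames(cell_meta) <- cell_meta$cell_id
      cell_meta$cell_id <- NULL
    }
    missing <- setdiff(colnames(counts), rownames(cell_meta))
    if (length(missing))
      stop("cell_meta does not cover cells: ",
           paste(head(missing, 5), collapse = ", "))
    meta <- cell_meta[colnames(counts), , drop = FALSE]
  }
  for (f in names(.meta_defaults))
    if (is.null(meta[[f]])) meta[[f]] <- .meta_defaults[[f]]
  SingleCellExperiment(assays = list(counts = counts),
                       colData = DataFrame(meta))
}

.check_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate ", what, " ids: ", paste(head(dup, 5), collapse = ", "))
  }
  invisible(TRUE)
}

.check_count_values <- function(counts) {
  x <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(x)) {
    if (any(x < 0)) stop("negative counts are not allowed")
    if (any(x != round(x))) stop("non-integer counts are not allowed")
  }
  invisible(TRUE)
}

#' Read a count matrix
#'
#' Reads a genes x cells count matrix either from a Matrix Market triplet
#' file with `genes.tsv` and `cells.tsv`/`barcodes.tsv` sidecars (10x-style
#' orientation: genes are rows), or from a dense TSV whose first column
#' holds gene ids and whose header holds cell ids. The cell sidecar may
#' carry annotation columns beyond the id, which are stored in `colData`.
#'
#' @param path path to the `.mtx` file (or its directory) for
#'   `format = "mtx"`, or to the TSV matrix for `format = "tsv"`.
#' @param format `"mtx"` or `"tsv"`.
#' @return A `SingleCellExperiment` with assay `"counts"`.
#' @seealso [writeCounts()] for the inverse operation.
#' @export
readCounts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (format == "mtx") .read_counts_mtx(path) else .read_counts_tsv(path)
}

.read_counts_mtx <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    dir <- path
  } else {
    mtx <- path
    dir <- dirname(path)
  }
  if (!file.exists(mtx)) stop("no such file: ", mtx)
  genes_f <- file.path(dir, "genes.tsv")
  cells_f <- file.path(dir, "cells.tsv")
  if (!file.exists(cells_f)) cells_f <- file.path(dir, "barcodes.tsv")
  if (!file.exists(genes_f) || !file.exists(cells_f))
    stop("MTX sidecars genes.tsv and cells.tsv/barcodes.tsv required in ", dir)
  m <- tryCatch(as(readMM(mtx), "CsparseMatrix"),
                error = function(e)
                  stop("malformed Matrix Market file ", mtx, ": ",
                       conditionMessage(e)))
  genes <- read.table(genes_f, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "")
  cells <- read.table(cells_f, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "")
  if (!"cell_id" %in% names(cells)) {
    ## headerless barcode file: re-read without header
    cells <- read.table(cells_f, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE, quote = "")
    names(cells)[1] <- "cell_id"
  }
  if (nrow(genes) != nrow(m))
    stop("genes.tsv has ", nrow(genes), " rows but matrix has ", nrow(m))
  if (nrow(cells) != ncol(m))
    stop("cell sidecar has ", nrow(cells), " rows but matrix has ", ncol(m))
  rownames(m) <- genes[[1]]
  colnames(m) <- cells$cell_id
  makeCountsSCE(m, cell_meta = cells)
}

.read_counts_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 2)
    stop("malformed dense TSV (need gene-id column + >=1 cell column): ", path)
  genes <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in dense TSV: ", path)
  rownames(m) <- genes
  makeCountsSCE(m)
}

#' Write a count matrix
#'
#' Inverse of [readCounts()]: writes the `"counts"` assay as a Matrix Market
#' triplet with `genes.tsv` and `cells.tsv` sidecars (the cell sidecar keeps
#' all `colData` columns), or as a dense TSV.
#'
#' @param sce a `SingleCellExperiment` with a `"counts"` assay.
#' @param path output directory (`"mtx"`) or file (`"tsv"`).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(sce, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  counts <- assay(sce, "counts")
  if (format == "mtx") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    writeMM(as(Matrix(counts, sparse = TRUE), "generalMatrix"),
            file.path(path, "matrix.mtx"))
    write.table(data.frame(gene_id = rownames(counts)),
                file.path(path, "genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    meta <- as.data.frame(colData(sce))
    meta <- cbind(cell_id = colnames(counts), meta)
    write.table(meta, file.path(path, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = rownames(counts),
                      as.matrix(counts), check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are collapsed with a warning; a line without genes is
#' an error naming the line number.
#'
#' @param path path to the GMT file.
#' @return Named list of [GeneSignature-class] objects.
#' @export
readSignatures <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || !any(nzchar(f[-(1:2)])))
      stop("GMT line ", i, " has an empty gene list")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    sigs[[i]] <- GeneSignature(f[1], genes, provenance = f[2])
  }
  names(sigs) <- vapply(sigs, signatureName, character(1))
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures list of [GeneSignature-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignatures <- function(signatures, path) {
  lines <- vapply(signatures, function(s)
    paste(c(signatureName(s), provenance(s), geneIds(s)), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene genomic positions from a BED-like TSV
#'
#' Expects columns `chrom`, `start`, `end`, `gene_id` (tab-separated, with
#' header). Internally positions are always 0-based half-open; set
#' `one_based = TRUE` for 1-based inclusive input, which is converted on
#' read. An `order_index` giving the rank of each gene within its chromosome
#' (by start coordinate, ties broken by gene id) is added.
#'
#' @param path input TSV path.
#' @param one_based logical; convert 1-based inclusive coordinates.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `order_index`.
#' @export
readGenePositions <- function(path, one_based = FALSE) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(tab)))
    stop("positions file must have columns: ", paste(need, collapse = ", "))
  if (one_based) tab$start <- tab$start - 1L
  if (any(tab$start < 0)) stop("negative start coordinates")
  .check_ids(tab$gene_id, "gene")
  genePositions(tab$gene_id, tab$chrom, tab$start, tab$end)
}

#' Build a gene-position table
#'
#' @param gene_id,chrom,start,end parallel vectors (0-based half-open).
#' @return data.frame as in [readGenePositions()].
#' @export
genePositions <- function(gene_id, chrom, start, end = start + 1L) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$gene_id), ]
  df$order_index <- stats::ave(seq_len(nrow(df)), df$chrom,
                               FUN = seq_along)
  rownames(df) <- df$gene_id
  df
}

#' Map a signature across species through an ortholog table
#'
#' Converts gene ids through a user-supplied one-to-one (or one-to-none)
#' mapping, e.g. mouse symbols to human orthologs. Unmapped genes are
#' dropped and counted in the provenance note; an entirely unmapped
#' signature is an error.
#'
#' @param signature a [GeneSignature-class].
#' @param table named character vector (`from -> to`) or two-column
#'   data.frame (`from`, `to`).
#' @return A mapped [GeneSignature-class].
#' @export
mapOrthologs <- function(signature, table) {
  if (is.data.frame(table)) {
    stopifnot(ncol(table) >= 2)
    table <- setNames(as.character(table[[2]]), as.character(table[[1]]))
  }
  if (anyDuplicated(names(table)))
    stop("ortholog table must be one-to-one or one-to-none")
  mapped <- table[geneIds(signature)]
  dropped <- sum(is.na(mapped))
  mapped <- unname(mapped[!is.na(mapped)])
  if (!length(mapped))
    stop("signature '", signatureName(signature), "' empty after mapping")
  GeneSignature(signatureName(signature), unique(mapped),
                provenance = paste0(provenance(signature),
                                    "; ortholog-mapped (", dropped,
                                    " gene(s) dropped)"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return [readPipelineConfig()] returns a [PipelineConfig-class];
#'   [writePipelineConfig()] returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param config a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}
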