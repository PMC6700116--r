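#' @rdname GeneSignature-class
#' @param object a `GeneSignature`.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GeneSignature-class
#' @export
setGeneric("signatureName", function(object) standardGeneric("signatureName"))

#' @rdname GeneSignature-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname GeneSignature-class
#' @export
setMethod("geneIds", "GeneSignature", function(object) object@genes)

#' @rdname GeneSignature-class
#' @export
setMethod("signatureName", "GeneSignature", function(object) object@name)

#' @rdname GeneSignature-class
#' @export
setMethod("provenance", "GeneSignature", function(object) object@provenance)

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "': ", length(object@genes),
      " genes (", object@provenance, ")\n", sep = "")
  g <- object@genes
  cat("  ", paste(head(g, 6), collapse = ", "),
      if (length(g) > 6) ", ..." else "", "\n", sep = "")
})

#' @rdname CnvMatrix-class
#' @param object a `CnvMatrix`.
#' @export
setGeneric("cnvValues", function(object) standardGeneric("cnvValues"))

#' @rdname CnvMatrix-class
#' @export
setGeneric("cnvWindows", function(object) standardGeneric("cnvWindows"))

#' @rdname CnvMatrix-class
#' @export
setMethod("cnvValues", "CnvMatrix", function(object) object@values)

#' @rdname CnvMatrix-class
#' @export
setMethod("cnvWindows", "CnvMatrix", function(object) object@windows)

setMethod("show", "CnvMatrix", function(object) {
  cat("CnvMatrix: ", nrow(object@values), " windows (",
      length(unique(object@windows$chrom)), " chromosomes) x ",
      ncol(object@values), " cells; window size ", object@windowSize,
      " genes; ", length(object@referenceCells), " reference cells\n",
      sep = "")
})

#' @rdname FractionEstimate-class
#' @param object a `FractionEstimate`.
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname FractionEstimate-class
#' @export
setGeneric("genesDiscarded", function(object) standardGeneric("genesDiscarded"))

#' @rdname FractionEstimate-class
#' @export
setGeneric("compartmentScores",
           function(object) standardGeneric("compartmentScores"))

#' @rdname FractionEstimate-class
#' @export
setMethod("compartmentScores", "FractionEstimate",
          function(object) object@scores)

#' @rdname FractionEstimate-class
#' @export
setMethod("fractions", "FractionEstimate", function(object) object@fractions)

#' @rdname FractionEstimate-class
#' @export
setMethod("genesDiscarded", "FractionEstimate",
          function(object) object@genesDiscarded)

setMethod("show", "FractionEstimate", function(object) {
  cat("FractionEstimate: ", nrow(object@fractions), " samples x ",
      ncol(object@fractions), " compartments (",
      paste(colnames(object@fractions), collapse = ", "), ")\n",
      "  mean fractions: ",
      paste(sprintf("%s=%.2f", colnames(object@fractions),
                    colMeans(object@fractions)), collapse = ", "),
      "\n  signature genes discarded: ", object@genesDiscarded, "\n",
      sep = "")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %-20s %s\n", s,
                paste(format(slot(object, s)), collapse = ", ")))
})
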