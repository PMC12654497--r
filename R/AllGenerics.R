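#' Kingdom names present in an object
#' @param x object
#' @export
setGeneric("kingdomNames", function(x) standardGeneric("kingdomNames"))

#' Sample identifiers
#' @param x object
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Number of samples
#' @param x object
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Per-kingdom taxon counts
#' @param x object
#' @export
setGeneric("taxaPerKingdom", function(x) standardGeneric("taxaPerKingdom"))

#' Extract one kingdom's samples x taxa matrix
#' @param x object
#' @param kingdom kingdom name
#' @export
setGeneric("kingdomMatrix", function(x, kingdom) standardGeneric("kingdomMatrix"))

#' Subtype labels
#' @param x object
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' Fused similarity matrix
#' @param x object
#' @export
setGeneric("fusedMatrix", function(x) standardGeneric("fusedMatrix"))

#' Kingdom weights used in fusion
#' @param x object
#' @export
setGeneric("fusionWeights", function(x) standardGeneric("fusionWeights"))

#' Silhouette trace of the cluster-number scan
#' @param x object
#' @export
setGeneric("silhouetteTrace", function(x) standardGeneric("silhouetteTrace"))

#' Tabular view of a result object
#' @param x object
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' SparCC correlation matrix
#' @param x object
#' @export
setGeneric("sparccRho", function(x) standardGeneric("sparccRho"))

#' Adjusted p-value matrix
#' @param x object
#' @export
setGeneric("adjustedP", function(x) standardGeneric("adjustedP"))

#' @rdname kingdomNames
setMethod("kingdomNames", "MultiKingdomTable", function(x) names(x@assays))

#' @rdname sampleIDs
setMethod("sampleIDs", "MultiKingdomTable", function(x) rownames(x@assays[[1L]]))

#' @rdname nSamples
setMethod("nSamples", "MultiKingdomTable", function(x) nrow(x@assays[[1L]]))

#' @rdname taxaPerKingdom
setMethod("taxaPerKingdom", "MultiKingdomTable",
          function(x) vapply(x@assays, ncol, 0L))

#' @rdname kingdomMatrix
setMethod("kingdomMatrix", "MultiKingdomTable", function(x, kingdom) {
  if (!kingdom %in% names(x@assays))
    stop("no assay for kingdom '", kingdom, "'")
  x@assays[[kingdom]]
})

#' @rdname subtypeLabels
setMethod("subtypeLabels", "FusionResult", function(x) x@labels)

#' @rdname fusedMatrix
setMethod("fusedMatrix", "FusionResult", function(x) x@fused)

#' @rdname fusionWeights
setMethod("fusionWeights", "FusionResult", function(x) x@weights)

#' @rdname silhouetteTrace
setMethod("silhouetteTrace", "FusionResult", function(x) x@silhouette)

#' @rdname resultTable
setMethod("resultTable", "DifferentialResult", function(x) x@table)

#' @rdname sparccRho
setMethod("sparccRho", "SparccResult", function(x) x@rho)

#' @rdname adjustedP
setMethod("adjustedP", "SparccResult", function(x) x@padj)
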