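#' Extract the dosage matrix
#'
#' @param x a [GenotypeCalls-class] object
#' @return integer matrix (markers x accessions) of alt-allele dosages with
#'   `NA` for missing calls.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeCalls", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' Marker map as a data.frame
#'
#' @param x a [GenotypeCalls-class] object
#' @return data.frame with columns `id`, `contig`, `position`, `ref`, `alt`,
#'   `variantClass`, one row per marker in matrix order.
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname markerTable
#' @export
setMethod("markerTable", "GenotypeCalls", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    mc <- S4Vectors::mcols(rr)
    data.frame(id = names(rr),
               contig = as.character(GenomicRanges::seqnames(rr)),
               position = GenomicRanges::start(rr),
               ref = as.character(mc$ref), alt = as.character(mc$alt),
               variantClass = as.character(mc$variantClass),
               row.names = NULL, stringsAsFactors = FALSE)
})

#' Similarity matrix accessors
#'
#' `similarityValues` returns the symmetric GS matrix, `overlapCounts` the
#' matrix of shared genotyped locus counts, and `asDissimilarity` exports
#' `1 - GS` as a `dist` object for downstream distance consumers
#' (ordination, neighbour-joining trees).
#'
#' @param x a [PairwiseSimilarity-class] object
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' @rdname similarityValues
#' @export
setMethod("similarityValues", "PairwiseSimilarity", function(x) x@similarity)

#' @rdname similarityValues
#' @export
setGeneric("overlapCounts", function(x) standardGeneric("overlapCounts"))

#' @rdname similarityValues
#' @export
setMethod("overlapCounts", "PairwiseSimilarity", function(x) x@overlap)

#' @rdname similarityValues
#' @export
setGeneric("asDissimilarity", function(x) standardGeneric("asDissimilarity"))

#' @rdname similarityValues
#' @export
setMethod("asDissimilarity", "PairwiseSimilarity", function(x)
    stats::as.dist(1 - x@similarity))
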