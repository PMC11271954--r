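#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats cor rbinom rpois runif rnorm rbeta setNames complete.cases
#' @importFrom utils read.delim write.table combn head tail
NULL

#' GenotypeCalls: biallelic genotypes as alt-allele dosage
#'
#' An S4 container for a matrix of biallelic SNP/Indel genotype calls, built on
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are markers
#' (with genomic position held as a `GRanges` and REF/ALT alleles in its
#' metadata columns), columns are accessions. The single assay `"dosage"`
#' codes each call as the count of the alternate allele: `0` (homozygous
#' reference, "AA"), `1` (heterozygous, "AB"), `2` (homozygous alternate,
#' "BB"), with `NA` for missing data.
#'
#' Accession metadata (columns `role`, `group`, `date` where available) lives
#' in `colData`, following the convention that each accession is analysed as a
#' possible `parent`, `offspring`, or `all` (both).
#'
#' @slot ... inherits all slots from `RangedSummarizedExperiment`.
#' @seealso [genotypeCalls()] the constructor, [readGenotypes()],
#'   [dosage()], [markerTable()]
#' @export
setClass("GenotypeCalls", contains = "RangedSummarizedExperiment")

.validGenotypeCalls <- function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        v <- d[!is.na(d)]
        if (length(v) && !all(v %in% c(0L, 1L, 2L)))
            msg <- c(msg, "dosage calls must be 0, 1, 2 or NA")
    }
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "marker ids (rownames) must be present and unique")
    cn <- colnames(object)
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "accession ids (colnames) must be present and unique")
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
    if (!all(c("ref", "alt") %in% colnames(mc)))
        msg <- c(msg, "rowRanges mcols must contain 'ref' and 'alt'")
    else if (nrow(mc) && any(as.character(mc$ref) == as.character(mc$alt)))
        msg <- c(msg, "ref and alt alleles must differ")
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeCalls", .validGenotypeCalls)

#' Construct a GenotypeCalls object
#'
#' @param dosage integer matrix of alt-allele dosages (markers x accessions),
#'   values in `{0,1,2,NA}`; rownames are marker ids, colnames accession ids.
#' @param contig,position character / integer vectors of marker coordinates
#'   (positions 1-based, as read from VCF).
#' @param ref,alt allele labels per marker.
#' @param variantClass optional per-marker class, `"SNP"` or `"Indel"`.
#'   Inferred from allele lengths when `NULL`.
#' @param colData optional `DataFrame`/data.frame of accession metadata.
#' @return a [GenotypeCalls-class] object.
#' @examples
#' m <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("m1", "m2"), c("acc1", "acc2")))
#' gc <- genotypeCalls(m, contig = c("c1", "c1"), position = c(100L, 700L),
#'                     ref = c("A", "T"), alt = c("G", "C"))
#' dosage(gc)
#' @export
genotypeCalls <- function(dosage, contig, position, ref, alt,
                          variantClass = NULL, colData = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("m", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("acc", seq_len(ncol(dosage)))
    ref <- as.character(ref); alt <- as.character(alt)
    if (is.null(variantClass))
        variantClass <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "Indel")
    if (any(position < 0)) stop("marker positions must be >= 0")
    rr <- GenomicRanges::GRanges(
        seqnames = as.character(contig),
        ranges = IRanges::IRanges(start = as.integer(position), width = 1L),
        ref = ref, alt = alt, variantClass = variantClass)
    names(rr) <- rownames(dosage)
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(dosage))
    else {
        colData <- S4Vectors::DataFrame(colData)
        rownames(colData) <- colnames(dosage)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = rr, colData = colData)
    methods::new("GenotypeCalls", se)
}

#' @describeIn GenotypeCalls-class compact display
#' @param object a `GenotypeCalls`
#' @export
setMethod("show", "GenotypeCalls", function(object) {
    d <- SummarizedExperiment::assay(object, "dosage")
    cat("GenotypeCalls:", nrow(object), "markers x", ncol(object), "accessions\n")
    cat("  contigs:", length(unique(as.character(
        GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object))))),
        " missing calls:", sprintf("%.2f%%", 100 * mean(is.na(d))), "\n")
})

#' Similarity between all accession pairs
#'
#' Symmetric matrix of modified Gower similarities together with the number of
#' loci genotyped in both members of each pair. Cells whose shared-locus count
#' falls below `minOverlap` are `NA` (undefined) rather than a misleading
#' value.
#'
#' @slot similarity numeric symmetric matrix of GS values in `[0, 1]`.
#' @slot overlap integer symmetric matrix of shared genotyped locus counts.
#' @slot minOverlap the overlap threshold below which GS is undefined.
#' @seealso [similarityMatrix()], [cloneGroups()]
#' @export
setClass("PairwiseSimilarity",
         representation(similarity = "matrix", overlap = "matrix",
                        minOverlap = "numeric"))

setValidity("PairwiseSimilarity", function(object) {
    s <- object@similarity; o <- object@overlap
    msg <- NULL
    if (!identical(dim(s), dim(o))) msg <- c(msg, "dimension mismatch")
    if (nrow(s) != ncol(s)) msg <- c(msg, "matrix must be square")
    v <- s[!is.na(s)]
    if (length(v) && (any(v < -1e-12) || any(v > 1 + 1e-12)))
        msg <- c(msg, "GS values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn PairwiseSimilarity-class compact display
#' @param object a `PairwiseSimilarity`
#' @export
setMethod("show", "PairwiseSimilarity", function(object) {
    s <- object@similarity
    off <- s[upper.tri(s)]
    cat("PairwiseSimilarity:", nrow(s), "accessions;",
        sum(is.na(off)), "undefined pairs (overlap <", object@minOverlap, ")\n")
    if (any(!is.na(off)))
        cat("  GS range:", sprintf("%.4f - %.4f", min(off, na.rm = TRUE),
                                   max(off, na.rm = TRUE)), "\n")
})
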