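#' Read a genotype matrix from VCF or tabular text
#'
#' VCF input is parsed with \pkg{vcfR}; only the GT field is consumed and
#' calls are recoded to alt-allele dosage. Multi-allelic records are skipped
#' with a message reporting the count. The tabular format is a tab-separated
#' file with a header row `id contig position ref alt <accession ids...>` and
#' one row per marker, calls coded `0/1/2/NA`.
#'
#' @param path path to the input file.
#' @param format `"vcf"` or `"table"`; guessed from the file extension when
#'   missing.
#' @return a [GenotypeCalls-class] object; marker order follows file order.
#'   The number of skipped multi-allelic records is attached as attribute
#'   `"skippedMultiallelic"`.
#' @export
readGenotypes <- function(path, format = c("vcf", "table")) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (missing(format))
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "table"
    format <- match.arg(format)
    if (format == "vcf") .readVcf(path) else .readTable(path)
}

.readVcf <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt)
    nskip <- sum(multi)
    if (nskip > 0) {
        message("skipped ", nskip, " multi-allelic record(s)")
        v <- v[!multi, ]
        fix <- fix[!multi, , drop = FALSE]
    }
    if (nrow(fix) == 0L) stop("no biallelic records in ", path)
    ids <- fix[, "ID"]
    auto <- is.na(ids) | ids == "." | ids == ""
    ids[auto] <- paste0(fix[auto, "CHROM"], "_", fix[auto, "POS"])
    if (anyDuplicated(ids)) stop("duplicate marker ids in ", path)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(fix), names(gt)))
    d <- .gtToDosage(gt)
    if (anyDuplicated(colnames(d))) stop("duplicate accession ids in ", path)
    rownames(d) <- ids
    out <- genotypeCalls(d, contig = fix[, "CHROM"],
                         position = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"])
    attr(out, "skippedMultiallelic") <- nskip
    out
}

.gtToDosage <- function(gt) {
    d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    d[clean %in% c("0/0")] <- 0L
    d[clean %in% c("0/1", "1/0")] <- 1L
    d[clean %in% c("1/1")] <- 2L
    d
}

.readTable <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    need <- c("id", "contig", "position", "ref", "alt")
    if (!all(need %in% colnames(tab)[1:5]))
        stop("malformed table: first five columns must be ",
             paste(need, collapse = ", "))
    if (anyDuplicated(tab$id)) stop("duplicate marker ids in ", path)
    acc <- colnames(tab)[-(1:5)]
    if (anyDuplicated(acc)) stop("duplicate accession ids in ", path)
    d <- as.matrix(tab[, -(1:5), drop = FALSE])
    storage.mode(d) <- "integer"
    rownames(d) <- tab$id
    genotypeCalls(d, contig = tab$contig, position = tab$position,
                  ref = tab$ref, alt = tab$alt)
}

#' Write a genotype matrix
#'
#' VCF output is a minimal, deterministic VCF 4.2 with a GT-only FORMAT; the
#' tabular format mirrors [readGenotypes()]. Output from either format
#' reloads to an identical object.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param path output path.
#' @param format `"vcf"` or `"table"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path, format = c("vcf", "table")) {
    format <- match.arg(format)
    mt <- markerTable(x)
    d <- dosage(x)
    if (format == "table") {
        gt <- d
        tab <- cbind(mt[, c("id", "contig", "position", "ref", "alt")],
                     as.data.frame(gt, check.names = FALSE))
        con <- file(path, open = "wt")
        on.exit(close(con))
        writeLines(paste(colnames(tab), collapse = "\t"), con)
        if (nrow(tab))
            write.table(tab, con, sep = "\t", quote = FALSE,
                        row.names = FALSE, col.names = FALSE)
        return(invisible(path))
    }
    gtmap <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(d), ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gtmap[d[ok] + 1L]
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(d)), collapse = "\t"))
    body <- character(0)
    if (nrow(d)) {
        left <- paste(mt$contig, mt$position, mt$id, mt$ref, mt$alt,
                      ".", ".", ".", "GT", sep = "\t")
        calls <- apply(gt, 1L, paste, collapse = "\t")
        body <- if (ncol(d)) paste(left, calls, sep = "\t") else left
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Combine genotype sets over accessions
#'
#' Column-binds [GenotypeCalls-class] objects sharing the same marker set,
#' harmonizing accession metadata columns (absent columns are filled with
#' `NA`).
#'
#' @param ... `GenotypeCalls` objects with identical markers.
#' @return a single [GenotypeCalls-class].
#' @export
combineAccessions <- function(...) {
    xs <- list(...)
    stopifnot(length(xs) >= 1L)
    cols <- unique(unlist(lapply(xs, function(x)
        colnames(SummarizedExperiment::colData(x)))))
    xs <- lapply(xs, function(x) {
        cd <- SummarizedExperiment::colData(x)
        for (cc in setdiff(cols, colnames(cd))) cd[[cc]] <- NA
        SummarizedExperiment::colData(x) <- cd[, cols, drop = FALSE]
        x
    })
    methods::new("GenotypeCalls", do.call(SummarizedExperiment::cbind, xs))
}

#' Read accession metadata
#'
#' CSV with columns `id`, `role` (one of `parent`, `offspring`, `all`), and
#' optional `group` (reference species/subspecies label) and `date` (year of
#' origin or introduction, used to orient significant dyads: older = parent).
#'
#' @param path path to the CSV file.
#' @return data.frame with the validated columns.
#' @export
readAccessionMeta <- function(path) {
    m <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "role") %in% colnames(m)))
        stop("metadata must contain columns 'id' and 'role'")
    bad <- setdiff(unique(m$role), c("parent", "offspring", "all"))
    if (length(bad))
        stop("invalid role(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(m$id)) stop("duplicate accession ids in metadata")
    if (is.null(m$group)) m$group <- NA_character_
    if (is.null(m$date)) m$date <- NA_integer_
    m
}

#' Per-marker summary statistics
#'
#' Minor allele frequency is computed from allele counts over non-missing
#' calls (`p = dosage sum / (2 * n called)`, `maf = min(p, 1 - p)`); the
#' heterozygote frequency is the fraction of non-missing calls that are
#' heterozygous; the missing rate is over all accessions. Markers with no
#' non-missing call get `NA` for maf and het rate rather than an error.
#'
#' @param x a [GenotypeCalls-class] object.
#' @return data.frame with one row per marker: `id`, `nCalled`, `pAlt`,
#'   `maf`, `hetRate`, `missingRate`.
#' @export
markerStats <- function(x) {
    d <- dosage(x)
    n <- ncol(d)
    called <- rowSums(!is.na(d))
    p <- rowSums(d, na.rm = TRUE) / (2 * called)
    p[called == 0L] <- NA_real_
    het <- rowSums(d == 1L, na.rm = TRUE) / called
    het[called == 0L] <- NA_real_
    data.frame(id = rownames(d), nCalled = called, pAlt = p,
               maf = pmin(p, 1 - p), hetRate = het,
               missingRate = 1 - called / n,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on MAF, missingness and heterozygote frequency
#'
#' Retains markers with `maf >= mafMin`, `missingRate <= missingMax` and
#' `hetRate <= hetMax` (conjunctive; the defaults are the standard
#' RADseq/GBS filter set MAF >= 0.05, missing <= 0.10, het <= 0.90).
#' Markers with undefined statistics (all calls missing) are removed.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param mafMin,missingMax,hetMax thresholds in `[0, 1]`.
#' @return the filtered [GenotypeCalls-class]; counts of markers failing each
#'   criterion are attached as attribute `"removedCounts"`.
#' @export
filterMarkers <- function(x, mafMin = 0.05, missingMax = 0.10, hetMax = 0.90) {
    stopifnot(mafMin >= 0, mafMin <= 1, missingMax >= 0, missingMax <= 1,
              hetMax >= 0, hetMax <= 1)
    st <- markerStats(x)
    okMaf <- !is.na(st$maf) & st$maf >= mafMin
    okMiss <- st$missingRate <= missingMax
    okHet <- is.na(st$hetRate) | st$hetRate <= hetMax
    keep <- okMaf & okMiss & okHet
    if (!any(keep)) message("filterMarkers: no markers retained")
    out <- x[keep, ]
    attr(out, "removedCounts") <- c(maf = sum(!okMaf), missing = sum(!okMiss),
                                    het = sum(!okHet & okMaf))
    out
}

.binIndex <- function(position, windowBp) position %/% windowBp

#' Thin markers to one per genomic window
#'
#' Per contig, markers are binned into non-overlapping half-open windows
#' `[k*windowBp, (k+1)*windowBp)` anchored at coordinate 0, and within each
#' bin the single marker with the highest heterozygote frequency is kept
#' (ties broken by lowest missing rate, then smallest position).
#'
#' @param x a [GenotypeCalls-class] object with marker positions.
#' @param windowBp window size in base pairs (default 500 nt).
#' @return the thinned [GenotypeCalls-class], at most one marker per
#'   (contig, window).
#' @export
thinByWindow <- function(x, windowBp = 500) {
    mt <- markerTable(x)
    if (any(is.na(mt$position))) stop("markers must have positions")
    st <- markerStats(x)
    bin <- .binIndex(mt$position, windowBp)
    key <- paste(mt$contig, bin, sep = "\r")
    het <- ifelse(is.na(st$hetRate), -1, st$hetRate)
    ord <- order(key, -het, st$missingRate, mt$position)
    keep <- ord[!duplicated(key[ord])]
    x[sort(keep), ]
}

#' Prune markers in linkage disequilibrium
#'
#' Greedy windowed LD pruning on the squared Pearson correlation of dosages
#' (pairwise-complete observations). Within each sliding window of
#' `windowMarkers` markers (step `stepMarkers`), while any pair exceeds
#' `r2Max`, the member with the higher missing rate (tie: later position) of
#' the worst pair is dropped. Passes repeat until a full pass removes
#' nothing. Zero-variance pairs are treated as uncorrelated.
#'
#' @param x a [GenotypeCalls-class] object, markers ordered by
#'   (contig, position); reorder first if needed.
#' @param r2Max squared-correlation threshold (markers with `r2 > r2Max`
#'   conflict).
#' @param windowMarkers,stepMarkers sliding window size and step, in markers.
#' @return the pruned [GenotypeCalls-class].
#' @export
ldPrune <- function(x, r2Max = 0.5, windowMarkers = 100, stepMarkers = 10) {
    st <- markerStats(x)
    mt <- markerTable(x)
    d <- t(dosage(x))            # accessions x markers for cor()
    alive <- rep(TRUE, ncol(d))
    repeat {
        removedThisPass <- FALSE
        idxAlive <- which(alive)
        m <- length(idxAlive)
        if (m < 2L) break
        starts <- seq(1L, max(1L, m - 1L), by = stepMarkers)
        for (s in starts) {
            win <- idxAlive[s:min(s + windowMarkers - 1L, m)]
            win <- win[alive[win]]
            if (length(win) < 2L) next
            r <- suppressWarnings(cor(d[, win, drop = FALSE],
                                      use = "pairwise.complete.obs"))
            r2 <- r * r
            r2[is.na(r2)] <- 0
            diag(r2) <- 0
            while (max(r2) > r2Max) {
                worst <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
                i <- win[worst[1L]]; j <- win[worst[2L]]
                drop <- if (st$missingRate[i] != st$missingRate[j]) {
                    if (st$missingRate[i] > st$missingRate[j]) i else j
                } else if (mt$position[i] >= mt$position[j]) i else j
                alive[drop] <- FALSE
                removedThisPass <- TRUE
                k <- match(drop, win)
                r2[k, ] <- 0; r2[, k] <- 0
            }
        }
        if (!removedThisPass) break
    }
    x[alive, ]
}

#' Randomly thin to a target marker count
#'
#' Uniform sample without replacement, reproducible under `seed`; surviving
#' markers keep their original order.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param nTarget number of markers to retain.
#' @param seed integer seed.
#' @return a [GenotypeCalls-class] with exactly `nTarget` markers.
#' @export
randomThin <- function(x, nTarget = 1000, seed = 1) {
    if (nTarget > nrow(x))
        stop("nTarget (", nTarget, ") exceeds marker count (", nrow(x), ")")
    keep <- withr::with_seed(seed, sort(sample.int(nrow(x), nTarget)))
    x[keep, ]
}
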