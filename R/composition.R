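#' Select species-diagnostic marker panels from reference accessions
#'
#' A marker enters a species' panel when, over the pooled reference
#' accessions, it is (a) genotyped in at least `presenceMin` of them,
#' (b) homozygous in every non-missing reference call, (c) fixed within each
#' reference group (all non-missing calls identical), and (d) polymorphic
#' between groups. With three or more groups the diagnostic species is the
#' unique odd group out (the one group fixed for the minority allele); with
#' exactly two groups both differ, and the marker is assigned to the group
#' fixed for the ALT allele (documented tie rule keeping panels disjoint).
#'
#' @param x a [GenotypeCalls-class] object.
#' @param referenceGroups named list mapping species label to reference
#'   accession ids; at least 2 groups of at least 2 accessions each.
#' @param presenceMin minimum pooled reference call rate (default 0.88).
#' @return data.frame (the species panels): `species`, `marker`, `contig`,
#'   `position`, `speciesAllele` (`"ref"`/`"alt"`), `callRate` (over all
#'   accessions in `x`). Panels are disjoint by construction.
#' @export
selectSpeciesMarkers <- function(x, referenceGroups, presenceMin = 0.88) {
    if (length(referenceGroups) < 2L)
        stop("need at least 2 reference groups")
    sizes <- vapply(referenceGroups, length, 1L)
    if (any(sizes < 2L))
        stop("each reference group needs >= 2 accessions: ",
             paste(names(referenceGroups)[sizes < 2L], collapse = ", "))
    d <- dosage(x)
    refIds <- unlist(referenceGroups, use.names = FALSE)
    miss <- setdiff(refIds, colnames(d))
    if (length(miss)) stop("reference accessions not in matrix: ",
                           paste(miss, collapse = ", "))
    R <- d[, refIds, drop = FALSE]
    presence <- rowMeans(!is.na(R))
    allHom <- apply(R, 1L, function(g) all(is.na(g) | g != 1L))
    # per-group fixed state: 0, 2, NA (not fixed / no calls)
    state <- vapply(referenceGroups, function(acc) {
        G <- d[, acc, drop = FALSE]
        apply(G, 1L, function(g) {
            g <- g[!is.na(g)]
            if (!length(g)) return(NA_real_)
            if (all(g == g[1L])) g[1L] else NA_real_
        })
    }, numeric(nrow(d)))
    if (is.null(dim(state)))
        state <- matrix(state, nrow = 1L, dimnames = list(rownames(d), names(referenceGroups)))
    fixedAll <- rowSums(is.na(state)) == 0L
    poly <- fixedAll & apply(state, 1L, function(s) length(unique(s)) > 1L)
    ok <- presence >= presenceMin & allHom & poly
    mt <- markerTable(x)
    st <- markerStats(x)
    out <- vector("list", 0L)
    for (idx in which(ok)) {
        s <- state[idx, ]
        if (length(s) == 2L) {
            species <- names(s)[s == 2][1L]  # group fixed for ALT
            allele <- "alt"
        } else {
            tabAlt <- sum(s == 2)
            if (tabAlt == 1L) { species <- names(s)[s == 2]; allele <- "alt" }
            else if (sum(s == 0) == 1L) { species <- names(s)[s == 0]; allele <- "ref" }
            else next  # no single odd group out (>3 groups, 2-2 split etc.)
        }
        out[[length(out) + 1L]] <- data.frame(
            species = species, marker = mt$id[idx], contig = mt$contig[idx],
            position = mt$position[idx], speciesAllele = allele,
            callRate = 1 - st$missingRate[idx], stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(species = character(0), marker = character(0),
                          contig = character(0), position = integer(0),
                          speciesAllele = character(0), callRate = numeric(0),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Equalize species panel sizes
#'
#' Reduces every panel to the size of the smallest one so each species
#' contributes the same number of diagnostic loci to the composition
#' denominator. Larger panels are reduced by (1) capping markers per
#' `windowBp` genomic bin at `perWindowCap`, keeping the highest call rates,
#' then (2) dropping the lowest-call-rate markers (tie: later position) until
#' the target size is reached.
#'
#' @param panels data.frame from [selectSpeciesMarkers()].
#' @param windowBp bin width for the per-window cap (default 500 bp).
#' @param perWindowCap maximum markers per bin during step 1 (default 3).
#' @return data.frame of the same shape; all species have equal marker
#'   counts.
#' @export
equalizePanels <- function(panels, windowBp = 500, perWindowCap = 3) {
    counts <- table(panels$species)
    if (!length(counts)) return(panels)
    target <- min(counts)
    keepRows <- vector("list", 0L)
    for (sp in names(counts)) {
        p <- panels[panels$species == sp, , drop = FALSE]
        if (nrow(p) > target) {
            bin <- paste(p$contig, .binIndex(p$position, windowBp), sep = "\r")
            ord <- order(bin, -p$callRate, p$position)
            rank <- stats::ave(seq_along(ord), bin[ord], FUN = seq_along)
            capped <- logical(nrow(p))
            capped[ord] <- rank <= perWindowCap
            if (sum(capped) < target) capped <- rep(TRUE, nrow(p))
            p <- p[capped, , drop = FALSE]
            if (nrow(p) > target) {
                drop <- order(p$callRate, -p$position)[seq_len(nrow(p) - target)]
                p <- p[-drop, , drop = FALSE]
            }
        }
        keepRows[[sp]] <- p
    }
    res <- do.call(rbind, keepRows)
    rownames(res) <- NULL
    res
}

# Per-locus L scores for one accession against one panel: 1 hom species
# allele, 0.5 het, 0 hom other allele or missing.
.lScores <- function(calls, speciesAllele) {
    L <- ifelse(speciesAllele == "alt", calls / 2, (2 - calls) / 2)
    L[is.na(L)] <- 0
    L
}

#' Interspecific composition from diagnostic panels
#'
#' For each accession and species panel, per-locus scores are `L = 1` when
#' homozygous for the species-specific allele, `0.5` when heterozygous, and
#' `0` when homozygous for the other allele or missing (missing deflates the
#' numerator by design; the emitted call rate exposes the bias). The
#' percentage attributed to each species is
#' `Perc(s) = sum(L_s) / sum over species of sum(L) * 100`.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param panels data.frame from [selectSpeciesMarkers()] /
#'   [equalizePanels()]; a warning is issued when panel sizes are unequal.
#' @param accessions accession ids to score (default: all in `x`).
#' @return data.frame with one row per accession: `id`, `perc.<species>`,
#'   `sumL.<species>`, `nInformative` (loci with `L > 0` over all panels),
#'   `panelCallRate`, `undefined` (`TRUE` when every `sum(L)` is 0).
#' @export
composition <- function(x, panels, accessions = colnames(x)) {
    d <- dosage(x)
    miss <- setdiff(accessions, colnames(d))
    if (length(miss)) stop("accession(s) not in matrix: ",
                           paste(miss, collapse = ", "))
    counts <- table(panels$species)
    if (length(unique(counts)) > 1L)
        warning("panel sizes are unequal (", paste(counts, collapse = "/"),
                "); consider equalizePanels()")
    species <- sort(names(counts))
    rowIdx <- lapply(species, function(sp) {
        p <- panels[panels$species == sp, ]
        list(idx = match(p$marker, rownames(d)), allele = p$speciesAllele)
    })
    names(rowIdx) <- species
    res <- lapply(accessions, function(acc) {
        g <- d[, acc]
        sumL <- vapply(species, function(sp) {
            ri <- rowIdx[[sp]]
            sum(.lScores(g[ri$idx], ri$allele))
        }, numeric(1))
        nInf <- sum(vapply(species, function(sp) {
            ri <- rowIdx[[sp]]
            sum(.lScores(g[ri$idx], ri$allele) > 0)
        }, numeric(1)))
        tot <- sum(sumL)
        perc <- if (tot > 0) 100 * sumL / tot else rep(0, length(species))
        callRate <- mean(!is.na(g[unlist(lapply(rowIdx, `[[`, "idx"))]))
        c(perc, sumL, nInf, callRate, as.numeric(tot == 0))
    })
    res <- do.call(rbind, res)
    out <- data.frame(id = accessions, res, stringsAsFactors = FALSE)
    colnames(out) <- c("id", paste0("perc.", species), paste0("sumL.", species),
                       "nInformative", "panelCallRate", "undefined")
    out$undefined <- out$undefined > 0
    rownames(out) <- NULL
    out
}

#' Call introgression segments along contigs
#'
#' Per donor-species panel and contig, panel loci are ordered by position and
#' maximal runs of consecutive loci carrying the donor allele (`L >= 0.5`)
#' are reported as segments when the run covers at least `minRun` loci.
#' Shorter runs are reported separately as singletons (putative genotyping
#' errors: isolated donor alleles appearing singly and not in a series).
#' Segment span is the inner span between the first and last supporting
#' locus — a lower bound on the true tract length.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param panels diagnostic panel data.frame.
#' @param accessions accession ids to scan (default: all).
#' @param minRun minimum supporting loci per segment (default 3).
#' @return list with `segments` (data.frame: `id`, `donor`, `contig`,
#'   `start`, `end`, `nLoci`, `zygosity` in all-het/all-hom/mixed) and
#'   `singletons` (same shape, runs shorter than `minRun`).
#' @export
introgressionSegments <- function(x, panels, accessions = colnames(x),
                                  minRun = 3) {
    d <- dosage(x)
    segs <- vector("list", 0L)
    sing <- vector("list", 0L)
    for (sp in unique(panels$species)) {
        p <- panels[panels$species == sp, , drop = FALSE]
        p <- p[order(p$contig, p$position), , drop = FALSE]
        ridx <- match(p$marker, rownames(d))
        for (acc in accessions) {
            L <- .lScores(d[ridx, acc], p$speciesAllele)
            for (ctg in unique(p$contig)) {
                sel <- p$contig == ctg
                Lc <- L[sel]; pos <- p$position[sel]
                r <- rle(Lc >= 0.5)
                ends <- cumsum(r$lengths)
                starts <- ends - r$lengths + 1L
                for (k in which(r$values)) {
                    ii <- starts[k]:ends[k]
                    zyg <- if (all(Lc[ii] == 1)) "all-hom"
                           else if (all(Lc[ii] == 0.5)) "all-het" else "mixed"
                    row <- data.frame(id = acc, donor = sp, contig = ctg,
                                      start = pos[ii[1L]], end = pos[ii[length(ii)]],
                                      nLoci = length(ii), zygosity = zyg,
                                      stringsAsFactors = FALSE)
                    if (length(ii) >= minRun) segs[[length(segs) + 1L]] <- row
                    else sing[[length(sing) + 1L]] <- row
                }
            }
        }
    }
    empty <- data.frame(id = character(0), donor = character(0),
                        contig = character(0), start = integer(0),
                        end = integer(0), nLoci = integer(0),
                        zygosity = character(0), stringsAsFactors = FALSE)
    list(segments = if (length(segs)) do.call(rbind, segs) else empty,
         singletons = if (length(sing)) do.call(rbind, sing) else empty)
}

#' Coverage gaps of a diagnostic panel along the genome
#'
#' Distances between consecutive panel loci per contig, binned to expose
#' genomic regions where the panel is blind to introgression (a donor tract
#' falling wholly inside a gap cannot be detected).
#'
#' @param panel data.frame for one species (columns `contig`, `position`).
#' @param bins list of `c(lo, hi)` bounds in Mb; a gap `g` falls in a bin
#'   when `lo <= g < hi` (Mb).
#' @return list with `counts` (named per-bin gap counts), `maxGapMb`, and
#'   `gaps` (data.frame of all inter-locus distances). Contigs with fewer
#'   than 2 loci are skipped with a message.
#' @export
panelCoverageGaps <- function(panel, bins = list(c(3, 5), c(5, Inf))) {
    gaps <- vector("list", 0L)
    for (ctg in unique(panel$contig)) {
        pos <- sort(panel$position[panel$contig == ctg])
        if (length(pos) < 2L) {
            message("contig ", ctg, " has < 2 panel loci; skipped")
            next
        }
        gaps[[ctg]] <- data.frame(contig = ctg, gapMb = diff(pos) / 1e6,
                                  stringsAsFactors = FALSE)
    }
    gaps <- if (length(gaps)) do.call(rbind, gaps)
            else data.frame(contig = character(0), gapMb = numeric(0))
    rownames(gaps) <- NULL
    counts <- vapply(bins, function(b)
        sum(gaps$gapMb >= b[1L] & gaps$gapMb < b[2L]), numeric(1))
    names(counts) <- vapply(bins, function(b)
        paste0(b[1L], "-", ifelse(is.finite(b[2L]), b[2L], "+"), "Mb"),
        character(1))
    list(counts = counts,
         maxGapMb = if (nrow(gaps)) max(gaps$gapMb) else NA_real_,
         gaps = gaps)
}
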