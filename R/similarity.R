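#' Modified Gower similarity between two genotype vectors
#'
#' For biallelic dosage genotypes the per-locus score is `s = 1` when the two
#' calls are identical, `0.5` when they share exactly one allele (homozygote
#' vs heterozygote), and `0` for opposite homozygotes; loci missing in either
#' accession carry weight 0. The similarity is `sum(s * w) / sum(w)`, i.e.
#' `1 - mean(|x - y|) / 2` over shared genotyped loci.
#'
#' @param x,y integer dosage vectors of equal length (`{0,1,2,NA}`).
#' @param minOverlap minimum number of loci genotyped in both; below this the
#'   result is `NA` (undefined), never silently 0.
#' @return GS in `[0, 1]`, or `NA` when overlap is insufficient.
#' @examples
#' gowerSimilarity(c(0, 1, 2, 0), c(0, 0, 2, NA), minOverlap = 1)  # 2.5/3
#' @export
gowerSimilarity <- function(x, y, minOverlap = 100) {
    stopifnot(length(x) == length(y))
    w <- !is.na(x) & !is.na(y)
    if (sum(w) < minOverlap) return(NA_real_)
    1 - sum(abs(x[w] - y[w])) / (2 * sum(w))
}

#' All-pairs modified Gower similarity
#'
#' Computes GS for every accession pair via genotype-class cross-products
#' (exactly equivalent to looping [gowerSimilarity()] over pairs). Pairs with
#' fewer than `minOverlap` shared genotyped loci are flagged `NA`.
#'
#' @param x a [GenotypeCalls-class] object with at least two accessions.
#' @param minOverlap minimum shared genotyped loci per pair.
#' @return a [PairwiseSimilarity-class] object. The diagonal is 1 wherever an
#'   accession has at least one non-missing call.
#' @export
similarityMatrix <- function(x, minOverlap = 100) {
    d <- dosage(x)
    if (ncol(d) < 2L) stop("need at least 2 accessions")
    cp <- .pairCounts(d)
    gs <- 1 - cp$diff / (2 * cp$w)
    gs[cp$w < minOverlap] <- NA_real_
    diag(gs) <- ifelse(diag(cp$w) > 0, 1, NA_real_)
    methods::new("PairwiseSimilarity", similarity = gs,
                 overlap = cp$w, minOverlap = as.numeric(minOverlap))
}

# Cross-product machinery shared by GS and P_OHL: per pair, the count of
# shared genotyped loci (w), total allele mismatch sum(|x-y|) (diff), and
# opposite-homozygote locus count (opp).
.pairCounts <- function(d) {
    h0 <- (!is.na(d) & d == 0L) * 1
    h1 <- (!is.na(d) & d == 1L) * 1
    h2 <- (!is.na(d) & d == 2L) * 1
    nm <- h0 + h1 + h2
    w <- crossprod(nm)
    c02 <- crossprod(h0, h2)
    opp <- c02 + t(c02)
    c01 <- crossprod(h0, h1)
    c12 <- crossprod(h1, h2)
    one <- c01 + t(c01) + c12 + t(c12)
    list(w = w, diff = 2 * opp + one, opp = opp)
}

#' Group clonally identical accessions
#'
#' Accessions joined by any pairwise GS above `threshold` are grouped by
#' single-linkage (connected components), matching how near-identical
#' cultivar triplets are reported as one clonal group even when one of the
#' three pairwise values dips below the threshold. Such non-transitive
#' within-group pairs are reported. Groups have at least two members.
#'
#' @param sim a [PairwiseSimilarity-class] object.
#' @param threshold GS above which a pair is considered clonal
#'   (default `0.995`, strict `>`).
#' @param missingRate optional named numeric vector of per-accession missing
#'   rates used to pick each group's representative (lowest missing rate,
#'   tie: lexicographic id); lexicographic only when `NULL`.
#' @return list with elements `groups` (list of member id vectors),
#'   `representatives` (one id per group, for de-duplicated downstream
#'   analyses), `threshold`, and `nonTransitive` (data.frame of within-group
#'   pairs at GS <= threshold).
#' @export
cloneGroups <- function(sim, threshold = 0.995, missingRate = NULL) {
    s <- similarityValues(sim)
    ids <- rownames(s)
    adj <- !is.na(s) & s > threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    groups <- split(ids, comp$membership)
    groups <- unname(groups[vapply(groups, length, 1L) >= 2L])
    groups <- lapply(groups, sort)
    nonTrans <- data.frame(id1 = character(0), id2 = character(0),
                           gs = numeric(0), stringsAsFactors = FALSE)
    for (grp in groups) {
        prs <- combn(grp, 2)
        gsv <- s[cbind(prs[1, ], prs[2, ])]
        low <- which(is.na(gsv) | gsv <= threshold)
        if (length(low))
            nonTrans <- rbind(nonTrans, data.frame(
                id1 = prs[1, low], id2 = prs[2, low], gs = gsv[low],
                stringsAsFactors = FALSE))
    }
    if (nrow(nonTrans))
        message("cloneGroups: ", nrow(nonTrans),
                " within-group pair(s) at GS <= ", threshold,
                " joined by single linkage")
    reps <- vapply(groups, function(grp) {
        if (!is.null(missingRate)) {
            mr <- missingRate[grp]
            grp <- grp[order(mr, grp)]
        }
        grp[1L]
    }, character(1))
    list(groups = groups, representatives = reps, threshold = threshold,
         nonTransitive = nonTrans)
}

#' Expected similarity between an accession and a selfed offspring
#'
#' Under selfing, each heterozygous locus has a 50% chance of becoming
#' homozygous in the next generation; a heterozygous parent locus therefore
#' contributes an expected per-locus score of
#' `0.25 * 0.5 + 0.5 * 1 + 0.25 * 0.5 = 0.75`, while homozygous loci always
#' score 1. The expectation is `1 - h / 4` where `h` is the heterozygous
#' fraction among the parent's non-missing loci. Used to judge whether a
#' near-identical "seedling" is plausibly a self (expected GS well below the
#' clonal range) or a clone/sport/apomict (GS ~ 1).
#'
#' @param x integer dosage vector with at least one non-missing call, or a
#'   single-accession [GenotypeCalls-class].
#' @return expected GS in `[0.75, 1]`, `NA` if all calls are missing.
#' @export
expectedSelfGS <- function(x) {
    if (methods::is(x, "GenotypeCalls")) {
        stopifnot(ncol(x) == 1L)
        x <- dosage(x)[, 1L]
    }
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    h <- mean(x[ok] == 1L)
    1 - h / 4
}
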