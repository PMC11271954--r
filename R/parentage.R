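#' Expected progeny genotype of a candidate parent pair
#'
#' Constructed only at loci where both parents are homozygous and genotyped:
#' two shared homozygotes force the offspring genotype (`0+0 -> 0`,
#' `2+2 -> 2`, `0+2 -> 1`). Loci where either parent is heterozygous or
#' missing are excluded (`NA` in the returned vector).
#'
#' @param p1,p2 integer dosage vectors of equal length.
#' @return a dosage vector of the same length, `NA` at non-EP loci, with the
#'   EP locus count attached as attribute `"nEpLoci"`. A warning is issued
#'   when no EP locus exists (all-`NA` result).
#' @export
expectedProgeny <- function(p1, p2) {
    stopifnot(length(p1) == length(p2))
    hom <- !is.na(p1) & !is.na(p2) & p1 != 1L & p2 != 1L
    ep <- rep(NA_real_, length(p1))
    ep[hom] <- (p1[hom] + p2[hom]) / 2
    if (!any(hom)) warning("no loci homozygous in both parents; EP undefined")
    attr(ep, "nEpLoci") <- sum(hom)
    ep
}

#' Proportion of opposite-homozygote loci
#'
#' For a true parent-offspring pair every locus shares at least one
#' transmitted allele, so P_OHL is 0 apart from genotyping error; unrelated
#' pairs accumulate opposite homozygotes in proportion to allele-frequency
#' divergence. A locus counts only when genotyped in both accessions; a
#' homozygote vs heterozygote shares an allele and does not count.
#'
#' @param x,y integer dosage vectors of equal length.
#' @param minOverlap minimum shared genotyped loci; below it the result is
#'   `NA`.
#' @return P_OHL in `[0, 1]` with attribute `"nLoci"`, or `NA`.
#' @export
pohl <- function(x, y, minOverlap = 100) {
    stopifnot(length(x) == length(y))
    w <- !is.na(x) & !is.na(y)
    n <- sum(w)
    if (n < minOverlap) return(NA_real_)
    out <- sum(abs(x[w] - y[w]) == 2L) / n
    attr(out, "nLoci") <- n
    out
}

# Null distribution of the Dixon r22 ratio for a pooled sample of 30 under a
# standard-normal null; `tail` is the tail the candidate sits on.
.dixonNull <- function(tail, nsim = 1e5, n = 30L) {
    X <- matrix(rnorm(nsim * n), nsim, n)
    S <- t(apply(X, 1L, sort.int, method = "quick"))
    if (tail == "min") (S[, 3L] - S[, 1L]) / (S[, n - 2L] - S[, 1L])
    else (S[, n] - S[, n - 2L]) / (S[, n] - S[, 3L])
}

#' Dixon outlier ratio test against 29 comparison values
#'
#' Tests whether `candidate` is an extreme outlier in the pooled sample of 30
#' using Dixon's r22 ratio (for a low outlier on the ascending pooled sample
#' `x[1..30]`: `(x3 - x1) / (x28 - x1)`; mirrored for a high outlier). The
#' p-value is estimated by Monte Carlo under a standard-normal null as the
#' fraction of null ratios at least as extreme as the observed one.
#'
#' @param candidate the value under test.
#' @param comparison exactly 29 comparison values.
#' @param tail `"min"` if the candidate is claimed to be a low outlier,
#'   `"max"` for a high outlier.
#' @param nsim Monte-Carlo replicates for the null (default 1e5).
#' @param seed optional integer seed for the null simulation.
#' @param null optional precomputed null ratio vector (from repeated calls
#'   within one scan); overrides `nsim`/`seed`.
#' @return list with `statistic`, `p.value` and `tail`. If the candidate is
#'   not on the claimed tail the p-value is 1 with a warning; a fully tied
#'   sample or degenerate ratio also gives p = 1.
#' @export
dixonTest <- function(candidate, comparison, tail = c("min", "max"),
                      nsim = 1e5, seed = NULL, null = NULL) {
    tail <- match.arg(tail)
    if (length(comparison) != 29L)
        stop("exactly 29 comparison values are required")
    pooled <- sort(c(candidate, comparison))
    n <- 30L
    onTail <- if (tail == "min") candidate <= min(comparison)
              else candidate >= max(comparison)
    if (!onTail) {
        warning("candidate is not on the claimed tail; p = 1")
        return(list(statistic = NA_real_, p.value = 1, tail = tail))
    }
    if (max(pooled) == min(pooled))
        return(list(statistic = NA_real_, p.value = 1, tail = tail))
    stat <- if (tail == "min") {
        den <- pooled[n - 2L] - pooled[1L]
        if (den == 0) NA_real_ else (pooled[3L] - pooled[1L]) / den
    } else {
        den <- pooled[n] - pooled[3L]
        if (den == 0) NA_real_ else (pooled[n] - pooled[n - 2L]) / den
    }
    if (is.na(stat)) return(list(statistic = NA_real_, p.value = 1, tail = tail))
    if (is.null(null)) {
        null <- if (is.null(seed)) .dixonNull(tail, nsim)
                else withr::with_seed(seed, .dixonNull(tail, nsim))
    }
    list(statistic = stat, p.value = mean(null >= stat), tail = tail)
}

# Shared gap-detection + paired-Dixon machinery for dyad and triad scans.
# `values` is the pooled statistic (P_OHL or GD). Returns per-candidate
# p-values for the entries below the significant gap, plus diagnostics.
# All randomness (29-gap sample, both Dixon nulls) is drawn inside; seed the
# caller with withr::with_seed.
.gapScan <- function(values, alpha = 0.05, nsim = 1e5) {
    n <- length(values)
    if (n < 31L) stop("gap scan requires at least 31 values (30 gaps)")
    ord <- order(values)
    v <- values[ord]
    gaps <- diff(v)
    half <- floor(length(gaps) / 2)
    gapIdx <- which.max(gaps[seq_len(half)])
    rest <- gaps[-gapIdx]
    sampled <- sample(rest, 29L)
    nullHigh <- .dixonNull("max", nsim)
    gapTest <- dixonTest(gaps[gapIdx], sampled, tail = "max", null = nullHigh)
    p <- rep(NA_real_, n)
    sig <- rep(FALSE, n)
    if (gapTest$p.value < alpha) {
        below <- seq_len(gapIdx)
        above <- v[(gapIdx + 1L):n]
        if (length(above) < 29L) {
            warning("fewer than 29 values above the gap; ",
                    "individual Dixon tests not possible")
        } else {
            comp <- above[seq_len(29L)]
            nullLow <- .dixonNull("min", nsim)
            for (k in below) {
                dt <- dixonTest(v[k], comp, tail = "min", null = nullLow)
                p[ord[k]] <- dt$p.value
                sig[ord[k]] <- dt$p.value < alpha
            }
        }
    }
    list(p = p, significant = sig, order = ord, sorted = v, gaps = gaps,
         gapIndex = gapIdx, gapSize = gaps[gapIdx], gapP = gapTest$p.value)
}

.roleOf <- function(meta, ids) {
    if (is.null(meta)) return(setNames(rep("all", length(ids)), ids))
    r <- setNames(meta$role[match(ids, meta$id)], ids)
    r[is.na(r)] <- "all"
    r
}

.cloneKey <- function(clones, ids) {
    key <- setNames(seq_along(ids) + length(ids), ids)  # unique by default
    if (!is.null(clones))
        for (g in seq_along(clones$groups)) {
            mem <- intersect(clones$groups[[g]], ids)
            key[mem] <- g
        }
    key
}

#' Scan all eligible accession pairs for parent-offspring dyads
#'
#' Computes P_OHL for every eligible pair (role-respecting: parent-parent and
#' offspring-offspring pairs are excluded; within-clone-group pairs are
#' excluded when `clones` is supplied), orders the values ascending, and
#' locates the largest gap among the first half of the consecutive gaps. A
#' first Dixon test asks whether that gap is a high outlier against 29 gaps
#' sampled without replacement from the remaining gaps; if significant, each
#' dyad below the gap is tested as a low outlier against the 29 lowest dyads
#' above the gap. When more than 25% of pairs fall below P_OHL 0.02 a
#' population-structure warning is raised: strong subgroup delineation can
#' artificially depress P_OHL and blur the true/spurious gap.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param meta optional accession metadata (see [readAccessionMeta()]); all
#'   accessions are treated as role `"all"` when `NULL`. `date` metadata, when
#'   present, orients significant dyads (older accession = parent).
#' @param alpha significance level for both Dixon tests.
#' @param minOverlap minimum shared genotyped loci per pair.
#' @param clones optional [cloneGroups()] result; clonal pairs are not dyad
#'   candidates.
#' @param nsim Monte-Carlo replicates for the Dixon nulls.
#' @param seed integer seed driving the 29-gap sample and both nulls.
#' @return data.frame of candidates sorted by P_OHL: `id1`, `id2`, `pohl`,
#'   `nLoci`, `pValue` (set only below the gap), `significant`, `parent`,
#'   `offspring` (oriented from dates where available). Attributes:
#'   `"gapScan"` (diagnostics incl. `gapP`), `"structureWarning"`,
#'   `"pohlReference"` (the literature rule-of-thumb 0.010, reported
#'   alongside but not used for significance).
#' @export
dyadScan <- function(x, meta = NULL, alpha = 0.05, minOverlap = 100,
                     clones = NULL, nsim = 1e5, seed = 1) {
    d <- dosage(x)
    ids <- colnames(d)
    cp <- .pairCounts(d)
    P <- as.matrix(cp$opp / cp$w)
    P[cp$w < minOverlap] <- NA_real_
    role <- .roleOf(meta, ids)
    ckey <- .cloneKey(clones, ids)
    prs <- which(upper.tri(P), arr.ind = TRUE)
    i <- prs[, 1L]; j <- prs[, 2L]
    elig <- !(role[ids[i]] == "parent" & role[ids[j]] == "parent") &
            !(role[ids[i]] == "offspring" & role[ids[j]] == "offspring") &
            ckey[ids[i]] != ckey[ids[j]]
    dropNA <- elig & is.na(P[prs])
    if (any(dropNA))
        warning(sum(dropNA), " pair(s) below minOverlap excluded")
    elig <- elig & !is.na(P[prs])
    i <- i[elig]; j <- j[elig]
    if (length(i) < 31L)
        stop("dyad scan requires >= 31 eligible pairs, got ", length(i))
    vals <- P[cbind(i, j)]
    nloc <- as.matrix(cp$w)[cbind(i, j)]
    structWarn <- mean(vals < 0.02) > 0.25
    if (structWarn)
        warning("population structure suspected: >25% of pairs have ",
                "P_OHL < 0.02; the true/spurious gap may be depressed")
    scan <- withr::with_seed(seed, .gapScan(vals, alpha = alpha, nsim = nsim))
    res <- data.frame(id1 = ids[i], id2 = ids[j], pohl = vals, nLoci = nloc,
                      pValue = scan$p, significant = scan$significant,
                      parent = NA_character_, offspring = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.null(meta) && !all(is.na(meta$date))) {
        dts <- setNames(meta$date, meta$id)
        d1 <- dts[res$id1]; d2 <- dts[res$id2]
        ok <- res$significant & !is.na(d1) & !is.na(d2) & d1 != d2
        res$parent[ok] <- ifelse(d1[ok] < d2[ok], res$id1[ok], res$id2[ok])
        res$offspring[ok] <- ifelse(d1[ok] < d2[ok], res$id2[ok], res$id1[ok])
    }
    res <- res[scan$order, ]
    rownames(res) <- NULL
    attr(res, "gapScan") <- scan[c("sorted", "gaps", "gapIndex", "gapSize", "gapP")]
    attr(res, "structureWarning") <- structWarn
    attr(res, "pohlReference") <- 0.010
    res
}

#' Scan parent pairs and offspring for triads
#'
#' For each eligible parent pair an expected progeny genotype (EP) is built
#' at loci homozygous in both parents ([expectedProgeny()]); each eligible
#' offspring is compared to the EP by Gower dissimilarity (`GD = 1 - GS`)
#' restricted to EP loci genotyped in the offspring. All (parent pair,
#' offspring) GD values are pooled and the same gap + paired-Dixon machinery
#' as [dyadScan()] assigns significance: a true offspring has GD near the
#' genotyping-error rate, far below the spurious cloud.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param meta optional metadata; parent candidates have role `parent` or
#'   `all`, offspring candidates `offspring` or `all`; an offspring is never
#'   tested against a pair containing itself.
#' @param alpha significance level.
#' @param minEpLoci minimum EP loci genotyped in the offspring for a triad to
#'   enter the scan.
#' @param nsim,seed Monte-Carlo controls as in [dyadScan()].
#' @return data.frame sorted by GD: `parent1`, `parent2`, `offspring`, `gd`,
#'   `nEpLoci`, `pValue`, `significant`; attribute `"gapScan"` as in
#'   [dyadScan()].
#' @export
triadScan <- function(x, meta = NULL, alpha = 0.05, minEpLoci = 100,
                      nsim = 1e5, seed = 1) {
    d <- dosage(x)
    ids <- colnames(d)
    role <- .roleOf(meta, ids)
    parents <- ids[role[ids] %in% c("parent", "all")]
    offs <- ids[role[ids] %in% c("offspring", "all")]
    if (length(parents) < 2L || length(offs) < 1L)
        stop("need >= 2 parent candidates and >= 1 offspring candidate")
    rows <- vector("list", 0L)
    pp <- combn(parents, 2)
    for (k in seq_len(ncol(pp))) {
        pa <- pp[1L, k]; pb <- pp[2L, k]
        g1 <- d[, pa]; g2 <- d[, pb]
        hom <- !is.na(g1) & !is.na(g2) & g1 != 1L & g2 != 1L
        if (!any(hom)) next
        ep <- (g1[hom] + g2[hom]) / 2
        oset <- setdiff(offs, c(pa, pb))
        if (!length(oset)) next
        O <- d[hom, oset, drop = FALSE]
        nep <- colSums(!is.na(O))
        gd <- colSums(abs(O - ep), na.rm = TRUE) / (2 * nep)
        keep <- nep >= minEpLoci
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
            parent1 = pa, parent2 = pb, offspring = oset[keep],
            gd = gd[keep], nEpLoci = nep[keep], stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    if (is.null(res) || nrow(res) < 31L)
        stop("triad scan requires >= 31 eligible triads, got ",
             if (is.null(res)) 0L else nrow(res))
    scan <- withr::with_seed(seed,
        .gapScan(res$gd, alpha = alpha, nsim = nsim))
    res$pValue <- scan$p
    res$significant <- scan$significant
    res <- res[scan$order, ]
    rownames(res) <- NULL
    attr(res, "gapScan") <- scan[c("sorted", "gaps", "gapIndex", "gapSize", "gapP")]
    res
}

#' Diagnostic plot of a dyad/triad gap scan
#'
#' Ordered statistic values with the tested gap marked, mirroring the
#' standard parentage-scan diagnostic (candidates below the gap highlighted).
#'
#' @param scan result of [dyadScan()] or [triadScan()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the gap-scan diagnostics list.
#' @export
plotGapScan <- function(scan, ...) {
    gs <- attr(scan, "gapScan")
    if (is.null(gs)) stop("no gap-scan diagnostics attached")
    v <- gs$sorted
    col <- rep("black", length(v))
    col[seq_len(gs$gapIndex)] <- "red"
    graphics::plot(seq_along(v), v, col = col, pch = 19, cex = 0.6,
                   xlab = "ordered candidates", ylab = "statistic", ...)
    graphics::abline(h = mean(v[gs$gapIndex + 0:1]), lty = 2, col = "red")
    invisible(gs)
}
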