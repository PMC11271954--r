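#' Select subspecies-diagnostic markers (fixed differences)
#'
#' Markers where every non-missing ssp. *chinensis* reference call is
#' homozygous for one allele and every non-missing ssp. *kousa* reference
#' call is homozygous for the other. Qualifying markers are ranked by call
#' rate and the top `nPanel` returned — the in-silico analog of choosing a
#' small KASP assay panel from the full fixed-difference set.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param chinensisRefs,kousaRefs reference accession ids (>= 2 each).
#' @param nPanel panel size (default 7); when fewer markers qualify, all are
#'   returned with a warning.
#' @return data.frame: `marker`, `chinensisAllele`, `kousaAllele`
#'   (`"ref"`/`"alt"`), `callRate`, sorted by decreasing call rate.
#' @export
selectDiagnosticMarkers <- function(x, chinensisRefs, kousaRefs, nPanel = 7) {
    if (length(chinensisRefs) < 2L || length(kousaRefs) < 2L)
        stop("each reference set needs >= 2 accessions")
    d <- dosage(x)
    fixedState <- function(acc) {
        G <- d[, acc, drop = FALSE]
        apply(G, 1L, function(g) {
            g <- g[!is.na(g)]
            if (!length(g) || any(g == 1L)) return(NA_real_)
            if (all(g == g[1L])) g[1L] else NA_real_
        })
    }
    sc <- fixedState(chinensisRefs)
    sk <- fixedState(kousaRefs)
    ok <- !is.na(sc) & !is.na(sk) & sc != sk
    st <- markerStats(x)
    res <- data.frame(marker = rownames(d)[ok],
                      chinensisAllele = ifelse(sc[ok] == 0, "ref", "alt"),
                      kousaAllele = ifelse(sk[ok] == 0, "ref", "alt"),
                      callRate = 1 - st$missingRate[ok],
                      stringsAsFactors = FALSE)
    res <- res[order(-res$callRate, res$marker), ]
    rownames(res) <- NULL
    if (nrow(res) < nPanel) {
        warning("only ", nrow(res), " fixed-difference markers available (",
                nPanel, " requested)")
        return(res)
    }
    res[seq_len(nPanel), ]
}

#' Classify a mean ssp. kousa allele fraction
#'
#' `< 0.10` is ssp. *chinensis*, `> 0.90` ssp. *kousa*, anything in between
#' (boundaries inclusive) a subspecies hybrid.
#'
#' @param meanKousa numeric in `[0, 1]` (vectorized); `NA` gives
#'   `"undetermined"`.
#' @return character vector of classes.
#' @export
classifySubspecies <- function(meanKousa) {
    out <- ifelse(is.na(meanKousa), "undetermined",
           ifelse(meanKousa < 0.10, "chinensis",
           ifelse(meanKousa > 0.90, "kousa", "hybrid")))
    out
}

# 0/0.5/1 scoring of calls against the kousa-allele orientation; `calls` is
# a vector or a markers x accessions matrix aligned with `kousaAllele`.
.sspScores <- function(calls, kousaAllele) {
    s <- calls / 2
    flip <- kousaAllele != "alt"
    if (is.matrix(calls)) s[flip, ] <- (2 - calls[flip, , drop = FALSE]) / 2
    else s[flip] <- (2 - calls[flip]) / 2
    s
}

#' Score accessions on a subspecies panel
#'
#' Each panel marker scores 0 (homozygous ssp. *chinensis* allele), 1
#' (homozygous ssp. *kousa* allele) or 0.5 (heterozygous); the mean is taken
#' over non-missing panel calls (missing calls are excluded, not scored 0,
#' since assay reads carry no missing-as-zero convention) and classified
#' with [classifySubspecies()].
#'
#' @param x a [GenotypeCalls-class] object.
#' @param panel data.frame from [selectDiagnosticMarkers()].
#' @param accessions accession ids to score (default: all).
#' @return list with `scores` (matrix accessions x markers of 0/0.5/1/NA,
#'   the heat-map export) and `summary` (data.frame: `id`, `nCalled`,
#'   `meanKousa`, `class`; all-missing accessions are `undetermined`).
#' @export
scorePanel <- function(x, panel, accessions = colnames(x)) {
    d <- dosage(x)
    ridx <- match(panel$marker, rownames(d))
    if (anyNA(ridx)) stop("panel marker(s) not in matrix")
    S <- t(.sspScores(d[ridx, accessions, drop = FALSE], panel$kousaAllele))
    dimnames(S) <- list(accessions, panel$marker)
    nCalled <- rowSums(!is.na(S))
    m <- rowMeans(S, na.rm = TRUE)
    m[nCalled == 0L] <- NA_real_
    list(scores = S,
         summary = data.frame(id = accessions, nCalled = nCalled,
                              meanKousa = m, class = classifySubspecies(m),
                              row.names = NULL, stringsAsFactors = FALSE))
}

#' Mean subspecies score over the full diagnostic set
#'
#' Same 0/0.5/1 scoring as [scorePanel()], averaged over the complete
#' fixed-difference marker set. Serves as the full-data membership proxy a
#' small panel is benchmarked against.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param fullSet data.frame in [selectDiagnosticMarkers()] shape (typically
#'   selected with a large `nPanel`).
#' @param accessions accession ids (default: all).
#' @return data.frame `id`, `nCalled`, `meanKousa`, `class`.
#' @export
diagnosticMean <- function(x, fullSet, accessions = colnames(x)) {
    scorePanel(x, fullSet, accessions)$summary
}

#' Concordance between two subspecies classifications
#'
#' @param panelClasses,referenceClasses data.frames with columns `id` and
#'   `class` (e.g. `summary` from [scorePanel()] and [diagnosticMean()]);
#'   compared over their common accessions.
#' @return list with `agreement` (fraction identical), `n`, and
#'   `disagreements` (data.frame of mismatching accessions with both
#'   classes).
#' @export
concordance <- function(panelClasses, referenceClasses) {
    common <- intersect(panelClasses$id, referenceClasses$id)
    if (!length(common)) stop("no accessions in common")
    a <- panelClasses$class[match(common, panelClasses$id)]
    b <- referenceClasses$class[match(common, referenceClasses$id)]
    dis <- data.frame(id = common, panelClass = a, referenceClass = b,
                      stringsAsFactors = FALSE)[a != b, , drop = FALSE]
    rownames(dis) <- NULL
    list(agreement = mean(a == b), n = length(common), disagreements = dis)
}
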