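# Shared fixture builders and naive per-locus oracles. The oracles stay
# deliberately loop-based and independent of the vectorized implementations
# they check.

randomCalls <- function(nMarkers = 50, nAcc = 8, missing = 0.1, seed = 1,
                        contigs = 2) {
    withr::with_seed(seed, {
        d <- matrix(sample(0:2, nMarkers * nAcc, replace = TRUE),
                    nMarkers, nAcc)
        d[runif(length(d)) < missing] <- NA
        rownames(d) <- paste0("m", seq_len(nMarkers))
        colnames(d) <- paste0("acc", seq_len(nAcc))
        ctg <- rep(paste0("c", seq_len(contigs)), length.out = nMarkers)
        pos <- unlist(lapply(split(seq_len(nMarkers), ctg), seq_along)) * 137L
        pos <- pos[order(order(ctg))]  # keep file order stable
        genotypeCalls(d, contig = sort(ctg), position = pos,
                      ref = "A", alt = "G")
    })
}

naiveGower <- function(x, y) {
    num <- den <- 0
    for (i in seq_along(x)) {
        if (is.na(x[i]) || is.na(y[i])) next
        s <- if (x[i] == y[i]) 1 else if (abs(x[i] - y[i]) == 1) 0.5 else 0
        num <- num + s
        den <- den + 1
    }
    if (den == 0) NA_real_ else num / den
}

naivePohl <- function(x, y) {
    num <- den <- 0
    for (i in seq_along(x)) {
        if (is.na(x[i]) || is.na(y[i])) next
        o <- (x[i] == 0 && y[i] == 2) || (x[i] == 2 && y[i] == 0)
        num <- num + o
        den <- den + 1
    }
    if (den == 0) NA_real_ else num / den
}

naiveEP <- function(p1, p2) {
    ep <- rep(NA_real_, length(p1))
    for (i in seq_along(p1)) {
        if (is.na(p1[i]) || is.na(p2[i])) next
        if (p1[i] == 1 || p2[i] == 1) next
        ep[i] <- if (p1[i] == p2[i]) p1[i] else 1
    }
    ep
}

naiveComposition <- function(g, panels) {
    species <- sort(unique(panels$species))
    sumL <- setNames(numeric(length(species)), species)
    for (k in seq_len(nrow(panels))) {
        call <- g[panels$marker[k]]
        L <- if (is.na(call)) 0
             else if (panels$speciesAllele[k] == "alt") call / 2
             else (2 - call) / 2
        sumL[panels$species[k]] <- sumL[panels$species[k]] + L
    }
    if (sum(sumL) == 0) return(setNames(rep(0, length(species)), species))
    100 * sumL / sum(sumL)
}

# small single-pool simulation used across parentage tests
onePoolConfig <- function(...) {
    simConfig(species = "kousa", subspeciesHost = "kousa",
              speciesDiagnosticPerContig = 0,
              subspeciesDiagnosticPerContig = 0, ...)
}
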