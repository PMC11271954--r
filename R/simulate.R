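#' Configuration for the pedigreed genotype simulator
#'
#' Defines the marker landscape and noise regime the synthetic datasets
#' emulate: several species pools carrying fixed species-diagnostic alleles,
#' two subspecies subpools within a host species carrying fixed subspecies
#' differences, a shared polymorphic background, Poisson recombination, and
#' RADseq-like genotyping error and missingness.
#'
#' @param nContigs number of contigs (default 10).
#' @param contigLengthBp contig length in bp (default 1e7).
#' @param markersPerContig polymorphic background markers per contig
#'   (default 300, i.e. ~3000 background markers overall, the scale of the
#'   marker matrices the analyses run on). Diagnostic markers are additional.
#' @param speciesDiagnosticPerContig species-diagnostic markers per contig,
#'   split equally across the species (default 270, 90 per species).
#' @param subspeciesDiagnosticPerContig subspecies-diagnostic markers per
#'   contig (default 30), polymorphic only between the two subspecies
#'   subpools of `subspeciesHost`.
#' @param backgroundShape Beta shape parameters for per-pool background
#'   alt-allele frequencies (default `c(0.8, 0.8)`, independent loci).
#' @param crossoverLambda mean crossovers per contig per meiosis (Poisson,
#'   uniform breakpoint positions, no interference; default 1.5).
#' @param errorRate per-call miscall probability (default 0.003; reproduces
#'   observed true-clone GS ~0.996-0.999 and true-dyad P_OHL ~0.003-0.008
#'   scales).
#' @param missingRate per-call missing probability (default 0.02).
#' @param species species pool labels.
#' @param subspecies the two subspecies labels within `subspeciesHost`.
#' @param subspeciesHost which species carries the subspecies structure.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(nContigs = 10, contigLengthBp = 1e7,
                      markersPerContig = 300,
                      speciesDiagnosticPerContig = 270,
                      subspeciesDiagnosticPerContig = 30,
                      backgroundShape = c(0.8, 0.8),
                      crossoverLambda = 1.5,
                      errorRate = 0.003, missingRate = 0.02,
                      species = c("florida", "kousa", "nuttallii"),
                      subspecies = c("chinensis", "kousa"),
                      subspeciesHost = "kousa") {
    stopifnot(nContigs >= 1, contigLengthBp >= 1,
              markersPerContig >= 0, speciesDiagnosticPerContig >= 0,
              subspeciesDiagnosticPerContig >= 0,
              errorRate >= 0, errorRate <= 1,
              missingRate >= 0, missingRate <= 1,
              crossoverLambda >= 0, length(species) >= 1,
              subspeciesHost %in% species,
              length(subspecies) == 2L)
    if (speciesDiagnosticPerContig %% length(species) != 0)
        stop("speciesDiagnosticPerContig must be divisible by the number of species")
    tot <- markersPerContig + speciesDiagnosticPerContig +
        subspeciesDiagnosticPerContig
    if (tot > contigLengthBp)
        stop("more markers than positions per contig")
    structure(list(nContigs = nContigs, contigLengthBp = contigLengthBp,
                   markersPerContig = markersPerContig,
                   speciesDiagnosticPerContig = speciesDiagnosticPerContig,
                   subspeciesDiagnosticPerContig = subspeciesDiagnosticPerContig,
                   backgroundShape = backgroundShape,
                   crossoverLambda = crossoverLambda,
                   errorRate = errorRate, missingRate = missingRate,
                   species = species, subspecies = subspecies,
                   subspeciesHost = subspeciesHost),
              class = "SimConfig")
}

# One simulated individual: phased haplotypes (loci x 2 alt-allele counts)
# and per-haplotype founder-species ancestry codes (indices into
# config$species).
.newIndividual <- function(h, anc) list(h = h, anc = anc)

# Draw a founder of `species` (optionally a subspecies of the host species)
# from the pool allele-frequency law. Uses the current RNG stream.
.drawFounder <- function(sim, species, subspecies = NA) {
    cfg <- sim$config
    truth <- sim$markerTruth
    nl <- nrow(truth)
    spIdx <- match(species, cfg$species)
    if (is.na(spIdx)) stop("unknown species: ", species)
    if (species == cfg$subspeciesHost && is.na(subspecies))
        subspecies <- sample(cfg$subspecies, 1L)
    h <- matrix(0L, nl, 2L)
    bg <- truth$category == "background"
    q <- sim$freq[bg, spIdx]
    h[bg, 1L] <- rbinom(sum(bg), 1L, q)
    h[bg, 2L] <- rbinom(sum(bg), 1L, q)
    spd <- truth$category == "species"
    own <- spd & truth$species == species
    altDiag <- truth$diagAllele == "alt"
    h[spd & own & altDiag, ] <- 1L
    h[spd & !own & !altDiag, ] <- 1L
    ssd <- truth$category == "subspecies"
    if (any(ssd)) {
        # chinensis-type allele where the founder is ssp. chinensis;
        # non-host species are fixed for the kousa-type allele
        chin <- identical(subspecies, cfg$subspecies[1L])
        chinAlt <- truth$diagAllele == "alt"
        take <- if (chin) ssd & chinAlt else ssd & !chinAlt
        h[take, ] <- 1L
    }
    anc <- matrix(spIdx, nl, 2L)
    .newIndividual(h, anc)
}

#' Simulate founder pools with diagnostic marker structure
#'
#' Builds the marker map (positions uniform per contig), plants
#' species-diagnostic loci (fixed homozygous for a randomly oriented
#' species-specific allele in the owning pool, fixed for the other allele
#' elsewhere) and subspecies-diagnostic loci (fixed differences between the
#' two subspecies subpools of the host species), draws per-pool background
#' allele frequencies from the configured Beta law, and samples founders in
#' Hardy-Weinberg proportions within pools.
#'
#' @param config a [simConfig()] object.
#' @param nPerSpecies founders per species pool: a single count or a named
#'   vector over `config$species`. Host-species founders are split evenly
#'   between the two subspecies (first half ssp. chinensis).
#' @param seed integer seed; the full result is reproducible.
#' @return a `FounderSim` list: `config`, `map` (marker data.frame),
#'   `markerTruth` (per-marker `category`, owning `species`, `diagAllele`,
#'   `subspecies` orientation), `freq` (background alt-allele frequency per
#'   pool), `pools` (founder id / species / subspecies), and `individuals`
#'   (phased haplotypes with ancestry labels).
#' @seealso [founderGenotypes()], [applyPedigree()], [applyErrorModel()]
#' @export
simulateFounders <- function(config, nPerSpecies = 12, seed = 1) {
    stopifnot(inherits(config, "SimConfig"))
    if (length(nPerSpecies) == 1L)
        nPerSpecies <- setNames(rep(nPerSpecies, length(config$species)),
                                config$species)
    nPerSpecies <- nPerSpecies[config$species]
    withr::with_seed(seed, {
        perCtg <- config$markersPerContig + config$speciesDiagnosticPerContig +
            config$subspeciesDiagnosticPerContig
        maps <- lapply(seq_len(config$nContigs), function(c) {
            pos <- sort(sample.int(config$contigLengthBp, perCtg))
            data.frame(contig = sprintf("ctg%02d", c), position = pos,
                       stringsAsFactors = FALSE)
        })
        map <- do.call(rbind, maps)
        map$id <- sprintf("%s_%d", map$contig, map$position)
        map$ref <- "A"; map$alt <- "G"
        nl <- nrow(map)
        perSp <- config$speciesDiagnosticPerContig / length(config$species)
        catOne <- c(rep("background", config$markersPerContig),
                    rep("species", config$speciesDiagnosticPerContig),
                    rep("subspecies", config$subspeciesDiagnosticPerContig))
        spOne <- c(rep(NA_character_, config$markersPerContig),
                   rep(config$species, each = perSp),
                   rep(NA_character_, config$subspeciesDiagnosticPerContig))
        truth <- do.call(rbind, lapply(seq_len(config$nContigs), function(c) {
            ord <- sample.int(perCtg)
            data.frame(category = catOne[ord], species = spOne[ord],
                       stringsAsFactors = FALSE)
        }))
        truth <- cbind(id = map$id, truth,
                       diagAllele = sample(c("ref", "alt"), nl, replace = TRUE),
                       stringsAsFactors = FALSE)
        truth$diagAllele[truth$category == "background"] <- NA_character_
        freq <- matrix(rbeta(nl * length(config$species),
                             config$backgroundShape[1L],
                             config$backgroundShape[2L]),
                       nl, length(config$species),
                       dimnames = list(map$id, config$species))
        sim <- list(config = config, map = map, markerTruth = truth,
                    freq = freq)
        pools <- vector("list", 0L)
        individuals <- list()
        for (sp in config$species) {
            n <- nPerSpecies[[sp]]
            if (n == 0L) next
            ssp <- rep(NA_character_, n)
            if (sp == config$subspeciesHost)
                ssp <- rep(config$subspecies,
                           c(ceiling(n / 2), floor(n / 2)))[seq_len(n)]
            for (k in seq_len(n)) {
                id <- sprintf("%s_f%02d", sp, k)
                individuals[[id]] <- .drawFounder(sim, sp, ssp[k])
                pools[[length(pools) + 1L]] <- data.frame(
                    id = id, species = sp, subspecies = ssp[k],
                    stringsAsFactors = FALSE)
            }
        }
        sim$pools <- if (length(pools)) do.call(rbind, pools)
                     else data.frame(id = character(0), species = character(0),
                                     subspecies = character(0))
        sim$individuals <- individuals
        structure(sim, class = "FounderSim")
    })
}

.individualsToCalls <- function(inds, map) {
    d <- vapply(inds, function(x) as.integer(x$h[, 1L] + x$h[, 2L]),
                integer(nrow(map)))
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(map),
                                     dimnames = list(NULL, names(inds)))
    rownames(d) <- map$id
    genotypeCalls(d, contig = map$contig, position = map$position,
                  ref = map$ref, alt = map$alt)
}

#' Founder genotypes as a GenotypeCalls object
#'
#' @param founders a `FounderSim` from [simulateFounders()].
#' @return a [GenotypeCalls-class] of the founders (unphased dosage view),
#'   with `species`/`subspecies` in `colData`.
#' @export
founderGenotypes <- function(founders) {
    x <- .individualsToCalls(founders$individuals, founders$map)
    SummarizedExperiment::colData(x)$species <-
        founders$pools$species[match(colnames(x), founders$pools$id)]
    SummarizedExperiment::colData(x)$subspecies <-
        founders$pools$subspecies[match(colnames(x), founders$pools$id)]
    x
}

#' Species-panel truth table of a simulated dataset
#'
#' The planted diagnostic panels, in the shape [selectSpeciesMarkers()]
#' returns — the ground truth that panel selection is benchmarked against.
#'
#' @param founders a `FounderSim`.
#' @return data.frame `species`, `marker`, `contig`, `position`,
#'   `speciesAllele`, `callRate` (1: truth has no missingness).
#' @export
truthPanels <- function(founders) {
    tr <- founders$markerTruth
    keep <- tr$category == "species"
    map <- founders$map
    out <- data.frame(species = tr$species[keep], marker = tr$id[keep],
                      contig = map$contig[keep], position = map$position[keep],
                      speciesAllele = tr$diagAllele[keep], callRate = 1,
                      stringsAsFactors = FALSE)
    out[order(out$species, out$contig, out$position), ]
}

# Meiosis: one gamete from a phased parent. Crossovers per contig are
# Poisson(lambda) at uniform positions; the gamete alternates parental
# haplotypes at the breakpoints, carrying ancestry labels along.
.makeGamete <- function(ind, contigIndex, positions, contigLengthBp, lambda) {
    nl <- length(positions)
    hap <- integer(nl)
    for (ci in contigIndex) {
        k <- rpois(1L, lambda)
        start <- sample.int(2L, 1L)
        if (k == 0L) {
            hap[ci] <- start
        } else {
            brk <- sort(runif(k, 0, contigLengthBp))
            seg <- findInterval(positions[ci], brk)
            hap[ci] <- ((start - 1L + seg) %% 2L) + 1L
        }
    }
    sel <- cbind(seq_len(nl), hap)
    list(h = ind$h[sel], anc = ind$anc[sel])
}

#' Generate offspring for a pedigree script
#'
#' Walks a pedigree (topological order) and simulates each node from phased
#' founder haplotypes: `cross` unites one gamete from each parent, `self`
#' two gametes from the same parent, `op` a maternal gamete with a gamete
#' from a freshly drawn founder of the assumed pollen species, and
#' `clone`/`apomict` copy the parent genotype (before any error model).
#' Founder nodes reuse an existing founder of the same id, otherwise a new
#' founder of the declared species (`founder:<species>` with optional
#' `:<subspecies>`) is drawn. Per-locus founder-species ancestry is tracked
#' through every meiosis.
#'
#' @param pedigree data.frame as from [readPedigree()].
#' @param founders a `FounderSim` from [simulateFounders()].
#' @param opSpecies pollen species assumed for `op` nodes whose `parent2`
#'   does not name one (default `"kousa"`).
#' @param seed integer seed.
#' @return list with `calls` (error-free [GenotypeCalls-class] of the
#'   pedigree nodes) and `truth`: `pedigree`, `cloneGroups` (connected
#'   clone/apomict components), `ancestry` (realized percent of each
#'   founder species per node; rows sum to 100), and `perLocusAncestry`
#'   (per species, a loci x nodes matrix of donor allele counts 0/1/2).
#' @export
applyPedigree <- function(pedigree, founders, opSpecies = "kousa", seed = 1) {
    stopifnot(inherits(founders, "FounderSim"))
    .validatePedigree(pedigree, known = names(founders$individuals))
    cfg <- founders$config
    map <- founders$map
    contigIndex <- split(seq_len(nrow(map)), map$contig)
    gamete <- function(ind) .makeGamete(ind, contigIndex, map$position,
                                        cfg$contigLengthBp,
                                        cfg$crossoverLambda)
    base <- .pedType(pedigree$type)
    withr::with_seed(seed, {
        inds <- list()
        cloneEdges <- vector("list", 0L)
        for (k in seq_len(nrow(pedigree))) {
            id <- pedigree$id[k]
            p1 <- pedigree$parent1[k]; p2 <- pedigree$parent2[k]
            get <- function(pid) {
                if (!is.null(inds[[pid]])) inds[[pid]]
                else if (!is.null(founders$individuals[[pid]]))
                    founders$individuals[[pid]]
                else stop("parent '", pid, "' not found")
            }
            inds[[id]] <- switch(base[k],
                founder = {
                    if (!is.null(founders$individuals[[id]]))
                        founders$individuals[[id]]
                    else .drawFounder(founders,
                                      .founderSpecies(pedigree$type[k]),
                                      .founderSubspecies(pedigree$type[k]))
                },
                cross = {
                    ga <- gamete(get(p1)); gb <- gamete(get(p2))
                    .newIndividual(cbind(ga$h, gb$h), cbind(ga$anc, gb$anc))
                },
                self = {
                    ga <- gamete(get(p1)); gb <- gamete(get(p1))
                    .newIndividual(cbind(ga$h, gb$h), cbind(ga$anc, gb$anc))
                },
                op = {
                    sp <- if (!is.na(p2) && p2 != "") p2 else opSpecies
                    pollen <- .drawFounder(founders, sp)
                    ga <- gamete(get(p1)); gb <- gamete(pollen)
                    .newIndividual(cbind(ga$h, gb$h), cbind(ga$anc, gb$anc))
                },
                clone = ,
                apomict = {
                    cloneEdges[[length(cloneEdges) + 1L]] <- c(p1, id)
                    get(p1)
                })
        }
        nodes <- pedigree$id
        calls <- .individualsToCalls(inds[nodes], map)
        nl <- nrow(map)
        anc <- vapply(cfg$species, function(sp) {
            si <- match(sp, cfg$species)
            vapply(nodes, function(id)
                100 * mean(inds[[id]]$anc == si), numeric(1))
        }, numeric(length(nodes)))
        if (is.null(dim(anc)))
            anc <- matrix(anc, nrow = 1L,
                          dimnames = list(nodes, cfg$species))
        ancestry <- data.frame(id = nodes, anc, row.names = NULL,
                               check.names = FALSE, stringsAsFactors = FALSE)
        perLocus <- lapply(setNames(cfg$species, cfg$species), function(sp) {
            si <- match(sp, cfg$species)
            m <- vapply(nodes, function(id)
                as.integer(rowSums(inds[[id]]$anc == si)), integer(nl))
            if (is.null(dim(m))) m <- matrix(m, nrow = nl)
            dimnames(m) <- list(map$id, nodes)
            m
        })
        cg <- list()
        if (length(cloneEdges)) {
            g <- igraph::graph_from_edgelist(do.call(rbind, cloneEdges),
                                             directed = FALSE)
            comp <- igraph::components(g)
            cg <- unname(split(names(comp$membership), comp$membership))
            cg <- lapply(cg, sort)
        }
        list(calls = calls,
             truth = list(pedigree = pedigree, cloneGroups = cg,
                          ancestry = ancestry, perLocusAncestry = perLocus))
    })
}

#' Apply RADseq-like genotyping error and missingness
#'
#' Independently per call: with probability `missingRate` the call is set
#' missing; otherwise with probability `errorRate` it is miscalled — a
#' heterozygote becomes one of the two homozygotes with equal probability,
#' a homozygote becomes the heterozygote. The hom-to-het-only direction for
#' homozygotes means a single miscall can never manufacture an
#' opposite-homozygote mismatch in a true parent-offspring pair. The input
#' object is not modified.
#'
#' @param x a [GenotypeCalls-class] object.
#' @param errorRate,missingRate per-call probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return a new [GenotypeCalls-class] with perturbed calls.
#' @export
applyErrorModel <- function(x, errorRate = 0.003, missingRate = 0.02,
                            seed = 1) {
    stopifnot(errorRate >= 0, errorRate <= 1,
              missingRate >= 0, missingRate <= 1)
    d <- dosage(x)
    withr::with_seed(seed, {
        n <- length(d)
        out <- d
        mk <- runif(n) < missingRate
        err <- !mk & !is.na(d) & runif(n) < errorRate
        het <- err & d == 1L
        hom <- err & d != 1L
        out[mk] <- NA_integer_
        out[het] <- 2L * rbinom(sum(het), 1L, 0.5)
        out[hom] <- 1L
        y <- x
        SummarizedExperiment::assay(y, "dosage") <- out
        y
    })
}
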