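# 3-group reference fixture: 2 refs per species, planted diagnostic loci
refFixture <- function() {
    acc <- c("fl1", "fl2", "ko1", "ko2", "nu1", "nu2")
    d <- rbind(
        mKref = c(2L, 2L, 0L, 0L, 2L, 2L),   # kousa fixed REF, others ALT
        mFalt = c(2L, 2L, 0L, 0L, 0L, 0L),   # florida fixed ALT
        mHet  = c(2L, 2L, 0L, 1L, 0L, 0L),   # one het reference call
        mPoly = c(2L, 0L, 0L, 0L, 2L, 2L),   # polymorphic within florida
        mMono = c(0L, 0L, 0L, 0L, 0L, 0L),   # all groups fixed same allele
        mMiss = c(2L, NA, NA, 0L, NA, 2L))   # presence 3/6 < 0.88
    colnames(d) <- acc
    genotypeCalls(d, contig = "c1", position = 1:6 * 1000, ref = "A", alt = "G")
}

test_that("species panel selection applies all four reference filters", {
    x <- refFixture()
    refs <- list(florida = c("fl1", "fl2"), kousa = c("ko1", "ko2"),
                 nuttallii = c("nu1", "nu2"))
    pan <- selectSpeciesMarkers(x, refs)
    expect_setequal(pan$marker, c("mKref", "mFalt"))
    expect_equal(pan$speciesAllele[pan$marker == "mKref"], "ref")
    expect_equal(pan$species[pan$marker == "mKref"], "kousa")
    expect_equal(pan$species[pan$marker == "mFalt"], "florida")
    expect_error(selectSpeciesMarkers(x, list(florida = "fl1", kousa = refs$kousa)),
                 ">= 2 accessions")
})

test_that("panel selection recovers planted diagnostics in a simulated pool", {
    cfg <- simConfig(nContigs = 4, markersPerContig = 50,
                     speciesDiagnosticPerContig = 30,
                     subspeciesDiagnosticPerContig = 0)
    f <- simulateFounders(cfg, nPerSpecies = 6, seed = 67)
    x <- founderGenotypes(f)
    refs <- split(f$pools$id, f$pools$species)
    pan <- selectSpeciesMarkers(x, refs)
    tp <- truthPanels(f)
    # every planted diagnostic is recovered with its planted orientation
    # (error-free, full presence); chance-fixed background may add extras
    m <- merge(tp, pan, by = "marker")
    expect_equal(nrow(m), nrow(tp))
    expect_equal(m$species.x, m$species.y)
    expect_equal(m$speciesAllele.x, m$speciesAllele.y)
})

test_that("panel equalization caps per-window then trims lowest call rates", {
    pan <- data.frame(
        species = c(rep("florida", 5), rep("kousa", 3), rep("nuttallii", 3)),
        marker = paste0("m", 1:11),
        contig = "c1",
        position = c(10L, 20L, 30L, 40L, 450L, 1:3 * 1000L, 1:3 * 2000L),
        speciesAllele = "alt",
        callRate = c(0.99, 0.98, 0.97, 0.96, 0.95, rep(0.9, 6)),
        stringsAsFactors = FALSE)
    eq <- equalizePanels(pan, windowBp = 500, perWindowCap = 3)
    expect_equal(as.integer(table(eq$species)), rep(3L, 3))
    # florida: all 5 in one bin; the two lowest call rates (m4, m5) go first
    expect_setequal(eq$marker[eq$species == "florida"], c("m1", "m2", "m3"))
    # already equal panels pass through unchanged
    expect_equal(equalizePanels(eq), eq)
})

test_that("composition reproduces pure, F1 and oracle values", {
    pan <- data.frame(species = rep(c("florida", "kousa", "nuttallii"), each = 2),
                      marker = paste0("m", 1:6), contig = "c1",
                      position = 1:6 * 1000L, speciesAllele = "alt",
                      callRate = 1, stringsAsFactors = FALSE)
    d <- cbind(pureK = c(0L, 0L, 2L, 2L, 0L, 0L),
               f1 = c(1L, 1L, 1L, 1L, 0L, 0L),
               none = c(0L, 0L, 0L, 0L, 0L, 0L))
    rownames(d) <- paste0("m", 1:6)
    x <- genotypeCalls(d, contig = "c1", position = 1:6 * 1000L,
                       ref = "A", alt = "G")
    cmp <- composition(x, pan)
    expect_equal(cmp$perc.kousa[cmp$id == "pureK"], 100)
    expect_equal(cmp$perc.florida[cmp$id == "f1"], 50)
    expect_equal(cmp$perc.kousa[cmp$id == "f1"], 50)
    expect_equal(cmp$perc.nuttallii[cmp$id == "f1"], 0)
    expect_true(cmp$undefined[cmp$id == "none"])
    # random genotypes against the per-locus oracle; invariant to panel order
    x2 <- randomCalls(60, 4, missing = 0.2, seed = 71)
    pan2 <- data.frame(species = rep(c("florida", "kousa", "nuttallii"), each = 15),
                       marker = paste0("m", 1:45),
                       contig = markerTable(x2)$contig[1:45],
                       position = markerTable(x2)$position[1:45],
                       speciesAllele = sample(c("ref", "alt"), 45, replace = TRUE),
                       callRate = 1, stringsAsFactors = FALSE)
    cmp2 <- composition(x2, pan2)
    for (k in 1:4) {
        oracle <- naiveComposition(dosage(x2)[, k], pan2)
        expect_equal(unname(unlist(cmp2[k, paste0("perc.", names(oracle))])),
                     unname(oracle))
    }
    perm <- pan2[sample(nrow(pan2)), ]
    expect_equal(composition(x2, perm)$perc.kousa, cmp2$perc.kousa)
    # defined percentages always sum to 100
    sums <- rowSums(cmp2[, c("perc.florida", "perc.kousa", "perc.nuttallii")])
    expect_equal(sums[!cmp2$undefined], rep(100, sum(!cmp2$undefined)),
                 ignore_attr = TRUE)
})

test_that("segment calling respects runs, singletons and contig boundaries", {
    pan <- data.frame(species = "nuttallii", marker = paste0("m", 1:10),
                      contig = rep(c("c1", "c2"), each = 5),
                      position = rep(1:5 * 1e6, 2), speciesAllele = "alt",
                      callRate = 1, stringsAsFactors = FALSE)
    # block of 3 het loci on c1, isolated singleton on c1;
    # hom block of 2 spanning the c1/c2 boundary must not join
    d <- cbind(acc = c(1L, 1L, 1L, 0L, 2L,  2L, 0L, 0L, 1L, 0L))
    rownames(d) <- paste0("m", 1:10)
    x <- genotypeCalls(d, contig = pan$contig, position = pan$position,
                       ref = "A", alt = "G")
    res <- introgressionSegments(x, pan, minRun = 3)
    expect_equal(nrow(res$segments), 1L)
    expect_equal(res$segments$start, 1e6)
    expect_equal(res$segments$end, 3e6)
    expect_equal(res$segments$nLoci, 3L)
    expect_equal(res$segments$zygosity, "all-het")
    expect_equal(nrow(res$singletons), 3L)   # m5 | m6 (split) and m9
    expect_true(all(res$singletons$nLoci < 3))
    # hom-donor run zygosity
    d2 <- cbind(acc = c(2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
    rownames(d2) <- paste0("m", 1:10)
    x2 <- genotypeCalls(d2, contig = pan$contig, position = pan$position,
                        ref = "A", alt = "G")
    expect_equal(introgressionSegments(x2, pan)$segments$zygosity, "all-hom")
})

test_that("panel coverage gaps are binned per contig", {
    pan <- data.frame(contig = "c1", position = seq(1e6, 10e6, by = 1e6))
    res <- panelCoverageGaps(pan)
    expect_equal(unname(res$counts), c(0, 0))
    # plant a 6-Mb void
    pan2 <- data.frame(contig = "c1",
                       position = c(seq(1e6, 4e6, by = 1e6), 10e6, 11e6))
    res2 <- panelCoverageGaps(pan2)
    expect_equal(unname(res2$counts["5-+Mb"]), 1)
    expect_equal(res2$maxGapMb, 6)
    expect_message(panelCoverageGaps(data.frame(contig = "c9", position = 1e6)),
                   "skipped")
})

test_that("pedigree expectations follow the halving rule", {
    ped <- data.frame(
        id = c("K", "F", "f1", "bc1", "bc2", "bc3"),
        type = c("founder:kousa", "founder:florida", "cross", "cross", "op", "op"),
        parent1 = c(NA, NA, "K", "f1", "bc1", "bc2"),
        parent2 = c(NA, NA, "F", "K", "", ""))
    E <- expectedComposition(ped, opSpecies = "kousa")
    expect_equal(E["f1", ], c(florida = 50, kousa = 50))
    expect_equal(E["bc1", ], c(florida = 25, kousa = 75))
    expect_equal(E["bc2", ], c(florida = 12.5, kousa = 87.5))
    expect_equal(E["bc3", "florida"], 6.25)
    # closed form: n-generation backcross chain gives 100 * (1 - 2^-(n+1))
    n <- 8
    chain <- data.frame(
        id = c("K", "F", "g0", paste0("g", seq_len(n))),
        type = c("founder:kousa", "founder:florida", "cross", rep("cross", n)),
        parent1 = c(NA, NA, "K", paste0("g", 0:(n - 1))),
        parent2 = c(NA, NA, "F", rep("K", n)))
    E2 <- expectedComposition(chain)
    expect_equal(unname(E2[paste0("g", 1:n), "kousa"]),
                 100 * (1 - 2^-(1 + 1:n)))
    # self, clone and apomict copy the parent vector
    ped2 <- rbind(ped, data.frame(id = c("s", "c", "a"),
                                  type = c("self", "clone", "apomict"),
                                  parent1 = c("f1", "bc1", "bc2"),
                                  parent2 = NA))
    E3 <- expectedComposition(ped2)
    expect_equal(E3["s", ], E3["f1", ])
    expect_equal(E3["c", ], E3["bc1", ])
    expect_equal(E3["a", ], E3["bc2", ])
})

test_that("pedigree validation rejects cycles and unlabeled founders", {
    bad <- data.frame(id = c("a", "b"), type = c("cross", "cross"),
                      parent1 = c("b", "a"), parent2 = c("b", "a"))
    expect_error(expectedComposition(bad), "undeclared|topological")
    bad2 <- data.frame(id = "a", type = "founder", parent1 = NA, parent2 = NA)
    expect_error(expectedComposition(bad2), "species label")
})
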