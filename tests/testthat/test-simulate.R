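test_that("simConfig validates its rates and counts", {
    expect_error(simConfig(errorRate = 1.2), "errorRate")
    expect_error(simConfig(speciesDiagnosticPerContig = 100), "divisible")
    cfg <- simConfig()
    expect_s3_class(cfg, "SimConfig")
    expect_equal(cfg$markersPerContig, 300)
    expect_equal(cfg$crossoverLambda, 1.5)
})

test_that("founder simulation is seed-deterministic end to end", {
    cfg <- simConfig(nContigs = 3, markersPerContig = 40,
                     speciesDiagnosticPerContig = 9,
                     subspeciesDiagnosticPerContig = 4)
    f1 <- simulateFounders(cfg, nPerSpecies = 4, seed = 83)
    f2 <- simulateFounders(cfg, nPerSpecies = 4, seed = 83)
    expect_identical(dosage(founderGenotypes(f1)), dosage(founderGenotypes(f2)))
    ped <- data.frame(id = "kid", type = "cross",
                      parent1 = "kousa_f01", parent2 = "florida_f01")
    s1 <- applyPedigree(ped, f1, seed = 84)
    s2 <- applyPedigree(ped, f2, seed = 84)
    expect_identical(dosage(s1$calls), dosage(s2$calls))
    expect_identical(s1$truth$ancestry, s2$truth$ancestry)
})

test_that("pure founders carry their diagnostic alleles homozygously", {
    cfg <- simConfig(nContigs = 3, markersPerContig = 30,
                     speciesDiagnosticPerContig = 9,
                     subspeciesDiagnosticPerContig = 0)
    f <- simulateFounders(cfg, nPerSpecies = 3, seed = 85)
    x <- founderGenotypes(f)
    tp <- truthPanels(f)
    cmp <- composition(x, tp)
    for (sp in unique(f$pools$species)) {
        own <- cmp[cmp$id %in% f$pools$id[f$pools$species == sp], ]
        expect_equal(own[[paste0("perc.", sp)]], rep(100, nrow(own)))
    }
})

test_that("gametes respect crossover counts and carry whole haplotypes at lambda 0", {
    cfg <- simConfig(nContigs = 2, markersPerContig = 50,
                     speciesDiagnosticPerContig = 0,
                     subspeciesDiagnosticPerContig = 0,
                     species = "kousa", subspeciesHost = "kousa",
                     crossoverLambda = 0)
    f <- simulateFounders(cfg, nPerSpecies = 2, seed = 87)
    ind <- f$individuals[[1]]
    map <- f$map
    ci <- split(seq_len(nrow(map)), map$contig)
    withr::with_seed(88, g <- MarkerKin:::.makeGamete(ind, ci, map$position,
                                                      cfg$contigLengthBp, 0))
    for (idx in ci) {
        same1 <- identical(g$h[idx], ind$h[idx, 1L])
        same2 <- identical(g$h[idx], ind$h[idx, 2L])
        expect_true(same1 || same2)
    }
})

test_that("F1 gametes transmit each parental species half the time on average", {
    cfg <- simConfig(nContigs = 2, markersPerContig = 50,
                     speciesDiagnosticPerContig = 0,
                     subspeciesDiagnosticPerContig = 0)
    f <- simulateFounders(cfg, nPerSpecies = 2, seed = 89)
    ped <- data.frame(id = "f1", type = "cross",
                      parent1 = "kousa_f01", parent2 = "florida_f01")
    sim <- applyPedigree(ped, f, seed = 90)
    # rebuild the phased F1 by hand from truth per-locus ancestry is not
    # needed: draw gametes from the stored founder-cross via a self pedigree
    kIdx <- match("kousa", cfg$species)
    map <- f$map
    ci <- split(seq_len(nrow(map)), map$contig)
    f1ind <- list(h = cbind(f$individuals[["kousa_f01"]]$h[, 1L],
                            f$individuals[["florida_f01"]]$h[, 1L]),
                  anc = cbind(matrix(kIdx, nrow(map), 1L),
                              matrix(match("florida", cfg$species), nrow(map), 1L)))
    withr::with_seed(91, {
        fr <- vapply(seq_len(10000), function(i) {
            g <- MarkerKin:::.makeGamete(f1ind, ci, map$position,
                                         cfg$contigLengthBp, 1.5)
            mean(g$anc == kIdx)
        }, numeric(1))
    })
    expect_lt(abs(mean(fr) - 0.5), 0.02)
    expect_gt(stats::sd(fr), 0)   # recombination actually mixes
})

test_that("realized ancestry fractions are conserved and BC2 centers near 12.5%", {
    cfg <- simConfig(nContigs = 10, markersPerContig = 60,
                     speciesDiagnosticPerContig = 0,
                     subspeciesDiagnosticPerContig = 0)
    f <- simulateFounders(cfg, nPerSpecies = 8, seed = 93)
    n <- 40
    ped <- rbind(
        data.frame(id = "f1", type = "cross", parent1 = "kousa_f01",
                   parent2 = "florida_f01"),
        data.frame(id = paste0("bc1_", 1:n), type = "cross", parent1 = "f1",
                   parent2 = sprintf("kousa_f%02d", 2 + (1:n %% 6))),
        data.frame(id = paste0("bc2_", 1:n), type = "cross",
                   parent1 = paste0("bc1_", 1:n),
                   parent2 = sprintf("kousa_f%02d", 2 + ((1:n + 3) %% 6))))
    sim <- applyPedigree(ped, f, seed = 94)
    anc <- sim$truth$ancestry
    expect_equal(rowSums(anc[, cfg$species]), rep(100, nrow(anc)),
                 ignore_attr = TRUE)
    bc2 <- anc[grepl("^bc2", anc$id), ]
    expect_lt(abs(mean(bc2$florida) - 12.5), 1.5)
    expect_equal(anc$florida[anc$id == "f1"], 50)
})

test_that("clones and open pollination behave as defined", {
    cfg <- simConfig(nContigs = 4, markersPerContig = 80,
                     speciesDiagnosticPerContig = 0,
                     subspeciesDiagnosticPerContig = 0)
    f <- simulateFounders(cfg, nPerSpecies = 4, seed = 95)
    ped <- data.frame(
        id = c("f1", "cl", "ap", "opk"),
        type = c("cross", "clone", "apomict", "op"),
        parent1 = c("kousa_f01", "f1", "cl", "f1"),
        parent2 = c("florida_f01", NA, NA, ""))
    sim <- applyPedigree(ped, f, opSpecies = "kousa", seed = 96)
    d <- dosage(sim$calls)
    expect_equal(gowerSimilarity(d[, "f1"], d[, "cl"], 10), 1)
    expect_equal(as.numeric(pohl(d[, "f1"], d[, "opk"], 10)), 0)
    expect_equal(sim$truth$cloneGroups, list(c("ap", "cl", "f1")))
    # OP pollen is pure kousa: expected donor fraction drops toward 25%
    expect_lt(sim$truth$ancestry$florida[sim$truth$ancestry$id == "opk"], 50)
})

test_that("the error model perturbs calls at the configured rates and directions", {
    x <- randomCalls(3000, 2, missing = 0, seed = 97)
    expect_identical(dosage(applyErrorModel(x, 0, 0, seed = 1)), dosage(x))
    expect_true(all(is.na(dosage(applyErrorModel(x, 0, 1, seed = 1)))))
    y <- applyErrorModel(x, errorRate = 0.2, missingRate = 0, seed = 2)
    d0 <- dosage(x); d1 <- dosage(y)
    flipped <- which(d0 != d1)
    # hom -> het only; het -> hom only
    expect_true(all(d1[flipped][d0[flipped] != 1L] == 1L))
    expect_true(all(d1[flipped][d0[flipped] == 1L] %in% c(0L, 2L)))
    expect_lt(abs(length(flipped) / length(d0) - 0.2), 0.03)
    # original object untouched
    expect_identical(dosage(x), d0)
})

test_that("single miscalls cannot create opposite homozygotes in true dyads", {
    cfg <- simConfig(nContigs = 10, markersPerContig = 300,
                     speciesDiagnosticPerContig = 0,
                     subspeciesDiagnosticPerContig = 0,
                     species = "kousa", subspeciesHost = "kousa")
    f <- simulateFounders(cfg, nPerSpecies = 6, seed = 98)
    ped <- data.frame(id = paste0("off", 1:3), type = "cross",
                      parent1 = sprintf("kousa_f%02d", 1:3),
                      parent2 = sprintf("kousa_f%02d", 4:6))
    sim <- applyPedigree(ped, f, seed = 99)
    x <- applyErrorModel(combineAccessions(founderGenotypes(f), sim$calls),
                         0.003, 0.02, seed = 100)
    d <- dosage(x)
    for (k in 1:3) {
        p <- as.numeric(pohl(d[, sprintf("kousa_f%02d", k)],
                             d[, paste0("off", k)], 100))
        expect_lt(p, 0.005)
    }
})
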