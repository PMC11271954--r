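Package: MarkerKin
Title: Clonal Identity, Parentage, and Hybrid Ancestry from Biallelic Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for cultivar and germplasm collections genotyped at
    thousands of biallelic SNP and Indel markers. Implements a modified Gower
    similarity for clonal-identity fingerprinting, parent-offspring triad and
    dyad assignment by opposite-homozygote exclusion with Dixon outlier tests
    on ordered dissimilarity gaps, selection of species- and
    subspecies-diagnostic marker panels, interspecific hybrid composition and
    introgression-segment mapping, pedigree-expectation calculation, and a
    pedigreed genotype simulator with recombination for validation on data
    with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
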