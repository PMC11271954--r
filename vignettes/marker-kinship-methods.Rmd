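---
title: "Clonal identity, parentage, and hybrid ancestry from biallelic markers: methods"
author: "MarkerKin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal identity, parentage, and hybrid ancestry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

MarkerKin analyses germplasm collections — cultivars, breeding selections and
wild-collected accessions — genotyped at thousands of biallelic SNP and Indel
markers, the typical output of RADseq/GBS pipelines. The running example
throughout is ornamental dogwood germplasm: three hybridizing species
(*Cornus florida*, *C. kousa*, *C. nuttallii*) and the two *C. kousa*
subspecies (*chinensis* and *kousa*), but nothing in the machinery is
taxon-specific.

All analyses operate on a `GenotypeCalls` object, an S4 container extending
`RangedSummarizedExperiment`: rows are markers (a `GRanges` with REF/ALT
alleles), columns are accessions, and the single assay codes each call as
alt-allele dosage — 0 ("AA"), 1 ("AB"), 2 ("BB"), `NA` missing. VCF input is
parsed with `vcfR` (GT field only; multi-allelic records are skipped and
counted); a plain tab-separated matrix format is supported symmetrically.

# Marker filtering

`filterMarkers()` applies the standard reduced-representation filter set
conjunctively: minor allele frequency ≥ 0.05 (computed from allele counts
over non-missing calls — the spec of the denominator matters; we use the
standard allele-count definition), missing rate ≤ 0.10, and heterozygote
frequency ≤ 0.90 (over non-missing calls; high-het markers are likely
paralog collapse). `thinByWindow()` keeps one marker per 500-nt genomic bin,
preferring the highest heterozygote frequency (ties: lowest missing rate,
then smallest position). Bins are half-open intervals anchored at coordinate
0 on each contig, applied to positions as read from the VCF; anchoring is a
convention the source data leave open, and fixing it makes the bin
arithmetic deterministic (positions 499 and 500 fall in different 500-nt
bins). `ldPrune()` implements a deterministic greedy windowed pruner on
squared Pearson correlation of dosages (pairwise-complete): within each
100-marker window, while any pair exceeds r² = 0.5 the member with the
higher missing rate (tie: later position) is dropped, windows slide by 10
markers, and passes repeat until stable. The removal rule and step size are
our documented reconstruction — the original analyses delegated this step to
PLINK, whose exact greedy order is not part of the record. `randomThin()`
draws a seeded uniform subsample (e.g. to 1000 markers for model-based
clustering input).

# Clonal identity

The modified Gower similarity between accessions $x$ and $y$ is

$$GS(x,y) = \frac{\sum_i s_i w_i}{\sum_i w_i},\qquad
s_i = \begin{cases}1 & \text{identical genotypes}\\
0.5 & \text{one shared allele (hom vs het)}\\
0 & \text{opposite homozygotes}\end{cases}$$

with $w_i = 1$ only when both accessions are genotyped at locus $i$.
Equivalently $GS = 1 - \overline{|x_i - y_i|}/2$ over shared loci, which is
how the all-pairs implementation computes it (genotype-class
cross-products); a naive per-locus loop serves as the independent oracle in
the tests. Pairs sharing fewer than `minOverlap` (default 100) genotyped
loci are reported as undefined rather than as a noisy number — the data
leave this threshold open and 100 loci bounds the GS standard error near
0.05.

Accessions with pairwise GS > 0.995 are treated as clones (sports, grafted
duplicates, mislabels, possibly apomicts). `cloneGroups()` builds groups as
connected components under single linkage: reported clone triplets in
practice include pairs slightly below the threshold, so transitive closure
with explicit reporting of sub-threshold within-group pairs is the
behaviour that matches how such groups are described; the non-transitive
pairs are returned for inspection. Each group nominates a representative
(lowest missing rate, tie: lexicographic id) for de-duplicated downstream
analyses.

`expectedSelfGS()` answers a recurring forensic question: is a
near-identical "seedling selection" a clone or a self? Under selfing each
heterozygous locus has a 50% chance of becoming homozygous, so the expected
parent-offspring GS is $1 - h/4$ for parental heterozygous fraction $h$ — a
genotype with $h = 0.312$ gives 0.922, far below the clonal range
(0.996–0.999 at realistic error rates), so a GS ≈ 0.998 "self" is better
explained as a clone or apomict. The closed form is verified against
Monte-Carlo selfing in the acceptance suite.

# Parentage

**Triads** (both parents sampled): for each candidate parent pair an
expected progeny genotype (EP) is built at loci where both parents are
homozygous and genotyped — two shared homozygotes force the offspring call
(0+0→0, 2+2→2, 0+2→1). Each candidate offspring is compared to the EP by
Gower dissimilarity $GD = 1 - GS$ restricted to EP loci genotyped in the
offspring (`minEpLoci` default 100). A true offspring mismatches the EP only
through genotyping error, so its GD sits one to two orders of magnitude
below the spurious cloud.

**Dyads** (one parent sampled): for every eligible pair the proportion of
opposite-homozygote loci

$$P_{OHL}(x,y) = \frac{\sum_i o_i w_i}{\sum_i w_i}$$

is computed, with $o_i = 1$ exactly when the calls are (0,2) or (2,0). A
true parent-offspring pair shares a transmitted allele at every locus, so
$P_{OHL} = 0$ apart from error. Role metadata restricts candidacy
(parent-parent and offspring-offspring pairs are excluded), clonal pairs
are excluded when clone groups are supplied (a clone trivially has
$P_{OHL} \approx 0$ but is not a parent), and significant dyads are oriented
by introduction dates where available (older = parent). The literature
rule-of-thumb threshold $P_{OHL} \approx 0.010$ is attached to the result
for reference but never drives significance.

**Gap detection and Dixon tests.** Both scans pool their statistic, sort
ascending, and locate the largest gap among the first
$\lfloor n_{gaps}/2 \rfloor$ consecutive gaps (earliest index on ties). A
first Dixon test asks whether that gap is a high outlier against 29 gaps
sampled uniformly without replacement from the remaining gaps; if it is
(p < α), each candidate below the gap is tested as a low outlier against
the 29 lowest values above the gap. The Dixon statistic is the r22 ratio
for a pooled sample of 30 — $(x_3 - x_1)/(x_{28} - x_1)$ for a low outlier,
mirrored for a high one — with p-values estimated by Monte Carlo under a
standard-normal null (default $10^5$ seeded replicates; published critical
tables for n = 30 are sparse and a simulated null gives continuous,
reproducible p-values). A candidate not on its claimed tail, or a fully
tied sample, returns p = 1. No multiple-testing correction is applied by
default, matching how such scans are reported (raw α < 0.05).

Two honest caveats, both reproduced by the test suite. First, when more
than 25% of pairs fall below $P_{OHL} = 0.02$ the scan raises a structure
warning: strong subgroup delineation (e.g. two subspecies with many fixed
differences) depresses within-group $P_{OHL}$ and can blur the true/spurious
gap. Second, the first Dixon test is *not* a calibrated null-hypothesis test
on unstructured data: the largest first-half gap of an ordered sample of
hundreds of pairwise statistics is an extreme-tail order spacing, typically
tens of times the median spacing, so comparing it against 29 randomly
sampled gaps flags it as an outlier in the large majority of fully
unrelated populations. The procedure's protection against false dyads comes
from the second Dixon test — candidates below a (possibly spurious) gap are
still compared against the 29 lowest values above it, and in an
unstructured cloud they are not outliers there. The dyad/triad benchmarks
in the acceptance suite measure both properties.

# Species-diagnostic panels and hybrid composition

`selectSpeciesMarkers()` screens reference accessions for diagnostic loci:
pooled reference call rate ≥ 0.88 (the presence threshold is read as a
pooled rate; a per-group alternative would be stricter but the pooled
reading matches how a single "% of the reference accessions" is stated),
every non-missing reference call homozygous, fixed within each reference
group, and polymorphic between groups. With three groups the diagnostic
species is the unique odd group out; with exactly two groups both differ
and the marker is assigned to the group fixed for the ALT allele — an
arbitrary but documented rule that keeps panels disjoint.
`equalizePanels()` reduces all panels to the smallest panel's size so each
species contributes equally to the composition denominator: first a cap of
three markers per 500-bp bin (keeping the highest call rates), then removal
of the lowest-call-rate markers (tie: later position) until sizes match —
our reconstruction of an equalization described only as a cap plus deletion
of "about 100" lowest-call-rate markers.

Composition per accession scores each panel locus
$L = 1$ (homozygous species allele), $0.5$ (heterozygous), $0$ (homozygous
other allele **or missing**), and reports

$$Perc(s) = \frac{\sum L_s}{\sum_{s'} \sum L_{s'}} \times 100 .$$

Scoring missing data as 0 follows the source convention verbatim even
though it deflates the numerator for high-missingness accessions; the
emitted panel call rate makes the bias visible. An F1 scores 50/50/0
exactly in error-free data; backcross generations halve the donor share in
expectation.

`introgressionSegments()` orders each donor panel along each contig and
reports maximal runs of consecutive loci with $L \ge 0.5$ as segments when
the run covers at least `minRun = 3` loci; shorter runs are listed as
singletons (isolated donor alleles are far more likely genotyping errors
than real tracts, which recombination leaves as multi-locus blocks).
Segment span is the inner span between supporting loci — a lower bound on
the true tract. `panelCoverageGaps()` bins inter-locus distances per contig
to expose genomic regions where a panel is blind to introgression.

`expectedComposition()` propagates pedigree expectations: founders are 100%
their species, crosses average their parents, selfs/clones/apomicts copy
the parent, and open-pollination events average the mother with a pure
vector of the assumed pollen species (default the recurrent species,
*C. kousa* in the motivating programme — a required, explicit assumption).
The donor fraction halves each backcross: F1 50/50, BC1 75/25, BC2
87.5/12.5, BC3 6.25% donor.

# Subspecies panel

`selectDiagnosticMarkers()` finds fixed differences between two subspecies
reference sets and ranks them by call rate; the top 7 emulate a small
KASP-style assay panel. Scoring is 0 / 0.5 / 1 (chinensis hom / het / kousa
hom) averaged over *non-missing* panel calls — unlike composition's L rule,
because assay reads have no missing-as-zero convention. Classification:
mean < 0.10 → ssp. *chinensis*, > 0.90 → ssp. *kousa*, otherwise hybrid;
the published ranges overlap at the boundaries, so exactly 0.10 and 0.90
fall in "hybrid" here (documented, configurable by the caller through the
mean). `concordance()` compares panel classes against the full
fixed-difference set mean, the in-silico stand-in for a model-based
membership analysis.

# The synthetic-data generator

Every quantitative claim in the test and acceptance suites is made on data
from `simulateFounders()` / `applyPedigree()` / `applyErrorModel()`, which
emulate the statistical structure the analyses assume:

* **Marker landscape** — 10 contigs of 10 Mb; per contig 300 polymorphic
  background loci (≈3000 overall, the scale of the real filtered matrices)
  plus planted diagnostic loci. The configuration lists background and
  diagnostic counts separately; benchmarks that need 2700
  diagnostic loci per species set 270 per species per contig, the divisible
  analog of the published 2703-per-species panels.
* **Pools** — background alt-allele frequencies drawn per species pool from
  Beta(0.8, 0.8) (U-shaped, mimicking the site-frequency spectra of
  reduced-representation panels after MAF filtering); founders are sampled
  in Hardy-Weinberg proportions within pools. Species-diagnostic loci are
  fixed homozygous for a randomly oriented species allele in the owning
  pool and for the other allele elsewhere; subspecies-diagnostic loci are
  fixed differences between the two host-species subpools.
* **Meiosis** — crossovers per contig are Poisson(1.5) at uniform
  positions, no obligate chiasma, no interference; per-locus
  founder-species ancestry is carried through every gamete, so realized
  ancestry fractions and donor blocks are known exactly.
* **Noise** — independently per call: missing with probability 0.02,
  otherwise miscalled with probability 0.003 (het → a random homozygote,
  hom → het). The hom→het-only direction means a single miscall can never
  turn a shared-allele locus into an opposite-homozygote pair, which is
  what keeps true-dyad $P_{OHL}$ at the per-mille scale observed in real
  data (0.003–0.008) while clone GS lands at 0.996–0.999. The rates are
  reverse-engineered from those two published scales — the source reports
  no direct error-rate estimate — and are configurable.

What the generator does **not** emulate: linkage disequilibrium within
pools (background frequencies are locus-independent), allele dropout as a
distinct error mode, relatedness structure inside "unrelated" pools, hybrid
sterility/viability selection, and triploids. Passing benchmarks therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to every pathology of real RADseq data.

# Numerical and design choices, in one place

* Dosage encoding with `NA` missing; all pairwise statistics use
  pairwise-complete loci with explicit minimum-overlap guards.
* Window bins anchored at 0, half-open, positions as read (1-based VCF).
* Clone grouping: single linkage at strict GS > 0.995; representative by
  lowest missing rate, tie lexicographic.
* Gap scan: first ⌊n/2⌋ gaps, earliest-index tie-break; 29-gap sample
  excludes the tested gap; both Dixon nulls are drawn inside one seeded
  stream per scan, so scans are exactly reproducible.
* Dixon r22 with Monte-Carlo normal null; p = fraction of null ratios at
  least as extreme.
* Panel selection presence threshold over pooled references; two-group
  fixed differences assigned to the ALT-fixed group.
* Composition: L = 0 for missing; percentages undefined (flagged) when all
  panel sums are zero.
* Subspecies boundaries 0.10/0.90 inclusive into "hybrid".
* Benchmark sizes in the test suite (20 seeds for the dyad/triad designs,
  200 clone pairs per replicate, 50 BC2 individuals, 10,000 selfing
  replicates) were chosen to estimate each property with standard errors
  comfortably inside the asserted bounds.

# Known limitations

Likelihood-based parentage (LOD scores), sibship reconstruction, HMM local
ancestry, phasing, imputation and triploid dosage are out of scope. The
first Dixon gap test should be read as a screening device, not a calibrated
test (see the parentage section); interpret a significant gap in a
structured or fully unrelated collection through the second-stage tests and
the structure warning. Open-pollination expectations assume pure
recurrent-species pollen; if interspecific hybrids contribute pollen, the
realized donor fraction exceeds the expectation.
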