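---
title: "Methods: inferring sex chromosome evolution from coverage, synteny and expression"
author: "karyoevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring sex chromosome evolution from coverage, synteny and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoevolve)
```

# The scientific problem

Beetle karyotypes evolve by chromosomal fusion and fission, and in several
lineages an autosome has fused to the ancestral X, creating a neo-sex
chromosome. Three observable signals let us reconstruct this history
without any cytogenetics:

1. **Sequencing depth by sex.** Males carry one X and females two, so an
   X-linked region shows half male depth and a normalized female/male (F/M)
   window ratio near 2; autosomes sit at 1, and Y-derived sequence has
   essentially no female coverage. A *neo-X* whose neo-Y partner has not
   fully degenerated sits in between: if the neo-Y still covers a fraction
   $\theta \in [0,1]$ of male reads, the expected male depth on the neo-X
   is $D_M(1+\theta)/2$ and the F/M ratio is $2/(1+\theta)$.
2. **Synteny of 1:1 orthologs.** Ancestral linkage groups ("Stevens
   elements", the beetle analogue of *Drosophila* Muller elements) conserve
   their gene content across species even as fusions and fissions repackage
   them, so cross-species ortholog placements reveal which modern
   chromosomes descend from which element.
3. **Expression.** After the Y copy of a gene is lost, males either halve
   its expression (no dosage compensation, M/F $\approx 0.5$) or restore it
   (complete compensation, M/F $\approx 1$); and sex chromosomes accumulate
   non-random complements of gonadally sex-biased genes.

`karyoevolve` implements this inference chain — window-level F/M ratio
classification, ancestral-element assignment with fusion/fission counts,
changepoint mapping of the ancestral-X/neo-X boundary, and
dosage-compensation / gonad-bias statistics — together with a simulator
that generates all three data types with known ground truth, so every
stage is testable end to end.

# Coverage-based sex linkage

## Windowing and normalization

Depth tracks (bedGraph or per-base TSV) are collapsed to per-window
medians (`windowMedians()`): each constant-depth interval contributes its
value weighted by the number of its sites inside the window, uncovered
sites count as depth 0 (the bedGraph convention of omitting zero runs),
and completely empty windows are flagged rather than used. The weighted
median resolves ties toward the lower value, so results are always
attained depths. The default window is 50 kb, with 10 kb as the usual
choice for fine-scale views of a single chromosome.

Each sample is divided by its own normalization constant before ratios are
formed (`fmRatio()`). Two modes are provided:

* `genome_median` (default): the genome-wide median window depth. A single
  pass, adequate when sex-linked sequence is a small fraction of the
  genome.
* `autosomal_median`: the median over a supplied autosomal scaffold set,
  typically the autosomal calls of a first `genome_median` pass (iterate
  once). This matters quantitatively: when, say, 20% of windows are
  sex-linked, the genome-wide male median is dragged below the autosomal
  mode and every ratio is deflated by several percent; re-normalizing
  against called autosomes restores the X expectation of 2. The package's
  own validation uses the two-pass mode whenever the value of the ratio
  (rather than a threshold crossing) is the quantity of interest.

Windows whose normalized male depth falls below `minMDepth` (default 0.1,
about 2–3 reads at 20–30x) are flagged as candidate female-specific
sequence and excluded from scaffold medians instead of producing unstable
ratios.

## Classification thresholds

A scaffold's call (`classifyScaffolds()`) comes from the median of its
window ratios — robust to repeat-dense outlier windows. The X rule is
**inclusive at 1.6** (`ratio >= 1.6`): the theoretical expectation is 2.0,
and the gap between 1.6 and 2.0 absorbs mapping noise; both thresholds are
configurable. No Y rule is forced by theory, so we use `ratio <= 0.3` with
male depth above the floor, which cleanly separates Y scaffolds from X and
autosomes at 10x or more. Scaffolds with fewer than `minWindows = 3`
informative windows are reported `ambiguous` rather than guessed. The
classes are mutually exclusive and exhaustive, and every call is invariant
to rescaling either sample's depths (only ratios to each sample's own
normalization constant enter).

## Neo-X differentiation and the breakpoint

`differentiationScore()` summarizes a region by (i) mean normalized male
depth relative to an autosomal reference, which estimates $(1+\theta)/2$;
(ii) the fraction of windows at or above the X threshold; and (iii) the SD
of the log2 ratio, since young neo-X chromosomes are heterogeneous along
their length.

`detectBreakpoint()` places the boundary between the ancestral-X and neo-X
arms of a fused chromosome by an exhaustive least-squares scan: every
window boundary is scored by the total within-segment squared error of the
log2 ratio, and the minimum is taken. Because the scan is exhaustive the
estimate is the global optimum by construction. A breakpoint is only
reported if the best split reduces the total cost by at least `minGain`
(default 10%) relative to the unsegmented fit — on a homogeneous
chromosome the best of $n-1$ candidate splits still captures some noise,
so an ungated scan would "find" a boundary anywhere. The confidence
interval collects all boundaries within one mean per-window cost unit of
the minimum. Segment classes (by median ratio against the X/Y thresholds)
are reported on both sides so that a synteny-based element assignment can
corroborate the coverage boundary; synteny is deliberately *not* part of
the optimization.

# Ancestral element assignment

`buildHomologyMatrix()` cross-tabulates 1:1 ortholog placements between a
focal and a target species. `assignElements()` then applies a majority
rule anchored on the focal species: a focal linkage group is an ancestral
element if, in at least one target species, strictly more than
`majorityFrac` (default 0.5) of its placed orthologs — and at least
`minOrthologs` (default 20) of them — land on a single target chromosome.
A tie at exactly the majority fraction leaves the group unassigned
(conservative), as does scatter across many chromosomes in every species.
The defaults were chosen so that noise-level cells (a handful of stray
orthologs) neither create spurious element splits nor block assignment;
both are configurable and `minOrthologs` doubles as the reporting
resolution of the composition table: a chromosome "carries" an element
only if it holds at least that many of its orthologs.

The composition table (`compositionTable()`) renders, per element and
species, `k(chrom1,chrom2,...)` cells — the number of chromosomes carrying
the element and their ids — with a dash row of zeros for unassigned
groups. `countEvents()` converts the same cells into fusion/fission counts
by star parsimony against the one-chromosome-per-element ancestor: each
extra chromosome carrying an element is one fission, each extra element
sharing a chromosome one fusion. This is per-species parsimony (matching
how such tables are presented), not a tree-aware reconstruction, and event
order and cancelling histories are outside its resolution.

Anchoring on a focal species presumes that species retains the ancestral
packaging (as the red flour beetle does among real beetles). In simulated
validation the ancestral karyotype itself is emitted as the focal row of
the ortholog table (`simulateOrthologTable(includeRoot = TRUE)`); a tip
that has undergone its own fusions cannot anchor element labels.

`conservedSexOrthologs()` intersects per-species X calls over the ortholog
table, and `detectNeoSexElements()` projects one species' X calls onto the
assignment, splitting the sex-linked elements into the ancestral-X element
and autosome-derived (neo) elements — one added element for a simple
fusion, two when the fused arm was itself a fusion product.

# Expression statistics

All per-tissue and per-group gene values are medians over replicates.
Genes enter an analysis if their value is at least `minFpkm = 1` in either
of the two contrasted groups (inclusive, `filterExpressed()`).

`dosageCompare()` reports per-stratum medians and the ratio of medians
(M/F), matching the boxplot framing of such analyses rather than the
median of per-gene ratios; zeros are kept without pseudocounts since only
ranks and medians are used. All pairwise stratum-by-sex groups are
compared with Wilcoxon rank-sum tests — exact by enumeration when both
groups are small (`min(n) <= 8`) and tie-free, otherwise the normal
approximation with tie and continuity correction (delegated to
`stats::wilcox.test()`, with the classical rank-sum statistic reported) —
and Bonferroni-corrected within the invoked comparison family, whose size
is reported alongside. Compact letter groups are maximal cliques of the
non-significance graph, so groups sharing a letter are statistically
indistinguishable at the corrected level.

`protoVsNeo()` compares neo-X gene expression against the same genes'
orthologs in an outgroup where the homologous element is still autosomal:
under complete compensation the neo-X/proto-X median ratio is near 1 in
both sexes; without compensation males fall to 0.5 while females stay at
1.

`classifyGonadBias()` applies the strict rule: a gene is ovary-
(testis-)biased only if its gonad value is strictly more than `fold = 2`
times the maximum over *all* other tissues; a gene at exactly 2-fold, or
an all-zero gene, is unbiased. `testEnrichment()` then tests each
chromosome stratum for enrichment and depletion of each bias class with
both hypergeometric tails (`stats::phyper()`), Bonferroni-corrected over
every stratum-by-class-by-tail test performed. The background is the gene
set carried by the bias calls — by default everything that passed the
expression filter; passing unfiltered calls switches the background to all
genes.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated. It emulates:

* **Karyotype histories** (`simulateKaryotypeHistory()`): from an ancestor
  with one chromosome per element (default 9 elements, labelled X and A–H,
  200 genes each), fusion and fission counts on each branch are Poisson
  with mean rate x branch length; fusions join two uniformly chosen
  chromosomes end-to-end with uniform orientations, fissions split a
  uniformly chosen multi-gene chromosome at a uniform internal gene
  boundary. Gene content is conserved and element labels are immutable, so
  ground truth is exact. Infeasible events are skipped and logged. Every
  sampled quantity is recorded per event, so `replayKaryotype()`
  reproduces all tip maps exactly and identical seeds give byte-identical
  histories.
* **Ortholog tables** (`simulateOrthologTable()`): complete 1:1, with
  within-segment gene shuffling at a per-gene rate. A segment is a maximal
  same-element run on a tip chromosome; the genes selected for shuffling
  are randomly permuted among their own slots, which keeps ordinal
  positions unique, makes rate 0 the identity and rate 1 a uniform
  within-segment permutation, and guarantees no gene ever crosses a fusion
  boundary — the qualitative pattern seen on real fused X chromosomes. No
  quantitative shuffling rate is known from real data, so the rate is
  free; the pipeline default is 0.2.
* **Sexed coverage** (`simulateCoverage()`): per-window depth is the
  window's total negative-binomial read-base count divided by window
  length. The class means are exactly the hemizygosity expectations above
  (with Y windows given a 1% female noise floor emulating repetitive
  cross-mapping rather than exact zeros), and `dispersion` is the NB size
  governing window-to-window overdispersion ($\mathrm{CV}^2 \approx
  1/\mathrm{size}$; large values approach the counting-noise/Poisson
  limit). Dividing the window total by its length keeps the simulated
  window median continuous, as a median over tens of kb of sites is in
  real data — a single integer draw at 20x would quantize the
  median-based normalization constants by +/-5%. The default dispersion of
  10 (CV ~32%) represents noisy draft-assembly mapping; breakpoint mapping
  on chromosome-level assemblies is validated in the counting-noise-limited
  regime (dispersion 1000 at 40x/60x), where 50 kb window medians are as
  tight as they are in practice.
* **Expression** (`simulateExpression()`): log-normal gene baselines
  (meanlog 3, sdlog 1), log-normal per-sample noise (sdlog 0.2), a
  two-state-plus-intermediate dosage model multiplying male X-class genes
  by 1 (complete), 0.5 (none) or $(1+\lambda)/2$ (partial), and
  gonad-biased fractions (default 10% ovary + 10% testis) spiked by
  `biasFold = 4` in their target gonad only. Truth labels are returned for
  recall/precision scoring.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: GC- and mappability-driven depth bias,
copy-number variation, collinearity breakage beyond within-segment
shuffling, gene gain/loss and translocation between elements,
recombination-suppression dynamics, TE accumulation on the Y, and
expression count noise tied to sequencing depth. The validation
demonstrates that the estimators recover the signal their models assume;
robustness to violations of those models must come from the real-data
thresholds (the 1.6 cutoff, the minimum-window and minimum-ortholog
floors) that the defaults deliberately keep conservative.

# Numerical choices and degenerate inputs

* Weighted medians take the lower middle value; scaffold medians use only
  informative (unflagged) windows.
* `log2` ratios of zero-female windows are set `NA` and excluded from the
  changepoint scan rather than propagating `-Inf`.
* The changepoint scan uses prefix sums ($O(n)$ after sorting) and is
  tested against a literal two-loop brute force; with a noiseless step the
  CI collapses to the exact boundary.
* Empty ratio tables classify to an empty call table; a constant signal
  reports "no breakpoint"; fewer than 10 informative windows is an error.
* Ties: a majority at exactly `majorityFrac` leaves a linkage group
  unassigned; a gene at exactly the bias fold is unbiased; the X threshold
  is inclusive (`>=`), per its definition.
* Strata with fewer than 2 genes are dropped (with a warning) from dosage
  comparisons; bias classes absent from the data get p = 1.
* All list-valued outputs are sorted deterministically, so repeated runs
  under one seed are byte-identical, including TSV provenance headers
  (tool version, configuration hash, seed — no timestamps).

# Validation problem sizes

The shipped tests and the acceptance script use: 100-scaffold genomes (80
autosomal, 15 X, 5 Y; 20–200 windows of 50 kb per scaffold) at 20x/30x
for classification and ratio calibration; 100-window fused chromosomes
with a theta step of 0 vs 0.8 at 40x/60x for breakpoint mapping; ten
5-tip histories of 9 elements x 200 genes (fusion rate 0.35, fission rate
0.2 per unit branch) for element recovery; 2,000–2,500-gene expression
matrices with 500 X-class genes over a six-tissue, two-replicate panel
for dosage and bias statistics; and the default demo pipeline (9 elements
x 200 genes, 50 kb windows, theta 0.6) run twice for determinism. These
sizes make every stage's sampling error small relative to the effects
being recovered while keeping a full validation run in the order of tens
of seconds.

# Known limitations

Event counting is star parsimony, not tree-aware, and cannot see
cancelling or reverting histories; element labels are anchored to a focal
species rather than a reconstructed ancestral gene order; the breakpoint
model allows a single changepoint (a chromosome with multiple fusion
strata needs repeated application to sub-regions); coverage classification
assumes sex-linked sequence is a minority of the genome (the normalization
anchor); and the Wilcoxon/hypergeometric machinery tests location shifts
and set enrichment only — no expression-level modelling of count noise or
batch structure is attempted.
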