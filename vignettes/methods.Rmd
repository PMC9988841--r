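---
title: "Models and methods behind chromassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromassoc)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Setting

In holocentric nematode chromosomes, heterochromatin is not pericentric:
H3K9-methylation sits in dispersed small domains concentrated on the distal
chromosome **arms**, while the gene-rich **centers** carry mostly euchromatic
marks. Reader proteins (chromodomain proteins and relatives) are profiled by
ChIP-seq alongside a panel of histone marks, and the question is which mark
each reader tracks, separately on arms and centers. All coordinates are
0-based half-open on disk (BED convention) and 1-based closed in memory
(GenomicRanges convention); GFF3 input is converted on read.

## Proximity significance

The overlap statistic works peak by peak. For a query peak $q$ of length $L$
lying in a domain segment $[D_0, D_1)$ (its own arm or center segment —
conditioning the null on the domain class keeps the test consistent with the
arm/center stratification used everywhere else), the null model places $q$
uniformly over all integer start positions that keep it inside the segment.
With observed distance $d$ to the nearest reference peak (bp gap; overlap or
book-ended contact counts as 0), the p-value is the fraction of placements
whose nearest-reference distance is at most $d$. The implementation counts
favourable placements in closed form — a placement start $s$ is within $d$
of reference $[r_0, r_1)$ iff $s \in [r_0 - d - L,\; r_1 + d]$, so the
favourable set is a union of integer intervals — and the test suite checks
it against exhaustive enumeration, instance by instance, for exact rational
agreement. p-values are exact, never continuity-corrected, and deliberately
left unadjusted for multiple testing (the classifier thresholds raw
$p < 0.05$; the per-peak table carries $p$ so users can adjust). Because the
placement distribution is discrete, the null distribution of $p$ is
stochastically at least uniform — the test is conservative, which the
calibration test verifies at the 0.05 level used downstream.

A subtlety worth recording: "distance 0" includes book-ended contact
(gap 0), matching the distance definition used for `nearest_distance`; a
query identical to a 10-bp reference in a 1-kb segment therefore has
$p = 21/991$ (placements overlapping *or touching*), not $19/991$ (strict
overlaps only). Either convention would classify that example as
significant; the package pins the one consistent with its distance
semantics.

## Signal correlation

The correlation read-out mirrors the standard percentile pipeline: peaks
called from **any** dataset in the panel are merged (book-ended intervals
merge); per merged peak, the 95th percentile of per-base signal is taken
from each BPM-normalized track (linear interpolation between order
statistics — the extraction tools leave the percentile method unspecified,
so it is pinned here); values are normalized to the matched input, log2
transformed with pseudocount $\varepsilon = 1$ coverage unit, and Z-scored;
Pearson correlation and complete-linkage clustering (distance $1 - r$)
follow. The pseudocount and log base are configuration knobs: the base
cancels after Z-scoring up to the scale of the standard deviation, and
$\varepsilon$ only matters at zero-coverage loci; both are logged with every
run. Using the *panel-wide* merged peaks matters: over a pair-only union,
almost every locus contains one of the pair's peaks, leaving no
both-absent stratum and collapsing $r$ toward zero even under perfect
coupling.

## Profile matrices and coverage calls

Heatmap evidence is made quantitative in two steps. `compute_matrix` builds
a reference-point matrix (summit if available, else peak center; ±3 kb in
20-bp bins, 300 columns; windows truncated at chromosome ends are
zero-padded and flagged). `coverage_call` then declares a row "covered" when
its mean signal over the central ±500 bp exceeds twice the genome-wide
background (median per-20-bp-bin BPM value), and the pair-level flag fires
when at least half the rows are covered ($\tau = 0.5$, inclusive). The
original selection of "plots displaying no heterogeneity" was visual; it is
operationalized as k-means over $k \in \{1,2,3\}$ (fixed seed, 10 restarts,
rows scaled by their maximum so shape dominates amplitude) choosing the
smallest $k$ whose clusters all have mean pairwise cosine similarity
$\ge \theta_h = 0.8$. Fold, $\tau$, and $\theta_h$ are exposed parameters
reported with every run; the worked example's coverage count of 1585/1854
targets (≈ 0.85) for a prominent pair sits comfortably above the majority
rule.

## The graded classifier

Grade = number of satisfied criteria among C1 ($r \ge 0.300$), C2
(significant-overlap fraction $\ge 0.30$), C3 (coverage flag), labelled
none / weak / detectable / prominent for 0–3. Both numeric thresholds are
inclusive, as printed. Reading "grade 1 meets any of the 3" as
"exactly one" (the satisfied-count mapping) is the only reading that makes
the grades mutually exclusive, so grade 0 is reported explicitly rather
than dropping unclassified pairs silently. Grades are computed separately
per domain class.

## Colocalization network

For every factor pair, both directional significant-overlap fractions are
computed genome-wide; the edge weight is their **minimum**, which penalizes
a small peak set being engulfed by a large one — a broad mark can cover most
of a reader's sites while the reader covers few of the mark's, and such
asymmetric pairs should not form strong edges. Tier cutoffs (strong ≥ 0.5,
moderate ≥ 0.25) are configuration defaults; no canonical strong/moderate
boundary exists. Community structure comes from an in-package
Louvain implementation (greedy modularity optimization with local moves and
aggregation): nodes are visited in lexicographic order and ties broken
toward the smaller community id, so the partition is reproducible
byte-for-byte, and the modularity is asserted non-decreasing across passes.
The modularity of the returned partition is recomputed independently (and
cross-checked against igraph in the tests);
$Q = \sum_c [W_c/W - (S_c/2W)^2]$.

## ChIP QC

FRiP is the fraction of 5' read positions inside called peaks. The strand
cross-correlation profile is the Pearson correlation between the binarized
plus- and minus-strand 5'-end occupancy vectors at shifts $0..400$ bp,
computed exactly from sparse position lists (pair counts by difference plus
boundary-corrected marginals; the dense-vector computation is the oracle in
the tests) and averaged over chromosomes weighted by length. NSC is the
fragment-peak to background ratio (background = profile minimum); RSC uses
the background-subtracted form $(cc_{frag} - b)/(cc_{read} - b)$ — the
standard definition; since the prose description of RSC as a plain peak
ratio is ambiguous, the unsubtracted ratio is also reported
(`rsc_raw`). The fragment-length peak is located outside a ±10-bp exclusion
zone around the read length (the "phantom" peak position).

## The synthetic generator

The generator's defaults encode the study conditions rather than free
dials:

* genome: five 2-Mb chromosomes; each arm is 22% of its chromosome, so arms
  jointly hold 44% of the genome — the documented genome-wide arm share;
* heterochromatin marks: dispersed domains, log-normal lengths with median
  2 kb, Poisson counts at ~8 domains per arm with a 10× lower center rate.
  That keeps a mark at roughly 4% of arm base pairs, which is what makes
  per-peak overlap significance attainable at $\alpha = 0.05$ — a mark
  blanketing its arm cannot be "significantly" overlapped under a
  within-arm placement null, which is the scientifically right behaviour;
* euchromatin marks: promoters (±500 bp of TSS) of genes labelled active
  (FPKM ≥ 1), genes being placed preferentially in centers;
* reader peaks: log-normal lengths with median 300 bp (most reader narrow
  peaks are shorter than 500 bp); coupling $\theta$ places each peak inside
  a uniformly chosen target-mark domain with probability $\theta$, else
  uniformly in the genome, so the realized in-mark fraction has the closed
  form $\theta + (1-\theta) \cdot$ (mark genome fraction) in expectation;
* tracks: piecewise-constant at 20-bp resolution, depth 10 over
  peaks/domains plus Poisson(1) background per bin — the bin-level noise
  model keeps simulation and BPM binning aligned and is cheap enough to
  regenerate in every test;
* reads: 200-bp fragments, 50-bp single-end reads (the library layout of
  the motivating datasets); each fragment emits its plus-strand left end
  and/or minus-strand right end with probability 0.5 each. Background
  fragments (0.2 per bp, lengths uniform 100–300 bp) are placed
  proportionally to per-10-kb accessibility multipliers (log-normal,
  sdlog 1.2). The block structure is what gives real input libraries their
  positive cross-correlation baseline; without it the profile of uniform
  reads hovers around zero and NSC (a max/min ratio) is numerically
  meaningless. Depth and block variance were fixed by a pilot so that the
  baseline dominates per-shift sampling noise on the 1.6-Mb QC chromosome
  used in the tests.

RNG: one master seed, expanded into an independent Lehmer-style stream per
sub-generator, so adding a reader never perturbs mark placement and
identical seeds reproduce bundles byte-for-byte.

What the generator does **not** emulate: sequence content and mappability
(there are no reads-in-sequence, so no true phantom peak at the read
length), PCR duplicates, copy-number variation, antibody efficiency
differences, or the 60-plus-dataset breadth of a real panel. Passing tests
therefore demonstrate that the statistics recover planted structure under a
faithful interval-level model, not that any particular biological dataset
will reach a given grade.

## Problem sizes used in the checks

The validation suite uses: the full 10-Mb genome with $n = 500$ reader
peaks and 20 seeds per coupling strength $\theta \in \{0, 0.3, 0.6, 0.9\}$
for grade recovery; 200 random instances (domains up to 10 kb) for exact
oracle agreement of the proximity p-values; 2,000 uniform draws for null
calibration; 20 seeds on a 1.6-Mb chromosome for QC recovery; and scaled-
down sizes (a 2×1-Mb two-chromosome bundle, 3–8 seeds) for the per-module
property tests, chosen so the whole suite stays comfortably within an
interactive development loop.

## Known limitations

* The proximity null treats reference peaks as fixed and the query as
  uniform; reciprocal conditioning (both directions are computed) is the
  only symmetry offered.
* `kmeans_min_k`'s homogeneity threshold is a proxy for a visual judgement;
  different $\theta_h$ can change the chosen $k$ on borderline data.
* The Louvain optimizer is deterministic but greedy; like all modularity
  maximizers it can land in local optima on large graphs (the brute-force
  cross-check is exact only at toy size).
* bedGraph output drops zero runs; supply chromosome lengths (or a domain
  table, from which the pipeline takes them) when re-reading tracks so
  trailing zero bins are not lost.
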