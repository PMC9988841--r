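# chromassoc

Association mapping of chromatin reader proteins onto histone-modification
landscapes from ChIP-seq data.

## The problem

Chromodomain proteins and other histone-mark readers bind methylated histone
tails, but which mark a given reader tracks in vivo is rarely obvious from
its sequence. Given called peaks and signal tracks for a panel of readers
and histone modifications (H3K9me2/3, H3K27me3, H3K4me3, H3K36me3,
H3K79me3), `chromassoc` quantifies each reader x mark association and
classifies it on a reproducible three-grade scale, stratified by the broad
chromosome domains of holocentric nematode genomes: gene-poor,
heterochromatin-rich **arms** versus gene-rich **centers**.

## The method

For one reader x mark pair within one domain class, three read-outs are
combined:

1. **Correlation (C1).** Peaks called from any dataset in the panel are
   merged; the 95th-percentile signal of each track over each merged peak is
   normalized to input, log2-transformed and Z-scored; C1 holds when the
   Pearson correlation *r* >= 0.300.
2. **Significant overlap (C2).** Every reader peak gets an exact proximity
   p-value: with the peak placed uniformly at random within its own
   arm/center segment, *p* is the probability of lying as close to the
   nearest mark peak as observed (overlap => distance 0). C2 holds when
   >= 30% of reader peaks have raw *p* < 0.05.
3. **Heatmap coverage (C3).** A reference-point profile matrix of mark
   signal (BPM-normalized, 20-bp bins, +/-3 kb around each peak's
   summit/center) is reduced to per-peak coverage calls (central signal
   > 2x the genome-wide background median); C3 holds when at least half of
   the reader's peaks are covered.

The grade is the number of satisfied criteria: 3 = "prominent",
2 = "detectable", 1 = "weak", 0 = "none". Around this core the package
provides arm/center partitioning, complete-linkage clustering of the
correlation matrix, a colocalization network (edge weight = the smaller of
the two directional significant-overlap fractions) with Louvain community
detection, ChIP QC metrics (FRiP, strand cross-correlation, NSC, RSC), and
a synthetic-data generator that plants reader-mark couplings of known
strength so every stage is testable offline.

## Worked example

The classifier applied to a fully specified case — the adult-stage CEC-5
ChIP against H3K9me2 on chromosome arms, with *r* = 0.333, 44.3% of peaks
significantly occupied, and coverage detected by heatmap analysis:

```r
library(chromassoc)
grade_association(r = 0.333, sig_fraction = 0.443, heatmap_flag = TRUE,
                  reader = "CEC-5", mark = "H3K9me2", domain_class = "arm")
#>   reader    mark domain_class     r sig_fraction heatmap_flag grade     label
#> 1  CEC-5 H3K9me2          arm 0.333        0.443         TRUE     3 prominent
```

All three criteria hold (0.333 >= 0.300, 0.443 >= 0.30, coverage detected),
so the pair is classified grade 3, "prominent".

End to end on synthetic data — a reader coupled at strength theta = 0.9 to a
heterochromatin mark on a 10-Mb five-chromosome genome:

```r
cfg <- synthetic_config(seed = 1)
b <- simulate_experiment(cfg,
  marks = list(H3K9me2 = list(type = "het"), H3K4me3 = list(type = "eu")),
  readers = list(reader = list(target = "H3K9me2", theta = 0.9, n = 500)))
loci <- merge_intervals(list(b$readers$reader$peaks, b$marks$H3K9me2$peaks,
                             b$marks$H3K4me3$peaks))
grade_pair(b$readers$reader, b$marks$H3K9me2, b$input, b$genome$domains,
           domain_class = "arm", loci = loci)
#>   reader    mark domain_class         r sig_fraction heatmap_flag grade     label
#> 1 reader H3K9me2          arm 0.6450694    0.5839416         TRUE     3 prominent
```

The planted coupling is recovered: r = 0.65, 58% significant overlap,
coverage detected, grade 3. The same reader's peaks fall 82% on arms
(`partition_by_domain`), an emergent consequence of the arm-enriched mark
domains, and the generator's truth manifest records the realized in-mark
fraction (0.91 here) for every reader.

`run_pipeline()` chains all stages (partition, grading in both domain
classes, correlation + clustering, network + communities, annotation, QC)
and writes per-stage TSVs plus a deterministic JSON summary. A thin CLI
wrapper with `simulate`, `run-all` and `qc` subcommands is installed at
`inst/cli/chromassoc-cli.R`.

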