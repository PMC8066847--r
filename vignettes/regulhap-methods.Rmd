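---
title: "Methods: haplotype-to-regulome mapping with regulhap"
author: "regulhap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-to-regulome mapping with regulhap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulhap)
```

## The problem

Most replicated disease-risk variants found by GWAS fall outside coding
sequence, and the working hypothesis for such loci is that risk is exerted
on regulatory elements — enhancers and promoters — in particular cell
types. `regulhap` implements a desk-reproducible version of a common
workflow for interrogating that hypothesis around a panel of replicated
index SNPs:

1. **Haplotype blocks.** Each index SNP is expanded to its linkage
   disequilibrium (LD) block: the interval from the smallest to the
   largest genomic position among its proxy SNPs with linkage
   $r^2 \ge 0.8$.
2. **Histone-mark enrichment.** For each cell type and histone mark
   (H3K27ac, H3K4me1, H3K4me3 ChIP-seq peak sets), the blocks are tested
   for an excess of peak-bearing blocks relative to random genomic
   regions of matched length.
3. **TAD reconstruction.** For a cell type with CTCF HiChIP data, the
   topologically associated domain (TAD) around each block is
   reconstructed by transitive traversal of the chromatin-loop anchor
   graph, followed by a gap-bounded merge of all reached anchors.
4. **Gene lists.** Genes whose bodies overlap the reconstructed domains
   are collected and filtered to those expressed (TPM > 1 in at least
   half of samples); the resulting lists are the input that downstream
   ontology tools consume.

## Coordinate conventions

Internally every span is a 0-based half-open interval `[start, end)`, the
BED convention; `read_bed(dialect = "printed1")` ingests 1-based
fully-closed coordinates as printed in publication tables by shifting the
start down by one. One consequence deserves emphasis: **block lengths are
reported as printed end − printed start**, not as the half-open interval
length (which is one bp larger). The bundled 11-block scleroderma-risk
table reproduces its published mean length of 59,976 bp only under this
convention (the raw mean is 59,976.27, floored to an integral bp count
for use as the random-region length):

```{r}
blocks <- ssc_risk_haplotypes()
mean(block_lengths(blocks))
average_block_length(blocks)
```

Degenerate single-position blocks (no proxy passes the threshold) are
represented with equal printed bounds, still covering one bp as an
interval; they are legitimate — the smallest real block in the bundled
table is only 1,438 bp — but `build_block()` warns when it creates one.

Chromosome names are matched by exact string equality everywhere. A
validation pass (`check_chrom_names()`) warns when two inputs share no
chromosome names but would match after stripping a `chr` prefix; nothing
is ever renamed silently.

## The enrichment statistic and its null

The observed statistic is the **number of query blocks with at least one
overlapping peak** — not the total number of block×peak intersections —
so a block saturated with peaks counts once, the same way a random region
does. Per null replicate, as many random regions as there are blocks are
drawn, each of length `average_block_length(blocks)`; a chromosome is
chosen with probability proportional to its number of valid start
positions and the start is uniform, which makes the draw uniform over the
concatenated valid-start space. Regions may overlap each other and no
assembly gaps or blacklists are excluded by default (the simplest null;
an exclusion list can be emulated by subtracting regions upstream).
A normal distribution is fitted to the replicate counts (sample SD,
denominator $n-1$; 1000 replicates by default) and the p-value is the
fitted normal's upper-tail survival probability at the observed count.
One-sided, because enrichment is a directional hypothesis. Results are
reported per peak set without multiple-testing correction, with a
Benjamini–Hochberg column added by `enrichment_table()` for transparency.

Two numerical edge cases are defined explicitly. When the null counts
have zero spread the fit is degenerate: the p-value is 0 above the null
value, 1 below it, and 0.5 at equality, and the result carries a
`degenerate_null` flag. And because the observed count lives on
$\{0,\dots,n\}$ while the fitted normal is continuous, the test is
slightly anti-conservative: evaluating the survival function at an
integer count, without continuity correction, inflates the type-I error
above its nominal level by roughly half the probability mass of the
boundary count. The calibration results below quantify this (about 0.07
at a nominal 0.05 under the default null scenario); it is a property of
the normal-approximation recipe itself, which the package reproduces
deliberately rather than repairs.

## TAD reconstruction from loop anchors

Loops are read from BEDPE with a read-support count; loops supported by
fewer than two reads are discarded, as are inter-chromosomal loops
(flagged and counted — cis-only domains are the standard interpretation,
and traversal refuses unfiltered input rather than guess). Anchors from
different loops that overlap by at least one bp are treated as a single
graph node: exact-coordinate identity would fragment the graph under the
anchor jitter real loop callers produce, while abutting-but-disjoint
anchors remain distinct. Each loop is an edge between its two anchor
nodes. Traversal seeds at the nodes overlapping the haplotype block and
takes the full connected component — there is no hop limit; termination
is guaranteed by the components being finite. A block overlapping no
anchor is **inactive**: the locus shows no loop engagement in this cell
type and contributes nothing downstream.

All anchors in the reached component are then merged with a maximum gap
of 1 Mb. If reached anchors cluster more than 1 Mb apart this yields
several TAD intervals; all are reported and all feed gene assignment,
rather than picking one by size or proximity. An optional corroboration
step checks that CTCF ChIP-seq peaks flank both boundaries of each
interval (within ±10 kb by default), the classic signature of a real
domain boundary.

Gene assignment is any-overlap of the full gene body with any TAD
interval (half-open: a gene ending exactly where the domain starts is
outside). The expression filter keeps genes with TPM strictly greater
than 1 in at least half of samples — so 2 of 4 samples passes, 1 of 3
fails, and a TPM of exactly 1.0 never counts.

## What the synthetic generator emulates

The three scenario generators produce every input format the pipeline
reads (chrom.sizes, block TSV, peak BED, loop BEDPE, gene BED, TPM TSV)
with planted structure, under a seed, with the caller's RNG state left
untouched:

* `make_null_scenario()` — one homogeneous 200 bp peak process at
  50 peaks/Mb (≈1% coverage) over a 10 Mb two-chromosome genome, with the
  11 query blocks themselves drawn uniformly. Block length is 10 kb: on a
  10 Mb genome this puts the per-block overlap probability near 0.4, the
  informative middle of the range. (Full-scale 60 kb blocks would overlap
  a peak with probability ≈0.95 on a genome this small, pinning the
  observed count at its maximum and making calibration unmeasurable;
  scaling the blocks with the genome, to ≈200 bp, would leave almost no
  counts at all.)
* `make_enriched_scenario(fold)` — the study's scale at reduced genome
  size: 11 blocks of ≈60 kb on a 10 Mb genome, background 5 peaks/Mb,
  plus an extra in-block process at `(fold − 1) ×` background so total
  in-block density is `fold ×` background and `fold = 1` reduces exactly
  to the null construction.
* `make_tad_scenario()` — a chain of 5 anchors (gaps 200–350 kb, all
  under the 1 Mb merge bound) seeded at one block; a support-1 distal
  loop the filter must remove; a disjoint noise component traversal must
  not reach; an inter-chromosomal loop that must be flagged; an inactive
  block; 6 expressed and 4 silent genes planted inside the chain span
  (plus genes outside it); and CTCF-style peaks at every chain anchor so
  the boundaries corroborate.

TPM draws use a log-normal centred near 10 TPM (`sdlog` 0.5) for
expressed genes and Uniform(0, 0.8] for silent genes, so silent mass sits
entirely at or below the threshold.

What the generators do **not** emulate: peak width/signal heterogeneity,
GC and mappability structure, assembly gaps, correlated peak placement
across marks, loop-anchor width variation, or read-level HiChIP data.
Passing tests therefore demonstrate the correctness and calibration of
the procedure under its own assumptions, not robustness to those
real-data features — in particular, the random-region null inherits the
published recipe's simplicity (no GC/length-matched or SNP-matched
controls).

## Numerical and design choices

* Sampling replicate regions is vectorized: all `n_reps × n` regions are
  drawn at once and intersected in a single overlap query, then counted
  per replicate.
* Every stochastic operation takes an explicit seed and is
  bit-reproducible given it; scenario files regenerated under the same
  seed are byte-identical, and the full pipeline run twice on the same
  inputs writes byte-identical outputs.
* The test suite and the acceptance script run the resampling studies at
  a reduced problem size — a 10 Mb genome with 200 replicates per test,
  500 null runs for calibration and 100 enriched runs for power — sizes
  at which the Monte-Carlo standard error of the calibration estimate is
  below 0.01 while the whole study completes in well under a minute.
* Ties and degenerate inputs: zero-spread nulls (see above); empty peak
  sets give observed = 0 with a degenerate null; a block table of one row
  is valid; merging an empty interval set returns an empty set.

## Known limitations

* The enrichment p-value inherits the normal-approximation recipe's mild
  anti-conservatism at small block counts (n = 11); an exact empirical
  rank p-value would be calibrated but would not be the published
  procedure.
* Published gene counts downstream of the domain step depend on the
  specific HiChIP, Hi-C, annotation and RNA-seq inputs of the original
  study and are not desk-reproducible; the package reproduces the
  procedure and emits the gene lists, not those counts.
* No liftover between assemblies is provided; all inputs are assumed to
  share one coordinate system, and `check_chrom_names()` only catches
  naming-convention mismatches, not assembly mismatches.
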