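# regulhap

Regulatory annotation of disease-risk haplotypes: histone-mark enrichment
testing and chromatin-loop TAD reconstruction.

## What it does, and for whom

Replicated GWAS index SNPs usually sit in non-coding sequence, where risk
is thought to act through regulatory elements in particular cell types.
`regulhap` is for genetic epidemiologists and functional genomicists who
want to interrogate a panel of replicated risk loci against public
epigenomic data. It implements the full desk workflow:

1. **LD blocks** — each index SNP is expanded to its haplotype block,
   the `[min, max]` span of its proxy-SNP positions at linkage
   r² ≥ 0.8.
2. **Histone-mark enrichment** — for each cell type × mark peak set
   (H3K27ac, H3K4me1, H3K4me3 ChIP-seq), the observed number of
   peak-bearing blocks is compared with a resampling null: per
   replicate, *n* random regions of length equal to the average block
   length (59,976 bp for the bundled scleroderma panel) are drawn
   genome-wide and their peak-overlap count recorded; a normal
   distribution N(μ̂, σ̂) fitted to 1000 replicate counts gives the
   one-sided upper-tail p-value
   `p = 1 − Φ((obs − μ̂)/σ̂)`, significant at p < 0.01. A Y/−
   presence/absence matrix of marks per block is emitted alongside.
3. **TAD reconstruction** — CTCF HiChIP loops (BEDPE, ≥ 2 supporting
   reads, cis only) define an anchor graph; anchors overlapping a block
   seed a transitive traversal, and all reached anchors are merged with
   a maximum gap of 1 Mb to give the locus's topologically associated
   domain. Blocks containing no loop anchor are reported inactive.
   Optionally, CTCF ChIP-seq peaks corroborate both domain boundaries.
4. **Gene lists** — genes whose bodies overlap the domain intervals are
   collected and filtered to expressed genes (TPM > 1 in at least half
   of samples), producing the plain-text lists downstream ontology tools
   consume.

A seeded synthetic-data generator emulates every input format
(chrom.sizes, block TSV, peak BED, loop BEDPE, gene BED, TPM TSV) with
planted structure, so the whole pipeline is testable offline.

## Worked example

```r
library(regulhap)

blocks <- ssc_risk_haplotypes()        # the bundled 11-block risk panel
block_lengths(blocks)
#>  [1]  65075 126258   1438  18416  21210  35355  68661 157479  71848  70084
#> [11]  23915
average_block_length(blocks)
#> [1] 59976
```

The average, 59,976 bp, is the fixed length used for the null's random
regions (lengths follow the printed end − start convention; see the
methods vignette). On a synthetic genome with peaks planted in every
block at 50× background density, the enrichment test finds the excess:

```r
sc <- make_enriched_scenario(seed = 42, fold = 50)
empirical_enrichment(sc$blocks, sc$peaks, sc$genome, n_reps = 1000, seed = 42)
#> Empirical peak enrichment (synthetic mark)
#>   observed: 11 of 11 blocks with >= 1 peak
#>   null: mean 4.072, sd 1.650 (1000 replicates of 11 regions, 59999 bp)
#>   one-sided p = 1.346e-05 -> significant at alpha = 0.01
```

All 11 blocks carry a peak, against ≈4.1 ± 1.7 expected for random
regions of the same length: strong enrichment. On a planted loop-chain
scenario, TAD reconstruction recovers exactly the planted domain and its
expressed genes:

```r
sct <- make_tad_scenario(seed = 42)
tads <- locus_tads(sct$blocks, sct$loops)   # filter, traverse, merge
tads$blockSeed
#> Locus TAD for blockSeed (chrS1:1995001-2055000)
#>   anchors reached: 5
#>   TAD interval: chrS1:2050000-3320268 (1270268 bp)
g <- genes_in_tads(tads, sct$genes)
expressed_genes(g$pooled, sct$tpm)
#> [1] "geneT01" "geneT02" "geneT03" "geneT04" "geneT05" "geneT06"
```

The domain spans the planted chain's outermost anchors; the six planted
expressed genes (and none of the silent ones) survive the TPM filter.
`run_pipeline(input_dir, out_dir)` runs all stages on a directory of
input files and writes the result tables; a command-line wrapper with
`simulate` / `enrich` / `tads` / `pipeline` subcommands is installed at
`inst/scripts/regulhap.R`.

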