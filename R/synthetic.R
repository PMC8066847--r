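#' @name synthetic-scenarios
#' @title Seeded synthetic scenarios with planted structure
#'
#' @description
#' The generators emulate every input the pipeline consumes — genome
#' layout, haplotype blocks, histone-mark peak BEDs, HiChIP loop BEDPEs,
#' gene annotation, and TPM matrices — with planted, known structure, so
#' each stage can be validated without external data. All draws happen
#' under the given seed and leave the caller's RNG state untouched;
#' regenerating with the same seed reproduces the scenario (and its
#' written files) bit-for-bit.
#'
#' Three stereotyped scenarios are provided:
#' \itemize{
#'   \item [make_null_scenario()]: peak density identical inside and
#'     outside the blocks and query blocks themselves drawn uniformly —
#'     the ground truth for type-I-error calibration of
#'     [empirical_enrichment()].
#'   \item [make_enriched_scenario()]: in-block peak density a chosen fold
#'     above background — the ground truth for power.
#'   \item [make_tad_scenario()]: a planted loop chain seeded at one
#'     block, plus a disjoint noise component, sub-threshold loops, an
#'     inactive block, and expressed/silent genes inside the chain span —
#'     the ground truth for TAD traversal, merging, and the expression
#'     filter.
#' }
NULL

# Homogeneous peak placement: background process genome-wide plus an extra
# in-block process, both Poisson in count, uniform in position.
sim_peaks <- function(genome, background_per_mb, peak_length,
                      blocks = NULL, extra_per_mb = 0) {
  place <- function(chrom, lo, hi, density_per_mb) {
    span <- hi - lo - peak_length
    if (span <= 0) return(NULL)
    n <- stats::rpois(1L, density_per_mb * (hi - lo) / 1e6)
    if (n == 0L) return(NULL)
    start <- lo + floor(stats::runif(n) * span)
    data.frame(chrom = chrom, start = start, end = start + peak_length,
               stringsAsFactors = FALSE)
  }
  bg <- lapply(names(genome), function(ch)
    place(ch, 0, genome[[ch]], background_per_mb))
  extra <- if (!is.null(blocks) && extra_per_mb > 0)
    lapply(seq_len(nrow(blocks)), function(i)
      place(blocks$chrom[i], blocks$start[i], blocks$end[i], extra_per_mb))
  else list()
  out <- do.call(rbind, c(bg, extra))
  if (is.null(out)) out <- genomic_intervals()
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# Blocks drawn uniformly from the genome, labelled block01..blockNN.
sim_blocks <- function(genome, n_blocks, block_length) {
  pos <- sample_random_regions(genome, block_length, n_blocks)
  haplotype_blocks(sprintf("block%02d", seq_len(n_blocks)), pos$chrom,
                   pos$start + 1, pos$end,
                   locus_name = sprintf("locus%02d", seq_len(n_blocks)))
}

# TPM matrix for planted genes: expressed genes draw from a log-normal
# centred near 10 TPM, silent genes uniform on (0, 0.8] — mass entirely at
# or below the TPM > 1 threshold.
sim_tpm <- function(gene_ids, expressed, n_samples) {
  m <- matrix(0, nrow = length(gene_ids), ncol = n_samples,
              dimnames = list(gene_ids, sprintf("sample%02d",
                                                seq_len(n_samples))))
  for (i in seq_along(gene_ids)) {
    m[i, ] <- if (expressed[i])
      stats::rlnorm(n_samples, meanlog = log(10), sdlog = 0.5)
    else stats::runif(n_samples, 0, 0.8)
  }
  m
}

new_scenario <- function(kind, seed, genome, blocks, peaks, loops, genes,
                         tpm, truth, params) {
  structure(list(kind = kind, seed = seed, genome = genome,
                 blocks = blocks, peaks = peaks, loops = loops,
                 genes = genes, tpm = tpm, truth = truth, params = params),
            class = "regulhap_scenario")
}

#' @export
print.regulhap_scenario <- function(x, ...) {
  cat("Synthetic scenario '", x$kind, "' (seed ", x$seed, ")\n", sep = "")
  cat("  genome:", length(x$genome), "chromosome(s),",
      format_bp(sum(x$genome)), "bp\n")
  cat("  blocks:", nrow(x$blocks), " peaks:", nrow(x$peaks$peaks),
      " loops:", nrow(x$loops), " genes:", nrow(x$genes), "\n")
  invisible(x)
}

#' Null scenario: no enrichment anywhere
#'
#' Peak density is identical inside and outside the blocks (a single
#' homogeneous process), and the query blocks are themselves drawn
#' uniformly from the genome, so the observed overlap count is a draw from
#' the same distribution as the resampling null. Defaults: a 10 Mb
#' two-chromosome genome, 11 blocks of 10 kb, and 200 bp peaks at
#' 50 peaks/Mb (about 1% genome coverage). The 10 kb block length puts the
#' per-block overlap probability near 0.4, the informative middle of the
#' calibration range; see the methods vignette.
#'
#' @param seed Integer seed.
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_blocks Number of query blocks.
#' @param block_length Block length in bp.
#' @param peak_density Peaks per Mb (background and in-block alike).
#' @param peak_length Peak length in bp.
#' @param n_samples Samples in the accompanying TPM matrix.
#' @return A \code{regulhap_scenario}.
#' @export
make_null_scenario <- function(seed, genome = c(chrS1 = 6e6, chrS2 = 4e6),
                               n_blocks = 11, block_length = 1e4,
                               peak_density = 50, peak_length = 200,
                               n_samples = 8) {
  make_enriched_scenario(seed, fold = 1, genome = genome,
                         n_blocks = n_blocks, block_length = block_length,
                         background_density = peak_density,
                         peak_length = peak_length, n_samples = n_samples,
                         kind = "null")
}

#' Enriched scenario: in-block peak density a fold above background
#'
#' The background peak process covers the whole genome; an extra in-block
#' process at \code{(fold - 1) * background_density} raises the total
#' in-block density to \code{fold} times background. \code{fold = 1}
#' reduces exactly to the null construction. Defaults mirror the real
#' study's scale at reduced genome size: 11 blocks of about 60 kb on a
#' 10 Mb genome with a sparse background (5 peaks/Mb).
#'
#' @param seed Integer seed.
#' @param fold In-block density fold over background (>= 1; default 50).
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_blocks Number of query blocks.
#' @param block_length Block length in bp.
#' @param background_density Background peaks per Mb.
#' @param peak_length Peak length in bp.
#' @param n_samples Samples in the accompanying TPM matrix.
#' @param kind Internal scenario label.
#' @return A \code{regulhap_scenario}.
#' @export
make_enriched_scenario <- function(seed, fold = 50,
                                   genome = c(chrS1 = 1e7),
                                   n_blocks = 11, block_length = 6e4,
                                   background_density = 5,
                                   peak_length = 200, n_samples = 8,
                                   kind = "enriched") {
  stopifnot(fold >= 1)
  with_seed(seed, {
    blocks <- sim_blocks(genome, n_blocks, block_length)
    peaks <- sim_peaks(genome, background_density, peak_length,
                       blocks = blocks,
                       extra_per_mb = (fold - 1) * background_density)
    pset <- peak_set("synthetic", "mark", peaks)
    # a token annotation/expression pair so every input format is present
    genes <- data.frame(gene_id = c("geneE1", "geneS1"),
                        gene_name = c("geneE1", "geneS1"),
                        chrom = names(genome)[1L],
                        start = c(1e5, 2e5), end = c(1.2e5, 2.2e5),
                        stringsAsFactors = FALSE)
    tpm <- sim_tpm(genes$gene_id, c(TRUE, FALSE), n_samples)
    truth <- list(fold = fold, n_blocks = n_blocks,
                  block_length = block_length,
                  background_density = background_density,
                  expressed_genes = "geneE1")
    new_scenario(kind, seed, genome, blocks, pset, empty_loops(), genes,
                 tpm, truth,
                 params = list(fold = fold,
                               background_density = background_density,
                               peak_length = peak_length))
  })
}

#' TAD scenario: a planted loop chain with noise
#'
#' Plants, on a 10 Mb + 5 Mb genome:
#' \itemize{
#'   \item a seed block whose first anchor starts a chain of \code{K}
#'     anchors with inter-anchor gaps well under 1 Mb, connected by loops
#'     of read support >= 2 — the reconstructed TAD must span exactly the
#'     chain's outermost anchors;
#'   \item a support-1 loop from the chain's last anchor to a distal
#'     anchor, which the support filter must remove;
#'   \item a disjoint noise component of loops far from the chain, which
#'     traversal must not reach;
#'   \item inter-chromosomal noise loops, which are flagged and excluded;
#'   \item an inactive block overlapping no anchor;
#'   \item expressed and silent genes inside the chain span (plus genes
#'     outside it), with a TPM matrix matching their planted status;
#'   \item CTCF-style peaks at every chain anchor, so the reconstructed
#'     boundaries corroborate.
#' }
#'
#' @param seed Integer seed.
#' @param K Number of chain anchors (default 5).
#' @param n_noise_loops Loops in the disjoint noise component (default 20).
#' @param n_expressed,n_silent Planted genes inside the chain span
#'   (defaults 6 and 4).
#' @param n_samples Samples in the TPM matrix (default 8).
#' @return A \code{regulhap_scenario} whose \code{truth} element records
#'   the planted chain span, anchors, block activity, and gene status.
#' @export
make_tad_scenario <- function(seed, K = 5, n_noise_loops = 20,
                              n_expressed = 6, n_silent = 4,
                              n_samples = 8) {
  stopifnot(K >= 2)
  genome <- c(chrS1 = 1e7, chrS2 = 5e6)
  with_seed(seed, {
    anchor_len <- 5e3
    # chain anchors: first at ~2.05 Mb, gaps jittered in [200, 350] kb
    gaps <- floor(stats::runif(K - 1L, 2e5, 3.5e5))
    a_start <- 2.05e6 + c(0, cumsum(gaps + anchor_len))
    chain <- data.frame(chrom = "chrS1", start = a_start,
                        end = a_start + anchor_len,
                        stringsAsFactors = FALSE)
    mkloop <- function(a, b, support) {
      data.frame(chromA = a$chrom, startA = a$start, endA = a$end,
                 chromB = b$chrom, startB = b$start, endB = b$end,
                 support = support,
                 inter_chromosomal = a$chrom != b$chrom,
                 stringsAsFactors = FALSE)
    }
    chain_loops <- do.call(rbind, lapply(seq_len(K - 1L), function(i)
      mkloop(chain[i, ], chain[i + 1L, ],
             support = sample(2:6, 1L))))
    # support-1 distal loop: must be removed by the read-support filter
    distal <- data.frame(chrom = "chrS1", start = 4.6e6, end = 4.6e6 + anchor_len)
    weak_loop <- mkloop(chain[K, ], distal, support = 1)
    # disjoint noise component at 6.5-9.8 Mb
    ns <- 6.5e6 + floor(stats::runif(2L * n_noise_loops, 0, 3.2e6))
    noise_loops <- do.call(rbind, lapply(seq_len(n_noise_loops), function(i)
      mkloop(data.frame(chrom = "chrS1", start = ns[2 * i - 1],
                        end = ns[2 * i - 1] + anchor_len),
             data.frame(chrom = "chrS1", start = ns[2 * i],
                        end = ns[2 * i] + anchor_len),
             support = sample(2:5, 1L))))
    # inter-chromosomal noise
    trans_loop <- mkloop(data.frame(chrom = "chrS1", start = 1e6,
                                    end = 1e6 + anchor_len),
                         data.frame(chrom = "chrS2", start = 1e6,
                                    end = 1e6 + anchor_len), support = 4)
    loops <- rbind(chain_loops, weak_loop, noise_loops, trans_loop)
    row.names(loops) <- NULL
    # seed block overlaps the first chain anchor; inactive block touches
    # no anchor (between the weak-loop distal anchor and noise component)
    blocks <- haplotype_blocks(
      c("blockSeed", "blockInactive"), "chrS1",
      printed_start = c(chain$start[1L] - 5.5e4 + 1, 5.5e6 + 1),
      printed_end = c(chain$start[1L] + 5e3, 5.56e6),
      locus_name = c("plantedTAD", "silentLocus"))
    chain_span <- c(chain$start[1L], chain$end[K])
    # genes: inside the chain span (expressed + silent), and outside
    gene_len <- 2e4
    n_in <- n_expressed + n_silent
    g_in_start <- floor(seq(chain_span[1L] + 1e4,
                            chain_span[2L] - gene_len - 1e4,
                            length.out = n_in))
    g_out_start <- c(5.8e6, 6.0e6, 9.85e6)
    genes <- data.frame(
      gene_id = c(sprintf("geneT%02d", seq_len(n_in)),
                  sprintf("geneO%02d", seq_along(g_out_start))),
      chrom = "chrS1",
      start = c(g_in_start, g_out_start),
      stringsAsFactors = FALSE)
    genes$end <- genes$start + gene_len
    genes$gene_name <- genes$gene_id
    genes <- genes[, c("gene_id", "gene_name", "chrom", "start", "end")]
    expressed <- c(rep(c(TRUE, FALSE), c(n_expressed, n_silent)),
                   c(TRUE, FALSE, TRUE)[seq_along(g_out_start)])
    tpm <- sim_tpm(genes$gene_id, expressed, n_samples)
    # CTCF-style peaks at every chain anchor midpoint
    ctcf <- data.frame(chrom = chain$chrom,
                       start = (chain$start + chain$end) / 2 - 250,
                       end = (chain$start + chain$end) / 2 + 250,
                       stringsAsFactors = FALSE)
    pset <- peak_set("CD4_T", "CTCF", ctcf)
    truth <- list(
      seed_block = "blockSeed", inactive_block = "blockInactive",
      chain_span = chain_span, n_chain_anchors = K,
      chain_anchors = chain, n_noise_loops = n_noise_loops,
      expressed_in_tad = genes$gene_id[seq_len(n_expressed)],
      silent_in_tad = genes$gene_id[n_expressed + seq_len(n_silent)],
      genes_outside = genes$gene_id[n_in + seq_along(g_out_start)])
    new_scenario("tads", seed, genome, blocks, pset, loops, genes, tpm,
                 truth, params = list(K = K, anchor_len = anchor_len,
                                      n_noise_loops = n_noise_loops))
  })
}

#' Write a scenario's input files
#'
#' Emits, under \code{dir}: \code{chrom.sizes}, \code{blocks.tsv},
#' \code{peaks.bed}, \code{loops.bedpe}, \code{genes.bed},
#' \code{tpm.tsv}, and \code{truth.json} (the planted ground truth, for
#' tests). File contents are a pure function of the scenario object, so a
#' scenario regenerated under the same seed writes byte-identical files.
#'
#' @param scenario A \code{regulhap_scenario}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "regulhap_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_chrom_sizes(scenario$genome, p("chrom.sizes"))
  write_haplotype_blocks(scenario$blocks, p("blocks.tsv"))
  write_bed(scenario$peaks$peaks, p("peaks.bed"))
  write_bedpe(scenario$loops, p("loops.bedpe"))
  write_genes(scenario$genes, p("genes.bed"))
  write_tpm_matrix(scenario$tpm, p("tpm.tsv"))
  jsonlite::write_json(scenario$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(stats::setNames(
    p(c("chrom.sizes", "blocks.tsv", "peaks.bed", "loops.bedpe",
        "genes.bed", "tpm.tsv", "truth.json")),
    c("chrom_sizes", "blocks", "peaks", "loops", "genes", "tpm", "truth")))
}
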