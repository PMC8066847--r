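#' Run the full haplotype-to-regulome pipeline on a directory of inputs
#'
#' Reads the standard input bundle (\code{chrom.sizes}, \code{blocks.tsv},
#' \code{peaks.bed}, \code{loops.bedpe}, \code{genes.bed}, \code{tpm.tsv};
#' the layout [write_scenario()] emits and the formats the module readers
#' define), then runs every stage: peak enrichment of the blocks with the
#' random-region null, the presence/absence matrix, loop filtering and TAD
#' reconstruction per block, gene assignment to the TAD intervals, and the
#' expression filter. Results are written to \code{out_dir} as plain-text
#' tables. Given a seed, two runs on the same inputs produce byte-identical
#' outputs.
#'
#' @param input_dir Directory holding the input bundle.
#' @param out_dir Output directory (created if absent).
#' @param peak_label Two-element character vector (cell type, mark) used to
#'   label the peak set.
#' @param n_reps Enrichment resampling replicates (default 1000).
#' @param alpha Significance level on the raw enrichment p-value.
#' @param seed Integer seed for the resampling null.
#' @param min_support Minimum loop read support (default 2).
#' @param max_gap TAD anchor-merge gap bound in bp (default 1e6).
#' @param tpm_threshold,min_fraction Expression-filter parameters
#'   (defaults: TPM > 1 in at least half of samples).
#' @return Invisibly, a list with elements \code{enrichment},
#'   \code{presence}, \code{tads}, \code{genes}, \code{expressed}, and
#'   \code{files} (paths written).
#' @export
run_pipeline <- function(input_dir, out_dir,
                         peak_label = c("peaks", "mark"),
                         n_reps = 1000, alpha = 0.01, seed = NULL,
                         min_support = 2, max_gap = 1e6,
                         tpm_threshold = 1, min_fraction = 0.5) {
  p <- function(f) file.path(input_dir, f)
  genome <- read_chrom_sizes(p("chrom.sizes"))
  blocks <- read_haplotype_blocks(p("blocks.tsv"))
  peaks <- peak_set(peak_label[1L], peak_label[2L], read_bed(p("peaks.bed")))
  loops <- read_bedpe(p("loops.bedpe"))
  genes <- read_genes(p("genes.bed"))
  tpm <- read_tpm_matrix(p("tpm.tsv"))
  check_chrom_names(blocks = blocks, peaks = peaks$peaks, genes = genes)

  enr <- empirical_enrichment(blocks, peaks, genome, n_reps = n_reps,
                              alpha = alpha, seed = seed)
  pres <- presence_matrix(blocks, list(peaks))
  tads <- locus_tads(blocks, loops, min_support = min_support,
                     max_gap = max_gap)
  gsets <- genes_in_tads(tads, genes)
  expressed <- expressed_genes(gsets$pooled, tpm,
                               tpm_threshold = tpm_threshold,
                               min_fraction = min_fraction)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(out_dir, f)
  enr_df <- as.data.frame(enr)
  utils::write.table(enr_df, o("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_presence_matrix(pres, o("presence.tsv"))
  tt <- tad_table(tads)
  tt$tad_start <- format_bp(tt$tad_start)
  tt$tad_end <- format_bp(tt$tad_end)
  utils::write.table(tt, o("tads.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ti <- do.call(rbind, lapply(tads, function(t) t$tad_intervals))
  write_bed(ti, o("tad_intervals.bed"))
  write_gene_list(gsets$pooled, o("genes_in_tads.txt"))
  write_gene_list(expressed, o("expressed_genes.txt"))

  invisible(list(enrichment = enr, presence = pres, tads = tads,
                 genes = gsets, expressed = expressed,
                 files = o(c("enrichment.tsv", "presence.tsv", "tads.tsv",
                             "tad_intervals.bed", "genes_in_tads.txt",
                             "expressed_genes.txt"))))
}

#' Type-I-error calibration of the enrichment test
#'
#' Runs [empirical_enrichment()] on independently generated null scenarios
#' (see [make_null_scenario()]) and reports the fraction of p-values below
#' \code{alpha}. Under a calibrated test this fraction matches
#' \code{alpha} up to Monte-Carlo error.
#'
#' @param n_runs Number of independent null scenarios (default 500).
#' @param n_reps Resampling replicates per run (default 200).
#' @param alpha Nominal level being checked (default 0.05).
#' @param seed Integer base seed; run \code{i} uses \code{seed + i}.
#' @param ... Passed to [make_null_scenario()].
#' @return List with \code{rate}, \code{p_values}, \code{n_runs},
#'   \code{alpha}.
#' @export
calibrate_enrichment <- function(n_runs = 500, n_reps = 200, alpha = 0.05,
                                 seed = 1, ...) {
  pv <- vapply(seq_len(n_runs), function(i) {
    sc <- make_null_scenario(seed + i, ...)
    empirical_enrichment(sc$blocks, sc$peaks, sc$genome, n_reps = n_reps,
                         alpha = alpha, seed = seed + i)$p_value
  }, 0)
  list(rate = mean(pv < alpha), p_values = pv, n_runs = n_runs,
       alpha = alpha)
}

#' Power of the enrichment test on enriched scenarios
#'
#' Runs [empirical_enrichment()] on independently generated enriched
#' scenarios (see [make_enriched_scenario()]) and reports the fraction of
#' runs with p-value below \code{alpha}.
#'
#' @param n_runs Number of independent scenarios (default 100).
#' @param fold In-block density fold over background (default 50).
#' @param n_reps Resampling replicates per run (default 200).
#' @param alpha Significance level (default 0.01).
#' @param seed Integer base seed; run \code{i} uses \code{seed + i}.
#' @param ... Passed to [make_enriched_scenario()].
#' @return List with \code{power}, \code{p_values}, \code{n_runs},
#'   \code{alpha}.
#' @export
enrichment_power <- function(n_runs = 100, fold = 50, n_reps = 200,
                             alpha = 0.01, seed = 1, ...) {
  pv <- vapply(seq_len(n_runs), function(i) {
    sc <- make_enriched_scenario(seed + i, fold = fold, ...)
    empirical_enrichment(sc$blocks, sc$peaks, sc$genome, n_reps = n_reps,
                         alpha = alpha, seed = seed + i)$p_value
  }, 0)
  list(power = mean(pv < alpha), p_values = pv, n_runs = n_runs,
       alpha = alpha)
}
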