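#' Bundle peaks with their cell type and histone mark
#'
#' @param cell_type Cell-type label (e.g. \code{"Monocyte"}).
#' @param mark Histone-mark label (e.g. \code{"H3K27ac"}).
#' @param peaks Interval data.frame of peaks; sorted per chromosome on
#'   construction.
#' @return A \code{peak_set} object.
#' @export
peak_set <- function(cell_type, mark, peaks) {
  validate_intervals(peaks, where = "peaks")
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  row.names(peaks) <- NULL
  structure(list(cell_type = cell_type, mark = mark, peaks = peaks),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("Peak set:", x$cell_type, x$mark, "-", nrow(x$peaks), "peaks\n")
  invisible(x)
}

peaks_of <- function(x) if (inherits(x, "peak_set")) x$peaks else x

#' Count regions overlapped by a peak set
#'
#' The enrichment statistic: the number of query regions having at least
#' one bp of overlap with at least one peak. Each region counts at most
#' once however many peaks it touches.
#'
#' @param regions Interval data.frame (query regions or haplotype blocks).
#' @param peaks A \code{peak_set} or plain interval data.frame.
#' @return Integer count in \code{[0, nrow(regions)]}.
#' @export
count_overlapping_regions <- function(regions, peaks) {
  peaks <- peaks_of(peaks)
  if (nrow(regions) == 0L || nrow(peaks) == 0L) return(0L)
  hits <- GenomicRanges::findOverlaps(as_granges(regions), as_granges(peaks))
  length(unique(S4Vectors::queryHits(hits)))
}

#' Which regions does a peak set overlap?
#'
#' @inheritParams count_overlapping_regions
#' @return Logical vector, one element per region.
#' @export
region_has_peak <- function(regions, peaks) {
  peaks <- peaks_of(peaks)
  out <- logical(nrow(regions))
  if (nrow(regions) == 0L || nrow(peaks) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges(regions), as_granges(peaks))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Sample fixed-length random regions from a genome
#'
#' Draws \code{n} regions of exactly \code{region_length} bp, each fully
#' inside one chromosome. A chromosome is chosen with probability
#' proportional to its number of valid start positions
#' (\code{length - region_length + 1}), which makes the draw uniform over
#' the concatenated valid-start space; the start is then uniform over valid
#' starts. Regions may overlap one another and nothing is masked.
#'
#' @param genome Named numeric vector of chromosome lengths
#'   (see [read_chrom_sizes()]).
#' @param region_length Region length in bp.
#' @param n Number of regions.
#' @param seed Optional integer; when given, the draw is made under this
#'   seed and the caller's RNG state is left untouched.
#' @return Interval data.frame of \code{n} rows.
#' @export
sample_random_regions <- function(genome, region_length, n, seed = NULL) {
  stopifnot(n >= 1, region_length >= 1)
  with_seed(seed, {
    valid <- genome - region_length + 1
    valid <- valid[valid >= 1]
    if (length(valid) == 0L)
      stop("no chromosome can host a region of ", region_length, " bp")
    chrom <- if (length(valid) == 1L) rep(names(valid), n)
             else sample(names(valid), n, replace = TRUE,
                         prob = valid / sum(valid))
    start <- floor(stats::runif(n) * valid[chrom])
    data.frame(chrom = chrom, start = start, end = start + region_length,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

# Evaluate expr; when seed is non-NULL, run it under set.seed(seed) and
# restore the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Empirical enrichment of haplotype blocks for a peak set
#'
#' Tests whether more blocks carry a peak than expected for random genomic
#' regions of the same length. Per replicate, as many random regions as
#' there are blocks are drawn, each of length
#' \code{average_block_length(blocks)}, and the number of regions with at
#' least one overlapping peak is recorded. A normal distribution is fitted
#' to the replicate counts (sample SD, denominator n-1) and the p-value is
#' the upper-tail survival probability of that normal at the observed count
#' for the real blocks — one-sided, since enrichment is a directional
#' hypothesis.
#'
#' If the null counts have zero spread the normal fit is degenerate; the
#' p-value is then 0 when the observation exceeds the null value, 1 when it
#' falls below, and 0.5 at equality, and the result is flagged.
#'
#' @param blocks Haplotype-block data.frame (see [build_block()]).
#' @param peaks A \code{peak_set} or interval data.frame.
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_reps Number of resampling replicates (default 1000).
#' @param alpha Significance level on the raw p-value (default 0.01).
#' @param seed Optional integer seed; the whole result is reproducible
#'   bit-for-bit given the seed.
#' @param region_length Length of the random regions; defaults to
#'   [average_block_length()] of the blocks.
#' @return An \code{enrichment_result}: list with \code{cell_type},
#'   \code{mark}, \code{observed}, \code{n_regions}, \code{n_reps},
#'   \code{null_mean}, \code{null_sd}, \code{p_value}, \code{significant},
#'   \code{degenerate_null}, \code{alpha}, \code{region_length},
#'   \code{null_counts}.
#' @examples
#' genome <- c(chr1 = 1e6)
#' blocks <- haplotype_blocks(c("rsA", "rsB"), "chr1",
#'                            c(1001, 500001), c(6000, 505000))
#' peaks <- genomic_intervals("chr1", c(2000, 900000), c(2200, 900200))
#' empirical_enrichment(blocks, peaks, genome, n_reps = 100, seed = 1)
#' @export
empirical_enrichment <- function(blocks, peaks, genome, n_reps = 1000,
                                 alpha = 0.01, seed = NULL,
                                 region_length = NULL) {
  stopifnot(nrow(blocks) > 0L, n_reps >= 2)
  pk <- peaks_of(peaks)
  if (is.null(region_length)) region_length <- average_block_length(blocks)
  region_length <- max(1, region_length)
  n <- nrow(blocks)
  observed <- count_overlapping_regions(blocks, pk)
  null_counts <- with_seed(seed, {
    draws <- sample_random_regions(genome, region_length, n * n_reps)
    hit <- region_has_peak(draws, pk)
    as.integer(rowsum(as.integer(hit),
                      group = rep(seq_len(n_reps), each = n)))
  })
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  degenerate <- null_sd == 0
  p_value <- if (degenerate) {
    if (observed > null_mean) 0 else if (observed < null_mean) 1 else 0.5
  } else {
    stats::pnorm(observed, mean = null_mean, sd = null_sd,
                 lower.tail = FALSE)
  }
  structure(list(
    cell_type = if (inherits(peaks, "peak_set")) peaks$cell_type else NA,
    mark = if (inherits(peaks, "peak_set")) peaks$mark else NA,
    observed = observed, n_regions = n, n_reps = n_reps,
    null_mean = null_mean, null_sd = null_sd, p_value = p_value,
    significant = p_value < alpha, degenerate_null = degenerate,
    alpha = alpha, region_length = region_length,
    null_counts = null_counts), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$cell_type, x$mark)), collapse = " ")
  cat("Empirical peak enrichment", if (nzchar(lab)) paste0("(", lab, ")"),
      "\n")
  cat(sprintf("  observed: %d of %d blocks with >= 1 peak\n",
              x$observed, x$n_regions))
  cat(sprintf("  null: mean %.3f, sd %.3f (%d replicates of %d regions, %s bp)\n",
              x$null_mean, x$null_sd, x$n_reps, x$n_regions,
              format_bp(x$region_length)))
  cat(sprintf("  one-sided p = %.4g%s -> %s at alpha = %g\n", x$p_value,
              if (x$degenerate_null) " [degenerate null]" else "",
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(cell_type = as.character(x$cell_type),
             mark = as.character(x$mark), observed = x$observed,
             n_regions = x$n_regions, n_reps = x$n_reps,
             null_mean = x$null_mean, null_sd = x$null_sd,
             p_value = x$p_value, significant = x$significant,
             degenerate_null = x$degenerate_null,
             stringsAsFactors = FALSE)
}

#' Enrichment across several peak sets
#'
#' Runs [empirical_enrichment()] for each peak set and tabulates the
#' results. Significance is called on the raw p-value at \code{alpha}
#' (per-test, uncorrected); a Benjamini-Hochberg adjusted column
#' \code{p_adj_BH} is added for transparency but does not drive the flag.
#'
#' @param blocks Haplotype-block data.frame.
#' @param peak_sets List of \code{peak_set} objects.
#' @param genome Named numeric vector of chromosome lengths.
#' @param seed Optional integer seed; set \code{i} uses \code{seed + i - 1}.
#' @inheritParams empirical_enrichment
#' @return A data.frame, one row per peak set.
#' @export
enrichment_table <- function(blocks, peak_sets, genome, n_reps = 1000,
                             alpha = 0.01, seed = NULL) {
  rows <- lapply(seq_along(peak_sets), function(i)
    as.data.frame(empirical_enrichment(
      blocks, peak_sets[[i]], genome, n_reps = n_reps, alpha = alpha,
      seed = if (is.null(seed)) NULL else seed + i - 1)))
  out <- do.call(rbind, rows)
  out$p_adj_BH <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Presence/absence of peak sets in each block
#'
#' The published-table-style matrix: one row per haplotype block, one
#' column per (cell type, mark) peak set, \code{"Y"} when at least one
#' peak of that set overlaps the block and \code{"-"} otherwise.
#'
#' @param blocks Haplotype-block data.frame.
#' @param peak_sets List of \code{peak_set} objects.
#' @return Character matrix of \code{"Y"}/\code{"-"} with class
#'   \code{presence_matrix}; block spans and SNP ids as row names,
#'   \code{cell_type.mark} as column names.
#' @export
presence_matrix <- function(blocks, peak_sets) {
  cols <- vapply(peak_sets, function(s)
    paste(s$cell_type, s$mark, sep = "."), "")
  m <- vapply(peak_sets, function(s)
    ifelse(region_has_peak(blocks, s), "Y", "-"),
    character(nrow(blocks)))
  m <- matrix(m, nrow = nrow(blocks),
              dimnames = list(paste(blocks$chrom, blocks$snp_id), cols))
  structure(m, class = c("presence_matrix", class(m)))
}

#' @export
print.presence_matrix <- function(x, ...) {
  print(unclass(x), quote = FALSE)
  invisible(x)
}

#' Write a presence matrix as TSV
#'
#' @param m A \code{presence_matrix}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_presence_matrix <- function(m, path) {
  out <- data.frame(block = rownames(m), unclass(m), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
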