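#' Read a proxy-SNP table
#'
#' The table emulates the output of an LD proxy search around index SNPs
#' (all variants with linkage r-squared above a threshold against the index
#' variant). Required columns: \code{index_snp}, \code{chrom},
#' \code{position} (1-based bp), \code{r2}.
#'
#' @param path Tab-separated file with a header row.
#' @return A \code{data.frame} with the four columns above.
#' @export
read_proxy_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("index_snp", "chrom", "position", "r2")
  if (!all(need %in% names(x)))
    stop(path, ": proxy table must have columns ",
         paste(need, collapse = ", "))
  if (any(x$r2 < 0 | x$r2 > 1))
    stop(path, ": r2 outside [0, 1]")
  x
}

#' Build the LD block for one index SNP
#'
#' The block is the min/max construction over proxy positions: among all
#' proxies of the index SNP with \code{r2 >= r2_threshold} (the index SNP
#' itself included), the smallest genomic position is the block start and
#' the largest is the block end. Positions are 1-based as published; the
#' stored interval is the 0-based half-open equivalent covering both
#' endpoints.
#'
#' @param index_snp rsID of the index SNP (must appear in \code{proxies}).
#' @param proxies Proxy table (see [read_proxy_table()]).
#' @param r2_threshold Minimum linkage r-squared for a proxy to extend the
#'   block (default 0.8).
#' @param locus_name Optional locus label.
#' @return A one-row haplotype-block data.frame with columns \code{snp_id},
#'   \code{locus_name}, \code{chrom}, \code{printed_start},
#'   \code{printed_end} (1-based inclusive, as published) and \code{start},
#'   \code{end} (0-based half-open).
#' @export
build_block <- function(index_snp, proxies, r2_threshold = 0.8,
                        locus_name = NA_character_) {
  rows <- proxies[proxies$index_snp == index_snp, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("index SNP '", index_snp, "' not present in proxy table")
  if (length(unique(rows$chrom)) > 1L)
    stop("proxies of '", index_snp, "' span multiple chromosomes: ",
         paste(unique(rows$chrom), collapse = ", "))
  pass <- rows[rows$r2 >= r2_threshold, , drop = FALSE]
  if (nrow(pass) == 0L) {
    # no proxy passes: degenerate 1-bp block at the index SNP itself
    warning("no proxy of '", index_snp, "' passes r2 >= ", r2_threshold,
            "; emitting a degenerate 1-bp block at the index position",
            call. = FALSE)
    idx <- rows[which.max(rows$r2), , drop = FALSE]
    pass <- idx
  }
  haplotype_blocks(snp_id = index_snp, chrom = rows$chrom[1L],
                   printed_start = min(pass$position),
                   printed_end = max(pass$position),
                   locus_name = locus_name)
}

#' Build LD blocks for every index SNP in a proxy table
#'
#' @inheritParams build_block
#' @return Haplotype-block data.frame, one row per index SNP.
#' @export
build_blocks <- function(proxies, r2_threshold = 0.8) {
  ids <- unique(proxies$index_snp)
  do.call(rbind, lapply(ids, build_block, proxies = proxies,
                        r2_threshold = r2_threshold))
}

#' Construct a haplotype-block table from printed coordinates
#'
#' @param snp_id rsID character vector.
#' @param chrom Chromosome names.
#' @param printed_start,printed_end 1-based inclusive block bounds as
#'   printed in publication tables. Equal bounds denote a degenerate
#'   single-position block (which still covers one bp as an interval).
#' @param locus_name Optional locus labels.
#' @return Haplotype-block data.frame (see [build_block()]).
#' @export
haplotype_blocks <- function(snp_id, chrom, printed_start, printed_end,
                             locus_name = NA_character_) {
  x <- data.frame(snp_id = as.character(snp_id),
                  locus_name = as.character(locus_name),
                  chrom = as.character(chrom),
                  printed_start = as.numeric(printed_start),
                  printed_end = as.numeric(printed_end),
                  stringsAsFactors = FALSE)
  if (any(x$printed_end < x$printed_start))
    stop("printed_end must not precede printed_start")
  x$start <- x$printed_start - 1
  x$end <- x$printed_end
  validate_intervals(x, where = "haplotype blocks")
  x
}

#' Read a haplotype-block table
#'
#' Loads blocks directly from a published-table-style TSV (header columns
#' \code{snp_id}, \code{chrom}, \code{start}, \code{end}, optional
#' \code{locus_name}; coordinates 1-based inclusive as printed), bypassing
#' the proxy-based construction.
#'
#' @param path Tab-separated file with a header row.
#' @return Haplotype-block data.frame (see [build_block()]).
#' @export
read_haplotype_blocks <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("snp_id", "chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop(path, ": block table must have columns ",
         paste(need, collapse = ", "))
  haplotype_blocks(x$snp_id, x$chrom, x$start, x$end,
                   locus_name = if ("locus_name" %in% names(x))
                     x$locus_name else NA_character_)
}

#' Write a haplotype-block table
#'
#' @param blocks Haplotype-block data.frame.
#' @param path Output path (TSV with printed 1-based coordinates, the same
#'   dialect [read_haplotype_blocks()] reads).
#' @return Invisibly, \code{path}.
#' @export
write_haplotype_blocks <- function(blocks, path) {
  out <- data.frame(snp_id = blocks$snp_id, chrom = blocks$chrom,
                    start = format_bp(blocks$printed_start),
                    end = format_bp(blocks$printed_end),
                    locus_name = blocks$locus_name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Block lengths under the published convention
#'
#' Lengths are computed as printed end minus printed start. This is the
#' convention under which the bundled 11-block scleroderma table averages
#' to the published 59,976 bp; the half-open interval length would be one
#' bp larger per block.
#'
#' @param blocks Haplotype-block data.frame.
#' @return Numeric vector of lengths in bp.
#' @export
block_lengths <- function(blocks) {
  stopifnot(nrow(blocks) > 0L)
  blocks$printed_end - blocks$printed_start
}

#' Average block length
#'
#' Floor of the arithmetic mean of [block_lengths()]; the integral bp
#' length used for the fixed-length random regions of the enrichment null.
#'
#' @param blocks Haplotype-block data.frame.
#' @return Integer-valued numeric scalar (bp).
#' @export
average_block_length <- function(blocks) {
  floor(mean(block_lengths(blocks)))
}

#' The 11 replicated scleroderma-risk haplotype blocks
#'
#' The bundled table of 11 replicated non-HLA systemic sclerosis risk
#' index SNPs and their LD blocks (GRCh38 printed coordinates), the query
#' set the enrichment analysis was designed around.
#'
#' @return Haplotype-block data.frame with 11 rows.
#' @examples
#' blocks <- ssc_risk_haplotypes()
#' average_block_length(blocks)
#' @export
ssc_risk_haplotypes <- function() {
  read_haplotype_blocks(system.file("extdata", "ssc_risk_haplotypes.tsv",
                                    package = "regulhap", mustWork = TRUE))
}
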