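#' Read a gene annotation
#'
#' Gene bodies as intervals plus identifiers. BED input (4+ columns; the
#' name column is the gene id) is read natively; GTF input takes the
#' \code{gene} features and uses the \code{gene_id}/\code{gene_name}
#' attributes (requires the rtracklayer package).
#'
#' @param path Annotation file.
#' @param format \code{"bed"} or \code{"gtf"} (default guessed from the
#'   file extension).
#' @return data.frame with columns \code{gene_id}, \code{gene_name},
#'   \code{chrom}, \code{start}, \code{end}.
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  if (format == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    return(data.frame(gene_id = gr$gene_id,
                      gene_name = if (!is.null(gr$gene_name)) gr$gene_name
                                  else gr$gene_id,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE))
  }
  x <- read_bed(path, dialect = "bed0", keep_name = TRUE)
  if (nrow(x) > 0L && anyNA(x$name))
    stop(path, ": BED gene annotation needs a name (4th) column")
  data.frame(gene_id = as.character(x$name), gene_name = as.character(x$name),
             chrom = x$chrom, start = x$start, end = x$end,
             stringsAsFactors = FALSE)
}

#' Write a gene annotation as BED4
#'
#' @param genes Gene data.frame (see [read_genes()]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_genes <- function(genes, path) {
  write_bed(data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, name = genes$gene_id,
                       stringsAsFactors = FALSE), path)
}

#' Genes overlapping reconstructed TADs
#'
#' A gene belongs to a locus TAD when its gene body overlaps any of the
#' locus's TAD intervals by at least one bp (half-open semantics: a gene
#' ending exactly where the TAD starts is outside). Inactive loci
#' contribute no genes.
#'
#' @param tads List of \code{locus_tad} objects with \code{tad_intervals}
#'   populated (see [locus_tads()]).
#' @param annotation Gene data.frame (see [read_genes()]).
#' @return List with \code{per_block} (named list of gene-id character
#'   vectors) and \code{pooled} (deduplicated union across blocks, in
#'   annotation order).
#' @export
genes_in_tads <- function(tads, annotation) {
  if (inherits(tads, "locus_tad")) tads <- list(tads)
  span <- annotation[, c("chrom", "start", "end")]
  per_block <- lapply(tads, function(td) {
    ti <- td$tad_intervals
    if (is.null(ti))
      stop("tad_intervals not populated; run anchors_to_tads() first")
    if (!td$active || nrow(ti) == 0L) return(character())
    annotation$gene_id[region_has_peak(span, ti)]
  })
  names(per_block) <- vapply(tads, function(td) td$block$snp_id, "")
  list(per_block = per_block,
       pooled = unique(unlist(per_block, use.names = FALSE)))
}

#' Read a gene-by-sample TPM matrix
#'
#' @param path Tab-separated file: header row of sample labels, first
#'   column gene ids.
#' @return Numeric matrix, genes x samples, gene ids as row names.
#' @export
read_tpm_matrix <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0))
    stop(path, ": TPM matrix must be non-negative and complete")
  m
}

#' Write a TPM matrix as TSV
#'
#' @param tpm Numeric matrix (genes x samples).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tpm_matrix <- function(tpm, path) {
  out <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter genes by expression
#'
#' A gene is called expressed when its TPM exceeds \code{tpm_threshold}
#' (strictly; a TPM of exactly 1.0 does not count at the default
#' threshold) in at least \code{min_fraction} of samples — by default at
#' least half, so 2 of 4 samples passes and 1 of 3 fails. Genes absent
#' from the matrix are dropped with a message.
#'
#' @param gene_ids Character vector of candidate gene ids.
#' @param tpm Numeric TPM matrix, gene ids as row names
#'   (see [read_tpm_matrix()]).
#' @param tpm_threshold Expression threshold (default 1).
#' @param min_fraction Minimum fraction of samples above threshold
#'   (default 0.5).
#' @return Character vector of expressed gene ids (in input order).
#' @export
expressed_genes <- function(gene_ids, tpm, tpm_threshold = 1,
                            min_fraction = 0.5) {
  stopifnot(tpm_threshold > 0, min_fraction > 0, min_fraction <= 1)
  if (length(tpm) == 0L || ncol(tpm) == 0L) stop("empty TPM matrix")
  missing <- setdiff(gene_ids, rownames(tpm))
  if (length(missing) > 0L)
    message(length(missing), " gene(s) absent from the TPM matrix dropped")
  ids <- gene_ids[gene_ids %in% rownames(tpm)]
  if (length(ids) == 0L) return(character())
  frac <- rowMeans(tpm[ids, , drop = FALSE] > tpm_threshold)
  ids[frac >= min_fraction]
}

#' Write a gene list (one id per line)
#'
#' Plain-text gene lists are the hand-off format for downstream ontology
#' tools.
#'
#' @param gene_ids Character vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gene_list <- function(gene_ids, path) {
  writeLines(gene_ids, path)
  invisible(path)
}
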