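#' Filter chromatin loops by read support
#'
#' Keeps intra-chromosomal loops whose read support is at least
#' \code{min_support} (default 2, dropping singleton-read loops).
#' Inter-chromosomal loops are always removed here — TAD reconstruction is
#' cis-only — and their number is reported via a message.
#'
#' @param loops Loop data.frame (see [read_bedpe()]).
#' @param min_support Minimum read support (default 2).
#' @return Filtered loop data.frame.
#' @export
filter_loops <- function(loops, min_support = 2) {
  n_trans <- sum(loops$inter_chromosomal)
  if (n_trans > 0L)
    message("excluding ", n_trans, " inter-chromosomal loop(s)")
  out <- loops[!loops$inter_chromosomal & loops$support >= min_support, ,
               drop = FALSE]
  row.names(out) <- NULL
  out
}

# Internal: pool the two anchors of every loop into one interval table with
# a back-reference to the loop and side.
pool_anchors <- function(loops) {
  n <- nrow(loops)
  data.frame(
    chrom = c(loops$chromA, loops$chromB),
    start = c(loops$startA, loops$startB),
    end = c(loops$endA, loops$endB),
    loop = rep(seq_len(n), 2L),
    stringsAsFactors = FALSE)
}

# Internal: assign each anchor to a node. Anchors that overlap by >= 1 bp
# (strictly; abutting anchors stay distinct) belong to the same node.
# Implemented as strict-overlap reduce: clusters of transitively
# overlapping anchors.
anchor_nodes <- function(anchors) {
  if (nrow(anchors) == 0L) return(integer())
  gr <- as_granges(anchors)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, red, minoverlap = 1L)
  node <- integer(nrow(anchors))
  node[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  node
}

# Internal: union-find with path halving.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i] <- parent[parent[i]]
  i
}

#' Transitive traversal of the loop-anchor graph from a block
#'
#' Identifies every genomic region in close physical proximity to a
#' haplotype block: anchors overlapping the block seed a breadth-first
#' closure over the anchor-interaction graph, in which every loop is an
#' edge between its two anchors and anchors overlapping each other (by at
#' least 1 bp) are one node. Traversal continues until no new region is
#' reached. A block no anchor overlaps is inactive — the locus shows no
#' loop engagement in this cell type — and yields an empty reach.
#'
#' @param block One-row haplotype-block data.frame.
#' @param loops Loop data.frame, already passed through [filter_loops()].
#' @return A \code{locus_tad} object: list with \code{block},
#'   \code{anchors_reached} (interval data.frame of the distinct anchors in
#'   the reached components), \code{tad_intervals} (empty until
#'   [anchors_to_tads()]), \code{active}, \code{n_anchors}.
#' @export
traverse_from_block <- function(block, loops) {
  stopifnot(nrow(block) == 1L)
  empty <- genomic_intervals()
  if (nrow(loops) > 0L && any(loops$inter_chromosomal))
    stop("loops must be filtered (inter-chromosomal loops present); ",
         "apply filter_loops() first")
  anchors <- pool_anchors(loops)
  if (nrow(anchors) == 0L)
    return(new_locus_tad(block, empty, active = FALSE))
  node <- anchor_nodes(anchors)
  # union nodes joined by a loop edge
  parent <- seq_len(max(node))
  n <- nrow(loops)
  for (i in seq_len(n)) {
    a <- uf_find(parent, node[i])
    b <- uf_find(parent, node[i + n])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(parent), function(i) uf_find(parent, i), 1L)
  seed_anchor <- overlaps(anchors,
                          block[rep(1L, nrow(anchors)),
                                c("chrom", "start", "end")])
  if (!any(seed_anchor))
    return(new_locus_tad(block, empty, active = FALSE))
  reached_comps <- unique(comp[node[seed_anchor]])
  keep <- comp[node] %in% reached_comps
  reach <- unique(anchors[keep, c("chrom", "start", "end")])
  reach <- reach[order(reach$chrom, reach$start, reach$end), , drop = FALSE]
  row.names(reach) <- NULL
  new_locus_tad(block, reach, active = TRUE)
}

new_locus_tad <- function(block, anchors_reached, active,
                          tad_intervals = NULL) {
  structure(list(block = block, anchors_reached = anchors_reached,
                 tad_intervals = tad_intervals, active = active,
                 n_anchors = nrow(anchors_reached)),
            class = "locus_tad")
}

#' Merge reached anchors into TAD intervals
#'
#' Applies the gap-bounded merge that defines the domain: all reached
#' anchors within \code{max_gap} (default 1 Mb) of each other are unioned.
#' Anchor clusters further apart than the gap bound yield multiple TAD
#' intervals, all of which are reported. An inactive input yields no
#' intervals.
#'
#' @param tad A \code{locus_tad} from [traverse_from_block()].
#' @param max_gap Maximum merge gap in bp (default 1e6).
#' @return The \code{locus_tad} with \code{tad_intervals} populated.
#' @export
anchors_to_tads <- function(tad, max_gap = 1e6) {
  stopifnot(inherits(tad, "locus_tad"))
  tad$tad_intervals <- if (!tad$active) genomic_intervals()
                       else merge_intervals(tad$anchors_reached, max_gap)
  tad
}

#' Reconstruct the TAD around every block
#'
#' Convenience wrapper: filters loops, traverses from each block, and
#' merges anchors, returning one \code{locus_tad} per block.
#'
#' @param blocks Haplotype-block data.frame.
#' @param loops Loop data.frame (unfiltered; [filter_loops()] is applied).
#' @param min_support Minimum loop read support (default 2).
#' @param max_gap Anchor-merge gap bound in bp (default 1e6).
#' @return Named list of \code{locus_tad} objects (names = SNP ids).
#' @export
locus_tads <- function(blocks, loops, min_support = 2, max_gap = 1e6) {
  fl <- filter_loops(loops, min_support)
  out <- lapply(seq_len(nrow(blocks)), function(i)
    anchors_to_tads(traverse_from_block(blocks[i, , drop = FALSE], fl),
                    max_gap))
  names(out) <- blocks$snp_id
  out
}

#' @export
print.locus_tad <- function(x, ...) {
  cat("Locus TAD for", x$block$snp_id,
      sprintf("(%s:%s-%s)\n", x$block$chrom, format_bp(x$block$printed_start),
              format_bp(x$block$printed_end)))
  if (!x$active) {
    cat("  inactive: no loop anchor overlaps the block\n")
  } else {
    cat("  anchors reached:", x$n_anchors, "\n")
    if (!is.null(x$tad_intervals) && nrow(x$tad_intervals) > 0L)
      cat(sprintf("  TAD interval: %s:%s-%s (%s bp)\n",
                  x$tad_intervals$chrom,
                  format_bp(x$tad_intervals$start),
                  format_bp(x$tad_intervals$end),
                  format_bp(interval_length(x$tad_intervals))), sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.locus_tad <- function(x, ...) {
  if (!x$active || is.null(x$tad_intervals) || nrow(x$tad_intervals) == 0L)
    return(data.frame(snp_id = x$block$snp_id, chrom = x$block$chrom,
                      tad_start = NA_real_, tad_end = NA_real_,
                      n_anchors = x$n_anchors, active = x$active,
                      stringsAsFactors = FALSE))
  data.frame(snp_id = x$block$snp_id, chrom = x$tad_intervals$chrom,
             tad_start = x$tad_intervals$start,
             tad_end = x$tad_intervals$end, n_anchors = x$n_anchors,
             active = x$active, stringsAsFactors = FALSE)
}

#' Tabulate a list of locus TADs
#'
#' @param tads List of \code{locus_tad} objects (see [locus_tads()]).
#' @return data.frame with one row per TAD interval (or per inactive
#'   block).
#' @export
tad_table <- function(tads) {
  do.call(rbind, lapply(tads, as.data.frame))
}

#' Corroborate TAD boundaries against CTCF peaks
#'
#' A reconstructed domain is expected to carry CTCF binding at both edges.
#' For each TAD interval, checks that at least one CTCF peak overlaps a
#' window of \code{flank} bp on either side of each boundary
#' (\code{[boundary - flank, boundary + flank)}).
#'
#' @param tad A \code{locus_tad} with \code{tad_intervals} populated.
#' @param ctcf_peaks A \code{peak_set} or interval data.frame of CTCF
#'   ChIP-seq peaks.
#' @param flank Half-width of the boundary window in bp (default 1e4).
#' @return Logical vector, one element per TAD interval: \code{TRUE} iff
#'   both boundaries have CTCF support.
#' @export
corroborate_boundaries <- function(tad, ctcf_peaks, flank = 1e4) {
  stopifnot(inherits(tad, "locus_tad"), !is.null(tad$tad_intervals))
  ti <- tad$tad_intervals
  if (nrow(ti) == 0L) return(logical())
  win <- function(pos) data.frame(chrom = ti$chrom,
                                  start = pmax(0, pos - flank),
                                  end = pos + flank,
                                  stringsAsFactors = FALSE)
  region_has_peak(win(ti$start), ctcf_peaks) &
    region_has_peak(win(ti$end), ctcf_peaks)
}
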