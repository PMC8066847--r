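#' Construct a validated set of genomic intervals
#'
#' Intervals are the universal coordinate unit of the package: 0-based,
#' half-open \code{[start, end)} spans on named chromosomes, the BED
#' convention. All higher-level containers (haplotype blocks, peak sets,
#' loop anchors, gene bodies, TAD intervals) carry their coordinates in
#' this form.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector of 0-based inclusive start offsets (>= 0).
#' @param end Integer vector of 0-based exclusive end offsets
#'   (\code{end > start}).
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer()) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

# Validation shared by every reader/constructor. `where` names the input in
# error messages (file path or argument name).
validate_intervals <- function(x, where = "intervals", layout = NULL) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  bad <- !nzchar(x$chrom) | is.na(x$chrom)
  if (any(bad))
    stop(where, ": empty chromosome name at row ", which(bad)[1L])
  bad <- is.na(x$start) | is.na(x$end) | x$start < 0
  if (any(bad))
    stop(where, ": negative or missing coordinate at row ", which(bad)[1L])
  bad <- x$end <= x$start
  if (any(bad))
    stop(where, ": end <= start at row ", which(bad)[1L])
  if (!is.null(layout)) {
    len <- layout[x$chrom]
    bad <- is.na(len) | x$end > len
    if (any(bad))
      stop(where, ": interval exceeds chromosome bounds (or unknown ",
           "chromosome) at row ", which(bad)[1L])
  }
  invisible(x)
}

#' Interval lengths in base pairs
#'
#' @param x Interval data.frame (see [genomic_intervals()]).
#' @return Numeric vector of \code{end - start}.
#' @export
interval_length <- function(x) x$end - x$start

# Internal: intervals <-> GRanges (GRanges/IRanges are 1-based closed).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: at least one shared base is required, so abutting
#' intervals (\code{a$end == b$start}) do not overlap. Vectorized over rows;
#' shorter input is recycled.
#'
#' @param a,b Interval data.frames (see [genomic_intervals()]).
#' @return Logical vector.
#' @examples
#' a <- genomic_intervals("chr1", 0, 10)
#' b <- genomic_intervals("chr1", 10, 20)
#' overlaps(a, b)  # FALSE: adjacency is not overlap
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Merge intervals closer than a maximum gap
#'
#' Per chromosome, sorts the intervals and unions any pair whose gap
#' (\code{next$start - prev$end}) is at most \code{max_gap}. With
#' \code{max_gap = 0} this is classical interval union (overlapping or
#' abutting intervals merge). This is the operation used both to collapse
#' peak sets and to turn reached loop anchors into TAD intervals with the
#' 1 Mb gap bound.
#'
#' @param x Interval data.frame.
#' @param max_gap Maximum gap in bp that still merges (integer >= 0).
#' @return Interval data.frame, sorted, pairwise gaps all > \code{max_gap};
#'   its union covers the union of the input.
#' @examples
#' merge_intervals(genomic_intervals(c("c", "c"), c(0, 5), c(10, 20)), 0)
#' @export
merge_intervals <- function(x, max_gap = 0) {
  stopifnot(max_gap >= 0)
  validate_intervals(x)
  if (nrow(x) == 0L) return(x[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = max_gap + 1)
  granges_to_intervals(GenomicRanges::sort(gr))
}

#' Read a BED file of intervals
#'
#' Supports two coordinate dialects: \code{"bed0"} (standard BED, 0-based
#' half-open; the identity) and \code{"printed1"} (1-based fully-closed
#' coordinates as printed in publication tables and genome browsers;
#' 1 is subtracted from the start only).
#'
#' @param path Path to a tab-separated file with >= 3 columns; lines
#'   starting with \code{#} are skipped.
#' @param dialect \code{"bed0"} or \code{"printed1"}.
#' @param keep_name If \code{TRUE} and a 4th column exists, it is returned
#'   as a \code{name} column.
#' @return Interval data.frame (plus \code{name} if requested).
#' @export
read_bed <- function(path, dialect = c("bed0", "printed1"),
                     keep_name = FALSE) {
  dialect <- match.arg(dialect)
  fields <- read_tab_lines(path, min_fields = 3L)
  if (length(fields$lines) == 0L) {
    out <- genomic_intervals()
    if (keep_name) out$name <- character()
    return(out)
  }
  start <- suppressWarnings(as.numeric(vapply(fields$lines, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields$lines, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != trunc(start) | end != trunc(end)
  if (any(bad))
    stop(path, ": non-integer coordinate at line ", fields$lineno[bad][1L])
  if (dialect == "printed1") start <- start - 1
  x <- data.frame(chrom = vapply(fields$lines, `[`, "", 1L),
                  start = start, end = end,
                  stringsAsFactors = FALSE, row.names = NULL)
  bad <- x$end <= x$start | x$start < 0 | !nzchar(x$chrom)
  if (any(bad))
    stop(path, ": invalid interval (end <= start, negative start, or ",
         "empty chromosome) at line ", fields$lineno[bad][1L])
  if (keep_name)
    x$name <- vapply(fields$lines, function(f)
      if (length(f) >= 4L) f[4L] else NA_character_, "")
  x
}

#' Write intervals as BED (dialect bed0)
#'
#' @param x Interval data.frame; an optional \code{name} column becomes
#'   BED column 4.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(x)))
  out <- x[, cols, drop = FALSE]
  out$start <- format_bp(out$start)
  out$end <- format_bp(out$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

# Internal: tokenize a tab-separated text file, skipping '#' comments and
# blank lines, enforcing a minimum field count with line-numbered errors.
read_tab_lines <- function(path, min_fields) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(raw) & !startsWith(raw, "#")
  lineno <- which(keep)
  lines <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(lines)
  if (any(nf < min_fields))
    stop(path, ": expected >= ", min_fields, " tab-separated fields at line ",
         lineno[nf < min_fields][1L])
  list(lines = lines, lineno = lineno)
}

#' Read chromatin loops from a BEDPE file
#'
#' Each record carries two anchor intervals; a read-support count is taken
#' from \code{support_column} when that column exists (records lacking it
#' default to support 1). Inter-chromosomal records are retained and
#' flagged; downstream TAD traversal excludes them.
#'
#' @param path Path to a BEDPE file (>= 6 tab-separated columns).
#' @param support_column 1-based column index of the read-support count
#'   (default 8, the standard position after the name/score columns).
#' @return A \code{data.frame} of loops with columns \code{chromA},
#'   \code{startA}, \code{endA}, \code{chromB}, \code{startB}, \code{endB},
#'   \code{support}, \code{inter_chromosomal}.
#' @export
read_bedpe <- function(path, support_column = 8L) {
  fields <- read_tab_lines(path, min_fields = 6L)
  if (length(fields$lines) == 0L) return(empty_loops())
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(fields$lines, `[`, "", i)))
    bad <- is.na(v) | v != trunc(v)
    if (any(bad))
      stop(path, ": non-integer coordinate at line ", fields$lineno[bad][1L])
    v
  }
  x <- data.frame(chromA = vapply(fields$lines, `[`, "", 1L),
                  startA = num(2L), endA = num(3L),
                  chromB = vapply(fields$lines, `[`, "", 4L),
                  startB = num(5L), endB = num(6L),
                  stringsAsFactors = FALSE, row.names = NULL)
  supp <- vapply(fields$lines, function(f)
    if (length(f) >= support_column) f[support_column] else NA_character_, "")
  support <- suppressWarnings(as.numeric(supp))
  bad <- !is.na(supp) & (is.na(support) | support != trunc(support))
  if (any(bad))
    stop(path, ": non-integer support value at line ", fields$lineno[bad][1L])
  support[is.na(support)] <- 1
  x$support <- support
  bad <- x$endA <= x$startA | x$endB <= x$startB | x$startA < 0 | x$startB < 0
  if (any(bad))
    stop(path, ": invalid anchor interval at line ", fields$lineno[bad][1L])
  x$inter_chromosomal <- x$chromA != x$chromB
  x
}

empty_loops <- function() {
  data.frame(chromA = character(), startA = numeric(), endA = numeric(),
             chromB = character(), startB = numeric(), endB = numeric(),
             support = numeric(), inter_chromosomal = logical(),
             stringsAsFactors = FALSE)
}

#' Write loops as BEDPE
#'
#' Columns 7 (name) is a dot placeholder; the support count is written in
#' column 8, matching what [read_bedpe()] reads back by default.
#'
#' @param loops Loop data.frame (see [read_bedpe()]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bedpe <- function(loops, path) {
  out <- data.frame(loops$chromA, format_bp(loops$startA),
                    format_bp(loops$endA), loops$chromB,
                    format_bp(loops$startB), format_bp(loops$endB),
                    ".", format_bp(loops$support))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes genome layout
#'
#' @param path Two-column tab-separated file (chromosome name, length in bp;
#'   the UCSC chrom.sizes dialect).
#' @return Named numeric vector of chromosome lengths (a genome layout).
#' @export
read_chrom_sizes <- function(path) {
  fields <- read_tab_lines(path, min_fields = 2L)
  len <- suppressWarnings(as.numeric(vapply(fields$lines, `[`, "", 2L)))
  bad <- is.na(len) | len <= 0 | len != trunc(len)
  if (any(bad))
    stop(path, ": invalid chromosome length at line ", fields$lineno[bad][1L])
  nm <- vapply(fields$lines, `[`, "", 1L)
  if (anyDuplicated(nm))
    stop(path, ": duplicated chromosome name '", nm[duplicated(nm)][1L], "'")
  stats::setNames(len, nm)
}

#' Write a genome layout as chrom.sizes
#'
#' @param genome Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(paste(names(genome), format_bp(genome), sep = "\t"), path)
  invisible(path)
}

#' Check chromosome-name compatibility between inputs
#'
#' Chromosome matching throughout the package is exact string equality; no
#' silent "chr" prefix normalization is performed. This validation pass
#' reports apparent prefix mismatches (e.g. \code{chr1} in one input, plain
#' \code{1} in another) so that data errors surface instead of producing
#' silently empty overlaps.
#'
#' @param ... Named character vectors (or interval data.frames, from which
#'   \code{chrom} is taken) to compare.
#' @return Invisibly \code{TRUE}; warns on detected prefix mismatches.
#' @export
check_chrom_names <- function(...) {
  inputs <- list(...)
  nm <- names(inputs)
  chroms <- lapply(inputs, function(x)
    unique(if (is.data.frame(x)) x$chrom else as.character(x)))
  strip <- function(v) sub("^chr", "", v)
  for (i in seq_along(chroms)) for (j in seq_along(chroms)) {
    if (i >= j) next
    shared <- intersect(chroms[[i]], chroms[[j]])
    shared_stripped <- intersect(strip(chroms[[i]]), strip(chroms[[j]]))
    if (length(shared) == 0L && length(shared_stripped) > 0L)
      warning("inputs '", nm[i], "' and '", nm[j], "' share no chromosome ",
              "names but match after removing a 'chr' prefix; ",
              "coordinate systems likely differ", call. = FALSE)
  }
  invisible(TRUE)
}
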