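# Independent brute-force oracles. These deliberately share no code with
# the package internals: all-pairs scans, per-base bitmaps, and boolean
# transitive-closure matrices.

pair_overlaps <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 < e2 && s2 < e1
}

# number of regions with >= 1 overlapping interval in `peaks` (all-pairs)
brute_count_overlapping <- function(regions, peaks) {
  if (nrow(regions) == 0L || nrow(peaks) == 0L) return(0L)
  n <- 0L
  for (i in seq_len(nrow(regions))) {
    hit <- FALSE
    for (j in seq_len(nrow(peaks))) {
      if (pair_overlaps(regions$chrom[i], regions$start[i], regions$end[i],
                        peaks$chrom[j], peaks$start[j], peaks$end[j])) {
        hit <- TRUE
        break
      }
    }
    n <- n + hit
  }
  n
}

# classical interval union via per-base occupancy bitmap (gap 0 only;
# coordinates must stay small)
brute_union_bitmap <- function(x) {
  out <- NULL
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, , drop = FALSE]
    occ <- logical(max(xi$end))
    for (i in seq_len(nrow(xi)))
      occ[(xi$start[i] + 1):xi$end[i]] <- TRUE
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out <- rbind(out, data.frame(chrom = ch, start = starts[keep],
                                 end = ends[keep],
                                 stringsAsFactors = FALSE))
  }
  row.names(out) <- NULL
  out
}

# gap-bounded merge by repeated pairwise unioning until fixpoint
brute_merge_fixpoint <- function(x, max_gap) {
  items <- split(x, seq_len(nrow(x)))
  repeat {
    changed <- FALSE
    for (i in seq_along(items)) {
      if (is.null(items[[i]])) next
      for (j in seq_along(items)) {
        if (i == j || is.null(items[[j]])) next
        a <- items[[i]]; b <- items[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap <= max_gap) {
          items[[i]] <- data.frame(chrom = a$chrom,
                                   start = min(a$start, b$start),
                                   end = max(a$end, b$end),
                                   stringsAsFactors = FALSE)
          items[j] <- list(NULL)
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, items)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# connected components of the anchor graph by boolean transitive closure:
# adjacency = anchor overlap OR loop edge; reached = closure rows of the
# anchors overlapping the block
brute_reached_anchors <- function(block, loops) {
  n <- nrow(loops)
  if (n == 0L) return(NULL)
  anc <- data.frame(
    chrom = c(loops$chromA, loops$chromB),
    start = c(loops$startA, loops$startB),
    end = c(loops$endA, loops$endB), stringsAsFactors = FALSE)
  m <- nrow(anc)
  adj <- diag(TRUE, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (pair_overlaps(anc$chrom[i], anc$start[i], anc$end[i],
                      anc$chrom[j], anc$start[j], anc$end[j]))
      adj[i, j] <- TRUE
  }
  for (k in seq_len(n)) {
    adj[k, k + n] <- TRUE
    adj[k + n, k] <- TRUE
  }
  # transitive closure (Floyd-Warshall on booleans)
  for (k in seq_len(m)) for (i in seq_len(m)) {
    if (adj[i, k]) adj[i, ] <- adj[i, ] | adj[k, ]
  }
  seed <- vapply(seq_len(m), function(i)
    pair_overlaps(anc$chrom[i], anc$start[i], anc$end[i],
                  block$chrom, block$start, block$end), TRUE)
  if (!any(seed)) return(NULL)
  reached <- apply(adj[seed, , drop = FALSE], 2L, any)
  out <- unique(anc[reached, , drop = FALSE])
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# direct per-gene recount of the expression filter
brute_expressed <- function(ids, tpm, thr = 1, frac = 0.5) {
  keep <- character()
  for (g in ids) {
    if (!g %in% rownames(tpm)) next
    n_above <- sum(tpm[g, ] > thr)
    if (n_above / ncol(tpm) >= frac) keep <- c(keep, g)
  }
  keep
}

# random small interval sets for property tests
rand_intervals <- function(n, chroms = c("cA", "cB"), max_pos = 1000,
                           max_len = 50) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# random loop set on one chromosome with anchors drawn from a small pool
rand_loops <- function(n_anchors, n_loops, max_pos = 5000,
                       anchor_len = 100) {
  as_ <- sample.int(max_pos, n_anchors, replace = TRUE) - 1L
  pool <- data.frame(chrom = "cA", start = as_, end = as_ + anchor_len,
                     stringsAsFactors = FALSE)
  i <- sample.int(n_anchors, n_loops, replace = TRUE)
  j <- sample.int(n_anchors, n_loops, replace = TRUE)
  data.frame(chromA = "cA", startA = pool$start[i], endA = pool$end[i],
             chromB = "cA", startB = pool$start[j], endB = pool$end[j],
             support = sample(2:5, n_loops, replace = TRUE),
             inter_chromosomal = FALSE, stringsAsFactors = FALSE)
}

sort_iv <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), c("chrom", "start", "end")]
  row.names(x) <- NULL
  x
}
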