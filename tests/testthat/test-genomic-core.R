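test_that("read_bed handles both coordinate dialects and empty input", {
  f <- withr::local_tempfile(lines = c("# a comment", "chrT\t10\t20"))
  x <- read_bed(f)
  expect_equal(x, genomic_intervals("chrT", 10, 20))
  expect_equal(interval_length(x), 10)

  # printed 1-based fully-closed coordinates: start shifts down by one
  f2 <- withr::local_tempfile(lines = "chr6\t137849452\t137921300")
  y <- read_bed(f2, dialect = "printed1")
  expect_equal(y$start, 137849451)
  expect_equal(y$end, 137921300)
  expect_equal(interval_length(y), 71849)

  f3 <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_bed(f3)), 0L)
})

test_that("read_bed reports malformed lines by number", {
  f <- withr::local_tempfile(lines = c("chrT\t0\t10", "chrT\t5"))
  expect_error(read_bed(f), "line 2")
  f2 <- withr::local_tempfile(lines = c("chrT\t0\t10", "chrT\tx\t20"))
  expect_error(read_bed(f2), "line 2")
  f3 <- withr::local_tempfile(lines = c("# hdr", "chrT\t30\t20"))
  expect_error(read_bed(f3), "line 2")
})

test_that("BED writing round-trips intervals bit-exactly", {
  withr::local_seed(11)
  x <- sort_iv(rand_intervals(60))
  f <- withr::local_tempfile()
  write_bed(x, f)
  expect_equal(read_bed(f), x)
  f2 <- withr::local_tempfile()
  write_bed(read_bed(f), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("read_bedpe parses anchors, support, and trans flags", {
  f <- withr::local_tempfile(
    lines = c("chrT\t0\t10\tchrT\t100\t110\t.\t3",
              "chrT\t5\t15\tchrT\t200\t210",
              "chrT\t0\t10\tchrU\t0\t10\t.\t2"))
  lp <- read_bedpe(f)
  expect_equal(lp$support, c(3, 1, 2))  # absent support column -> 1
  expect_equal(lp$inter_chromosomal, c(FALSE, FALSE, TRUE))
  expect_equal(lp$startB[1], 100)

  f2 <- withr::local_tempfile(lines = "chrT\t0\t10\tchrT\t100")
  expect_error(read_bedpe(f2), "line 1")
  f3 <- withr::local_tempfile(lines = "chrT\t10\t0\tchrT\t100\t110")
  expect_error(read_bedpe(f3), "line 1")
})

test_that("overlap semantics are half-open, chromosome-aware, symmetric", {
  a <- genomic_intervals("cA", 0, 10)
  expect_false(overlaps(a, genomic_intervals("cA", 10, 20)))  # abutting
  expect_true(overlaps(a, genomic_intervals("cA", 9, 20)))
  expect_false(overlaps(a, genomic_intervals("cB", 0, 10)))

  withr::local_seed(5)
  x <- rand_intervals(80)
  y <- rand_intervals(80)
  expect_equal(overlaps(x, y), overlaps(y, x))   # symmetry
  expect_true(all(overlaps(x, x)))               # reflexivity
})

test_that("merge_intervals honours the gap bound and is idempotent", {
  two <- genomic_intervals(c("c", "c"), c(0, 5), c(10, 20))
  expect_equal(merge_intervals(two, 0), genomic_intervals("c", 0, 20))

  near <- genomic_intervals(c("c", "c"), c(0, 1e6), c(10, 1e6 + 10))
  expect_equal(merge_intervals(near, 1e6),
               genomic_intervals("c", 0, 1e6 + 10))  # gap 999,990 merges

  far <- genomic_intervals(c("c", "c"), c(0, 2e6), c(10, 2e6 + 10))
  expect_equal(merge_intervals(far, 1e6), far)

  withr::local_seed(21)
  for (gap in c(0, 7, 40)) {
    x <- rand_intervals(50)
    m <- merge_intervals(x, gap)
    expect_identical(merge_intervals(m, gap), m)   # idempotence
    gaps_ok <- tapply(seq_len(nrow(m)), m$chrom, function(i) {
      if (length(i) < 2) return(TRUE)
      all(m$start[i][-1] - m$end[i][-length(i)] > gap)
    })
    expect_true(all(unlist(gaps_ok)))
  }
})

test_that("merge with gap 0 equals the per-base occupancy union", {
  withr::local_seed(33)
  for (rep in 1:20) {
    x <- rand_intervals(sample(1:40, 1))
    expect_equal(sort_iv(merge_intervals(x, 0)),
                 sort_iv(brute_union_bitmap(x)))
  }
})

test_that("chrom.sizes reading validates and round-trips", {
  f <- withr::local_tempfile(lines = c("chr1\t1000000", "chr2\t500000"))
  g <- read_chrom_sizes(f)
  expect_equal(g, c(chr1 = 1e6, chr2 = 5e5))
  f2 <- withr::local_tempfile()
  write_chrom_sizes(g, f2)
  expect_identical(readLines(f), readLines(f2))

  fdup <- withr::local_tempfile(lines = c("chr1\t10", "chr1\t20"))
  expect_error(read_chrom_sizes(fdup), "duplicated")
  fneg <- withr::local_tempfile(lines = "chr1\t0")
  expect_error(read_chrom_sizes(fneg), "line 1")
})

test_that("chromosome prefix mismatches are reported, not silently fixed", {
  a <- genomic_intervals("chr1", 0, 10)
  b <- genomic_intervals("1", 0, 10)
  expect_warning(check_chrom_names(peaks = a, blocks = b), "chr")
  expect_silent(check_chrom_names(peaks = a, blocks = a))
  expect_false(overlaps(a, b))  # and they really do not match
})

test_that("interval validation rejects degenerate spans", {
  expect_error(genomic_intervals("c", 5, 5), "end <= start")
  expect_error(genomic_intervals("c", -1, 5), "negative")
  expect_error(genomic_intervals("", 0, 5), "empty chromosome")
})
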