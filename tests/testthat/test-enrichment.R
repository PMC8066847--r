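test_that("count_overlapping_regions counts regions, not intersections", {
  regions <- genomic_intervals(rep("c", 3), c(0, 100, 200), c(50, 150, 250))
  peaks <- genomic_intervals(rep("c", 3), c(110, 120, 130), c(115, 125, 135))
  expect_equal(count_overlapping_regions(regions, peaks), 1L)  # region 2 only
  expect_equal(count_overlapping_regions(regions, regions), 3L)
  expect_equal(count_overlapping_regions(regions, genomic_intervals()), 0L)
  expect_equal(region_has_peak(regions, peaks), c(FALSE, TRUE, FALSE))
})

test_that("count is monotone under added peaks and matches the oracle", {
  withr::local_seed(14)
  for (rep in 1:30) {
    regions <- rand_intervals(sample(1:30, 1))
    peaks <- rand_intervals(sample(1:60, 1))
    expect_equal(count_overlapping_regions(regions, peaks),
                 brute_count_overlapping(regions, peaks))
    more <- rbind(peaks, rand_intervals(10))
    expect_gte(count_overlapping_regions(regions, more),
               count_overlapping_regions(regions, peaks))
  }
})

test_that("random regions respect the genome layout", {
  # single valid placement
  forced <- sample_random_regions(c(chrT = 1000), 1000, 1, seed = 1)
  expect_equal(forced, genomic_intervals("chrT", 0, 1000))

  expect_error(sample_random_regions(c(chrT = 100), 200, 1, seed = 1),
               "no chromosome")

  r <- sample_random_regions(c(cA = 1e5, cB = 5e4), 2000, 500, seed = 3)
  expect_true(all(interval_length(r) == 2000))
  lens <- c(cA = 1e5, cB = 5e4)
  expect_true(all(r$end <= lens[r$chrom]))
  expect_true(all(r$start >= 0))
})

test_that("chromosomes are drawn proportionally to valid-start space", {
  r <- sample_random_regions(c(cA = 1e6, cB = 1e6), 100, 1e4, seed = 7)
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(mean(r$chrom == "cA") - 0.5), 3 * se)
})

test_that("region sampling and enrichment are seed-reproducible", {
  g <- c(cA = 1e6)
  expect_identical(sample_random_regions(g, 500, 50, seed = 42),
                   sample_random_regions(g, 500, 50, seed = 42))

  sc <- make_null_scenario(8)
  e1 <- empirical_enrichment(sc$blocks, sc$peaks, sc$genome,
                             n_reps = 100, seed = 9)
  e2 <- empirical_enrichment(sc$blocks, sc$peaks, sc$genome,
                             n_reps = 100, seed = 9)
  expect_identical(e1, e2)
  # and the caller's RNG state is untouched
  set.seed(1); before <- .Random.seed
  empirical_enrichment(sc$blocks, sc$peaks, sc$genome, n_reps = 10,
                       seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("degenerate nulls are flagged with tie-broken p-values", {
  g <- c(cA = 1e5)
  blocks <- haplotype_blocks(c("r1", "r2"), "cA", c(1001, 50001),
                             c(3000, 52000))
  # peaks tiling the whole genome: every region hits, observed == null
  tiling <- genomic_intervals("cA", 0, 1e5)
  e <- empirical_enrichment(blocks, tiling, g, n_reps = 50, seed = 2)
  expect_true(e$degenerate_null)
  expect_equal(e$p_value, 0.5)
  expect_equal(e$observed, 2L)

  # empty peak set: all counts zero
  e0 <- empirical_enrichment(blocks, genomic_intervals(), g, n_reps = 50,
                             seed = 2)
  expect_true(e0$degenerate_null)
  expect_equal(e0$observed, 0L)
  expect_equal(e0$p_value, 0.5)

  # observed above a zero-spread null -> p = 0
  one_peak <- genomic_intervals("cA", 1500, 1600)
  blocks_wide <- haplotype_blocks("r1", "cA", 1001, 3000)
  e1 <- empirical_enrichment(blocks_wide, one_peak, g, n_reps = 30,
                             seed = 4, region_length = 10)
  if (e1$degenerate_null) expect_true(e1$p_value %in% c(0, 0.5))
})

test_that("enrichment results carry a coherent summary row", {
  sc <- make_enriched_scenario(5, fold = 50)
  e <- empirical_enrichment(sc$blocks, sc$peaks, sc$genome, n_reps = 200,
                            seed = 5)
  expect_s3_class(e, "enrichment_result")
  expect_true(e$p_value >= 0 && e$p_value <= 1)
  expect_lte(e$observed, e$n_regions)
  expect_equal(e$n_reps, 200)
  expect_equal(length(e$null_counts), 200L)
  expect_equal(e$significant, e$p_value < e$alpha)
  df <- as.data.frame(e)
  expect_equal(df$observed, e$observed)
  expect_equal(df$cell_type, "synthetic")
  expect_output(print(e), "one-sided p")
})

test_that("enrichment_table runs per set and adds a BH column", {
  sc <- make_null_scenario(12)
  sets <- list(sc$peaks,
               peak_set("other", "H3K4me1", sc$peaks$peaks[1:20, ]))
  tab <- enrichment_table(sc$blocks, sets, sc$genome, n_reps = 50,
                          seed = 31)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$p_adj_BH >= tab$p_value - 1e-12))
  expect_equal(tab$mark, c("mark", "H3K4me1"))
})

test_that("presence matrix marks overlaps with Y and absences with -", {
  blocks <- haplotype_blocks(c("rsA", "rsB"), "cA", c(1001, 5001),
                             c(2000, 6000))
  hit <- peak_set("Mono", "H3K27ac", genomic_intervals("cA", 1500, 1600))
  empty <- peak_set("HUVEC", "H3K4me3", genomic_intervals())
  m <- presence_matrix(blocks, list(hit, empty))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m[, "Mono.H3K27ac"]), c("Y", "-"))
  expect_equal(unname(m[, "HUVEC.H3K4me3"]), c("-", "-"))
  # a block nothing overlaps is an all-absent row
  expect_true(all(m["cA rsB", ] == "-"))
  f <- withr::local_tempfile()
  write_presence_matrix(m, f)
  expect_match(readLines(f)[2], "^cA rsA\tY\t-$")
})
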