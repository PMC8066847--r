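test_that("scenario generation is bit-reproducible under a seed", {
  for (make in list(make_null_scenario, make_enriched_scenario,
                    make_tad_scenario)) {
    expect_identical(make(17), make(17))
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(make_tad_scenario(17), d1)
  write_scenario(make_tad_scenario(17), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  # and generation leaves the caller's RNG alone
  set.seed(2); before <- .Random.seed
  make_null_scenario(99)
  expect_identical(.Random.seed, before)
})

test_that("written scenario files parse back to the generated objects", {
  sc <- make_tad_scenario(23)
  d <- withr::local_tempdir()
  paths <- write_scenario(sc, d)
  expect_equal(read_chrom_sizes(paths["chrom_sizes"]), sc$genome)
  expect_equal(read_haplotype_blocks(paths["blocks"]), sc$blocks)
  expect_equal(read_bed(paths["peaks"]), sc$peaks$peaks,
               ignore_attr = "row.names")
  expect_equal(read_bedpe(paths["loops"]), sc$loops)
  expect_equal(read_genes(paths["genes"]), sc$genes)
  expect_equal(read_tpm_matrix(paths["tpm"]), sc$tpm)
  # regenerating files from the parsed objects is byte-identical
  d2 <- withr::local_tempdir()
  write_bed(read_bed(paths["peaks"]), file.path(d2, "peaks.bed"))
  write_bedpe(read_bedpe(paths["loops"]), file.path(d2, "loops.bedpe"))
  expect_identical(readLines(paths["peaks"]),
                   readLines(file.path(d2, "peaks.bed")))
  expect_identical(readLines(paths["loops"]),
                   readLines(file.path(d2, "loops.bedpe")))
})

test_that("null scenario has homogeneous peak density and fold-1 parity", {
  expect_identical(make_null_scenario(31)$peaks,
                   make_enriched_scenario(
                     31, fold = 1, genome = c(chrS1 = 6e6, chrS2 = 4e6),
                     block_length = 1e4, background_density = 50,
                     kind = "null")$peaks)
  # density 0 produces no peaks and zero counts everywhere
  sc0 <- make_null_scenario(31, peak_density = 0)
  expect_equal(nrow(sc0$peaks$peaks), 0L)
  expect_equal(count_overlapping_regions(sc0$blocks, sc0$peaks), 0L)
})

test_that("enriched scenarios concentrate peaks inside the blocks", {
  sc <- make_enriched_scenario(37, fold = 50)
  inside <- count_overlapping_regions(sc$peaks$peaks, sc$blocks)
  expect_gt(inside / nrow(sc$peaks$peaks), 0.5)
  expect_equal(region_has_peak(sc$blocks, sc$peaks),
               rep(TRUE, nrow(sc$blocks)))
})

test_that("the planted TAD scenario is internally consistent", {
  sc <- make_tad_scenario(43)
  tr <- sc$truth
  # chain anchors inside the genome and with sub-1 Mb gaps
  expect_true(all(tr$chain_anchors$end <= sc$genome[tr$chain_anchors$chrom]))
  gaps <- tr$chain_anchors$start[-1] -
    tr$chain_anchors$end[-nrow(tr$chain_anchors)]
  expect_true(all(gaps > 0 & gaps < 1e6))
  # the seed block overlaps the first anchor only; the inactive block none
  anchors <- genomic_intervals(
    c(sc$loops$chromA, sc$loops$chromB),
    c(sc$loops$startA, sc$loops$startB),
    c(sc$loops$endA, sc$loops$endB))
  seed_blk <- sc$blocks[sc$blocks$snp_id == tr$seed_block, ]
  inact <- sc$blocks[sc$blocks$snp_id == tr$inactive_block, ]
  expect_true(any(overlaps(anchors, seed_blk[rep(1, nrow(anchors)), ])))
  expect_false(any(overlaps(anchors, inact[rep(1, nrow(anchors)), ])))
  # planted TPM matches the expressed/silent labels
  expect_true(all(rowMeans(sc$tpm[tr$expressed_in_tad, ] > 1) >= 0.5))
  expect_true(all(sc$tpm[tr$silent_in_tad, ] <= 1))
})

test_that("planted structure is recovered by the TAD stage", {
  sc <- make_tad_scenario(47)
  tads <- suppressMessages(locus_tads(sc$blocks, sc$loops))
  tad <- tads[[sc$truth$seed_block]]
  # single interval spanning exactly the chain's outermost anchors
  expect_equal(nrow(tad$tad_intervals), 1L)
  expect_equal(c(tad$tad_intervals$start, tad$tad_intervals$end),
               sc$truth$chain_span)
  expect_equal(tad$n_anchors, sc$truth$n_chain_anchors)
  expect_false(tads[[sc$truth$inactive_block]]$active)
  # chain boundaries corroborate against the planted CTCF peaks
  expect_true(corroborate_boundaries(tad, sc$peaks))

  # weakening the chain to support 1 inactivates the locus
  weak <- sc$loops
  weak$support[weak$chromA == "chrS1" & weak$startA < 4e6] <- 1
  tads_w <- suppressMessages(locus_tads(sc$blocks, weak))
  expect_false(tads_w[[sc$truth$seed_block]]$active)

  # planted expressed genes are recovered exactly
  g <- genes_in_tads(tads, sc$genes)
  expect_setequal(g$per_block[[sc$truth$seed_block]],
                  c(sc$truth$expressed_in_tad, sc$truth$silent_in_tad))
  expect_equal(expressed_genes(g$pooled, sc$tpm),
               sc$truth$expressed_in_tad)
})
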