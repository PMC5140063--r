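test_that("read_bed parses BED3/BED6, sorts, and rejects malformed input", {
  p <- withr::local_tempfile()
  writeLines("chr1\t0\t100", p)
  gr <- read_bed(p)
  expect_equal(gr_df(gr), data.frame(chrom = "chr1", start = 0, end = 100))

  writeLines("chr1\t100\t100", p)
  expect_error(read_bed(p), "empty interval")

  writeLines(c("chr2\t500\t600", "chr2\t10\t20", "chr2\t100\t250"), p)
  expect_equal(gr_df(read_bed(p))$start, c(10, 100, 500))

  writeLines(c("chr1\t0\t100", "chr1\tfive\t200"), p)
  expect_error(read_bed(p), "line 2")

  writeLines("chr1\t10", p)
  expect_error(read_bed(p), "line 1")

  # BED6 metadata preserved
  writeLines("chr1\t10\t50\tpeak1\t7.5\t-", p)
  gr <- read_bed(p)
  expect_equal(S4Vectors::mcols(gr)$name, "peak1")
  expect_equal(S4Vectors::mcols(gr)$score, 7.5)
  expect_equal(as.character(GenomicRanges::strand(gr)), "-")
})

test_that("BED round-trips through write_bed and read_bed", {
  set.seed(11)
  for (k in 1:20) {
    df <- unique(random_intervals(15))
    gr <- df_to_gr(df)
    p <- tempfile(fileext = ".bed")
    write_bed(gr, p)
    expect_equal(gr_df(read_bed(p)), gr_df(gr))
    unlink(p)
  }
})

test_that("read_refflat derives the TSS from the strand and validates exons", {
  p <- withr::local_tempfile()
  writeLines(c(
    "GA\ttxA\tchr1\t+\t1000\t5000\t1000\t1000\t2\t1000,3000,\t2000,5000,",
    "GB\ttxB\tchr1\t-\t1000\t5000\t1000\t1000\t1\t1000,\t5000,"
  ), p)
  g <- read_refflat(p)
  expect_equal(g$tss, c(1000, 5000))
  expect_equal(g$exon_starts[[1]], c(1000, 3000))

  writeLines(
    "GC\ttxC\tchr1\t+\t0\t100\t0\t0\t2\t0,10,20,\t5,15,25,", p)
  expect_error(read_refflat(p), "exonCount")

  writeLines(
    "GD\ttxD\tchr1\t+\t100\t200\t100\t100\t1\t50,\t150,", p)
  expect_error(read_refflat(p), "outside")
})

test_that("refFlat writing round-trips gene models", {
  sim <- simulate_expression(small_cfg(3))
  p <- tempfile()
  write_refflat(sim$layout$genes, p)
  back <- read_refflat(p)
  expect_equal(back$gene_id, sim$layout$genes$gene_id)
  expect_equal(back$tss, sim$layout$genes$tss)
  expect_equal(back$exon_starts, sim$layout$genes$exon_starts,
               ignore_attr = TRUE)
  unlink(p)
})

test_that("subtract_regions removes whole regions on any overlap", {
  a <- gr0("chr1", 0, 100)
  b <- gr0("chr1", 50, 60)
  expect_length(subtract_regions(a, b), 0)

  b2 <- gr0("chr1", 200, 300)
  expect_equal(gr_df(subtract_regions(a, b2)),
               data.frame(chrom = "chr1", start = 0, end = 100))

  expect_length(subtract_regions(GenomicRanges::GRanges(), a), 0)
  # book-ended (zero-base overlap) is not an overlap
  expect_length(subtract_regions(gr0("chr1", 0, 50), gr0("chr1", 50, 80)), 1)
})

test_that("subtract_regions matches the per-base oracle on random sets", {
  set.seed(21)
  for (k in 1:60) {
    a <- random_intervals(sample(0:30, 1))
    b <- random_intervals(sample(0:30, 1))
    got <- gr_df(subtract_regions(df_to_gr(a), df_to_gr(b)))
    expect_equal(got, bf_subtract(sort_df(a), b), ignore_attr = TRUE)
  }
})

test_that("merge_within_gap stitches across gaps and is idempotent", {
  a <- gr0("chr1", c(0, 10000, 22000), c(2000, 12000, 24000))
  m <- merge_within_gap(a, 12500)
  expect_equal(gr_df(m), data.frame(chrom = "chr1", start = 0, end = 24000))
  expect_equal(S4Vectors::mcols(m)$n_constituents, 3)

  b <- gr0("chr1", c(0, 20000), c(1000, 21000))
  expect_equal(nrow(gr_df(merge_within_gap(b, 12500))), 2)

  single <- gr0("chr2", 5, 10)
  expect_equal(gr_df(merge_within_gap(single, 100)), gr_df(single))

  set.seed(31)
  for (k in 1:40) {
    df <- random_intervals(sample(1:30, 1))
    gap <- sample(c(0, 5, 50, 200), 1)
    m1 <- merge_within_gap(df_to_gr(df), gap)
    bf <- bf_merge(df, gap)
    expect_equal(gr_df(m1), bf[, c("chrom", "start", "end")],
                 ignore_attr = TRUE)
    expect_equal(S4Vectors::mcols(m1)$n_constituents, bf$n)
    # idempotence
    m2 <- merge_within_gap(m1, gap)
    expect_equal(gr_df(m2), gr_df(m1))
  }
})

test_that("extend_reads anchors at the 5' end, clips at 0, needs strand", {
  plus <- granges0("chr1", 100, 136, strand = "+")
  expect_equal(gr_df(extend_reads(plus, 300)),
               data.frame(chrom = "chr1", start = 100, end = 400))

  minus <- granges0("chr1", 100, 136, strand = "-")
  expect_equal(gr_df(extend_reads(minus, 300)),
               data.frame(chrom = "chr1", start = 0, end = 136))

  minus2 <- granges0("chr1", 500, 536, strand = "-")
  expect_equal(gr_df(extend_reads(minus2, 300)),
               data.frame(chrom = "chr1", start = 236, end = 536))

  expect_error(extend_reads(plus, 0), "> 0")
  unstranded <- granges0("chr1", 100, 136)
  expect_error(extend_reads(unstranded, 300), "strand")
})

test_that("nearest_distance is 0 inside peaks and edge distance outside", {
  tss <- granges0("chr1", c(1000, 3500), c(1001, 3501))
  peaks <- gr0("chr1", 3000, 4000)
  expect_equal(nearest_distance(tss, peaks), c(2000, 0))
  expect_error(nearest_distance(tss, GenomicRanges::GRanges()), "empty")
})
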