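tf_genes <- function() {
  # one long + gene, one - gene, far apart
  data.frame(
    gene_id = c("gp", "gm"), tx_id = c("gp", "gm"), chrom = "cT",
    strand = c("+", "-"),
    tx_start = c(10000, 100000), tx_end = c(20000, 110000),
    tss = c(10000, 110000),
    exon_starts = I(list(c(10000, 15000), c(100000, 108000))),
    exon_ends = I(list(c(11000, 16000), c(101000, 110000))),
    stringsAsFactors = FALSE
  )
}

test_that("peak annotation classifies midpoints with the stated priority", {
  genes <- tf_genes()
  peaks <- gr0("cT",
               c(10050, 13800, 15100, 21000, 50000, 107400),
               c(10250, 14200, 15500, 22000, 50400, 108000))
  ann <- annotate_peaks(peaks, genes)
  got <- ann$annotation
  expect_equal(got$class[got$start == 10050], "promoter")  # 150 b from TSS
  expect_equal(got$class[got$start == 13800], "intron")
  expect_equal(got$class[got$start == 15100], "exon")
  expect_equal(got$class[got$start == 21000], "tts_proximal")
  expect_equal(got$class[got$start == 50000], "intergenic")
  # midpoint 107700 is inside gm's intron but also in gm's promoter window
  # (TSS 110000): promoter wins
  expect_equal(got$class[got$start == 107400], "promoter")
  expect_equal(sum(ann$fractions), 1, tolerance = 1e-12)
})

test_that("annotation fractions always partition the peak set", {
  sim <- simulate_all(small_cfg(5))
  ann <- annotate_peaks(sim$tf$peaks, sim$layout$genes)
  expect_equal(sum(ann$fractions), 1, tolerance = 1e-12)
  # planted placement classes are recovered
  expect_equal(unname(ann$annotation$class), sim$tf$truth$class)
})

test_that("group enrichment counts peaks in group regulatory space", {
  genes <- tf_genes()
  k27 <- gr0("cT", c(9000, 109000), c(11000, 111000))
  peaks <- gr0("cT", c(9500, 50000), c(9900, 50400))
  groups <- list(gp = "gp", gm = "gm", none = character())
  e <- group_enrichment(peaks, peak_signal = c(200, 200), lib_size = 1e6,
                        h3k27ac = k27, groups = groups, genes = genes,
                        tss_window = 5000)
  expect_equal(e$n_peaks[e$group == "gp"], 1)
  expect_equal(e$n_peaks[e$group == "gm"], 0)
  expect_equal(e$rpkm[e$group == "gm"], 0)
  expect_true(e$flagged[e$group == "none"])

  # doubling the signal doubles RPKM, leaves counts unchanged
  e2 <- group_enrichment(peaks, peak_signal = c(400, 400), lib_size = 1e6,
                         h3k27ac = k27, groups = groups, genes = genes,
                         tss_window = 5000)
  expect_equal(e2$rpkm, 2 * e$rpkm)
  expect_equal(e2$n_peaks, e$n_peaks)

  # order invariance: permuting peaks leaves the summary unchanged
  e3 <- group_enrichment(peaks[2:1], peak_signal = c(200, 200),
                         lib_size = 1e6, h3k27ac = k27, groups = groups,
                         genes = genes, tss_window = 5000)
  expect_equal(e3, e)
})

test_that("nearest peak distance matches a brute-force all-pairs minimum", {
  genes <- tf_genes()
  peaks <- gr0("cT", c(12000, 13000), c(12500, 13500))
  d <- nearest_peak_distance(c("gp", "gm"), peaks, genes)
  expect_equal(d$distance[d$gene_id == "gp"], 2000)

  set.seed(91)
  for (k in 1:30) {
    df <- random_intervals(12, chroms = "cT", max_pos = 5000)
    tsspos <- sample.int(6000, 5) - 1
    g <- data.frame(gene_id = paste0("g", 1:5), tx_id = paste0("g", 1:5),
                    chrom = "cT", strand = "+", tx_start = tsspos,
                    tx_end = tsspos + 10, tss = tsspos,
                    exon_starts = I(as.list(tsspos)),
                    exon_ends = I(as.list(tsspos + 10)),
                    stringsAsFactors = FALSE)
    got <- nearest_peak_distance(g$gene_id, df_to_gr(df), g)
    for (i in 1:5) {
      p <- tsspos[i]
      dmin <- min(pmax(0, pmax(df$start - p, p - (df$end - 1))))
      expect_equal(got$distance[i], dmin)
    }
  }
})

test_that("planted TF enrichment favours BA-specific and common genes", {
  sim <- simulate_all(small_cfg(6))
  res <- run_pipeline(sim, params = pipeline_params(tf_tss_window = 3000))
  e <- res$tf$enrichment
  rpkm <- setNames(e$rpkm, e$group)
  expect_gt(rpkm["BA_specific"], rpkm["WA_specific"])
  expect_gt(rpkm["common"], rpkm["WA_specific"])
})
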