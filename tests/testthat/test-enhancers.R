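ref_genes <- function(tss = 20000, chrom = "chrT") {
  data.frame(gene_id = "g1", tx_id = "t1", chrom = chrom, strand = "+",
             tx_start = tss, tx_end = tss + 2000, tss = tss,
             exon_starts = I(list(tss)), exon_ends = I(list(tss + 2000)),
             stringsAsFactors = FALSE)
}

test_that("the enhancer universe excludes promoters and H3K4me3 regions", {
  genes <- ref_genes(20000)
  k27 <- list(s1 = gr0("chrT", c(0, 17000, 40000),
                       c(1000, 17600, 41000)))
  # region [17000,17600) overlaps the TSS window [17500, 22500) by 100 b
  k4 <- list(s1 = gr0("chrT", 0, 500))
  u <- build_enhancer_universe(k27, k4, genes)
  expect_equal(gr_df(u$regions),
               data.frame(chrom = "chrT", start = 40000, end = 41000))

  # distal H3K27ac with no H3K4me3 anywhere is retained
  u2 <- build_enhancer_universe(list(s1 = gr0("chrT", 40000, 41000)),
                                list(), genes)
  expect_equal(nrow(gr_df(u2$regions)), 1)

  # pooling union-merges stage peak sets
  u3 <- build_enhancer_universe(
    list(s1 = gr0("chrT", 40000, 41000), s2 = gr0("chrT", 40500, 41500)),
    list(), genes)
  expect_equal(gr_df(u3$regions),
               data.frame(chrom = "chrT", start = 40000, end = 41500))

  # a single-base TSS-window overlap excludes the region
  u4 <- build_enhancer_universe(
    list(s1 = gr0("chrT", c(17400, 40000), c(17501, 41000))), list(), genes)
  expect_equal(gr_df(u4$regions)$start, 40000)

  expect_error(build_enhancer_universe(list(), list(), genes), "H3K27ac")
})

test_that("stage-specific enhancer calls follow the z predicates", {
  df <- random_intervals(3, chroms = "cZ")
  z <- rbind(c(1.5, -0.2, -0.5, -0.3, -0.1),
             c(1.2, 0.5, 0.3, 0.2, 0.1),
             c(0.9, 0.9, 0.9, 0.9, 0.9))
  colnames(z) <- paste0("s", 1:5)
  u <- make_universe(df, z)
  # recover which output row is which input region via z values
  calls <- call_stage_specific_enhancers(u)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$stage, "s1")
  expect_equal(calls$z, 1.5)
})

test_that("calls equal brute force over regions x stages; z_high monotone", {
  set.seed(71)
  df <- random_intervals(200, chroms = "cZ", max_pos = 100000)
  df <- df[!duplicated(df[c("chrom", "start")]), ]
  z <- matrix(rnorm(nrow(df) * 5, 0, 1), nrow(df), 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  u <- make_universe(df, z)
  zs <- u$zscore$values
  calls <- call_stage_specific_enhancers(u)
  exp_keys <- character()
  for (i in seq_len(nrow(zs))) {
    for (j in 1:5) {
      if (zs[i, j] > 1 && sum(zs[i, -j] > 0) <= 3) {
        exp_keys <- c(exp_keys, paste(i, colnames(zs)[j]))
      }
    }
  }
  expect_setequal(paste(calls$region_idx, calls$stage), exp_keys)

  n_prev <- Inf
  for (zh in c(0.5, 1, 1.5, 2)) {
    n_now <- nrow(call_stage_specific_enhancers(u, z_high = zh))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("H3K4me1 concordance separates co-placed from independent marks", {
  set.seed(72)
  df <- random_intervals(150, chroms = "cZ", max_pos = 100000)
  df <- df[!duplicated(df[c("chrom", "start")]), ]
  n <- nrow(df)
  z27 <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("s", 1:5)))
  z27[1:30, 1] <- 2.5   # strong stage-1 enhancers
  u <- make_universe(df, z27)
  calls <- call_stage_specific_enhancers(u)

  # co-placed companion mark: same signal plus small noise
  co <- u$zscore$values + matrix(rnorm(n * 5, 0, 0.2), n, 5)
  m_co <- signal_matrix(u$regions, co, unit = "zscore",
                        zscore_axis = "per_stage_across_regions")
  conc <- h3k4me1_concordance(m_co, calls)
  expect_gt(conc$frac_concordant[conc$stage == "s1"], 0.9)
  expect_gt(conc$mean_z_called[conc$stage == "s1"],
            conc$mean_z_universe[conc$stage == "s1"])

  # independent companion mark: concordance near the background P(z > 0)
  ind <- matrix(rnorm(n * 5), n, 5, dimnames = dimnames(co))
  m_ind <- signal_matrix(u$regions, ind, unit = "zscore",
                         zscore_axis = "per_stage_across_regions")
  conc2 <- h3k4me1_concordance(m_ind, calls)
  f <- conc2$frac_concordant[conc2$stage == "s1"]
  expect_gt(f, 0.25)
  expect_lt(f, 0.75)

  # empty call list gives an empty table
  empty <- h3k4me1_concordance(m_co, calls[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(h3k4me1_concordance(NULL, calls), "missing")
})
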