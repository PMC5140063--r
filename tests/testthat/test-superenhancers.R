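test_that("stitching filters by activity, merges, and applies span filter", {
  df <- data.frame(chrom = "cS", start = c(0, 10000, 22000, 50000),
                   end = c(2000, 12000, 24000, 51000))
  z <- matrix(c(1, 1, 1, -0.5), 4, 1, dimnames = list(NULL, "d7"))
  u <- make_universe(df, z)
  st <- stitch_active_enhancers(u, "d7")
  expect_equal(gr_df(st$regions),
               data.frame(chrom = "cS", start = 0, end = 24000))
  expect_equal(S4Vectors::mcols(st$regions)$n_constituents, 3)

  # short stitched spans are dropped
  df2 <- data.frame(chrom = "cS", start = c(0, 5000), end = c(1000, 6000))
  u2 <- make_universe(df2, matrix(1, 2, 1, dimnames = list(NULL, "d7")))
  expect_length(stitch_active_enhancers(u2, "d7")$regions, 0)

  expect_error(stitch_active_enhancers(u, "nope"), "unknown stage")
})

test_that("stitch + span filter equals the brute-force oracle", {
  set.seed(81)
  for (k in 1:60) {
    df <- random_intervals(sample(2:25, 1), chroms = "cS", max_pos = 3000,
                           max_len = 100)
    df <- df[!duplicated(df[c("chrom", "start")]), , drop = FALSE]
    z <- matrix(rnorm(nrow(df)), nrow(df), 1, dimnames = list(NULL, "d7"))
    gap <- sample(c(100, 300, 800), 1)
    span <- sample(c(200, 500), 1)
    u <- make_universe(df, z)
    got <- gr_df(stitch_active_enhancers(u, "d7", gap = gap,
                                         min_span = span)$regions)
    # oracle: filter on the sorted z, O(n^2) merge, strict span filter
    zs <- u$zscore$values[, 1]
    act <- gr_df(u$regions)[zs > 0, , drop = FALSE]
    bf <- bf_merge(act, gap)
    bf <- bf[bf$end - bf$start > span, c("chrom", "start", "end")]
    expect_equal(got, sort_df(bf), ignore_attr = TRUE)
  }
})

test_that("slope ranking cuts at the entry to the high-signal regime", {
  r <- rank_and_cut(c(1, 1, 1, 1, 100))
  expect_equal(r$is_se, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  flat <- rank_and_cut(rep(3, 6))
  expect_false(any(flat$is_se))

  # raising the threshold never adds SEs
  set.seed(82)
  for (k in 1:30) {
    sig <- rlnorm(sample(3:40, 1), 1, 1.5)
    prev <- rank_and_cut(sig, slope_threshold = 0.5)
    for (thr in c(1, 2, 4)) {
      now <- rank_and_cut(sig, slope_threshold = thr)
      expect_true(all(now$signal[now$is_se] %in% prev$signal[prev$is_se]))
      expect_lte(sum(now$is_se), sum(prev$is_se))
      # the SE set is a suffix of the ranked list
      if (any(now$is_se)) {
        expect_true(all(now$is_se[min(which(now$is_se)):nrow(now)]))
      }
      prev <- now
    }
  }

  expect_warning(r1 <- rank_and_cut(5), "fewer than 2")
  expect_false(any(r1$is_se))
})

test_that("late-specific SEs drop any overlap with early-stage SEs", {
  d7 <- data.frame(chrom = "cS", start = c(0, 10000, 30000),
                   end = c(5000, 15000, 44000),
                   is_se = c(TRUE, TRUE, FALSE))
  early <- list(data.frame(chrom = "cS", start = 4999, end = 6000,
                           is_se = TRUE))
  late <- late_specific_ses(d7, early)
  # one-base overlap removes; the non-SE row is ignored entirely
  expect_equal(late$start, 10000)

  # no early SEs: all d7 SEs retained
  expect_equal(nrow(late_specific_ses(d7, list())), 2)

  # random fixtures against an all-pairs overlap filter
  set.seed(83)
  for (k in 1:40) {
    a <- random_intervals(10); a$is_se <- runif(10) < 0.7
    b <- random_intervals(8); b$is_se <- runif(8) < 0.5
    got <- late_specific_ses(a, list(b))
    sub <- a[a$is_se, ]
    keep <- logical(nrow(sub))
    bb <- b[b$is_se, ]
    for (i in seq_len(nrow(sub))) {
      ov <- any(bb$chrom == sub$chrom[i] & bb$start < sub$end[i] &
                  bb$end > sub$start[i])
      keep[i] <- !ov
    }
    expect_equal(got$start, sub$start[keep])
  }
})

test_that("target assignment follows window, correlation and fallback rules", {
  ses <- data.frame(chrom = "cS", start = 1e6, end = 1e6 + 30000)
  se_signal <- matrix(c(1, 1, 2, 8, 10), 1, 5,
                      dimnames = list(NULL, paste0("s", 1:5)))
  mk_gene <- function(id, tss) {
    data.frame(gene_id = id, tx_id = id, chrom = "cS", strand = "+",
               tx_start = tss, tx_end = tss + 1000, tss = tss,
               exon_starts = I(list(tss)), exon_ends = I(list(tss + 1000)),
               stringsAsFactors = FALSE)
  }
  genes <- rbind(mk_gene("perfect", 1e6 + 40000),
                 mk_gene("far", 1e6 + 230000),
                 mk_gene("weak_a", 1e6 - 50000),
                 mk_gene("weak_b", 1e6 - 60000))
  expr <- rbind(perfect = 2 * se_signal[1, ],
                far = 100 * se_signal[1, ],
                weak_a = c(6, 3, 2, 7, 6),    # r ~ 0.62
                weak_b = c(8, 6, 4, 3, 2))    # r < 0
  colnames(expr) <- paste0("s", 1:5)

  got <- assign_se_targets(ses, se_signal, expr, genes)
  # perfect correlation inside the window: corr_primary; the r = 0.99 gene
  # 200 kb away is never considered
  expect_true("perfect" %in% got$target)
  expect_false("far" %in% got$target)
  expect_equal(got$mode[got$target == "perfect"], "corr_primary")
  expect_equal(got$r[got$target == "perfect"], 1)

  # fallback: with the perfect gene removed, only the best r > 0.5 gene
  got2 <- assign_se_targets(ses, se_signal, expr[c("weak_a", "weak_b"), ],
                            genes[3:4, ])
  expect_equal(got2$target, "weak_a")
  expect_equal(got2$mode, "corr_fallback")

  # constant expression profiles are never assigned
  flat <- matrix(8, 1, 5, dimnames = list("flat", paste0("s", 1:5)))
  got3 <- assign_se_targets(ses, se_signal, flat, mk_gene("flat", 1e6))
  expect_equal(nrow(got3), 0)

  # stage grids must match
  expr_bad <- expr
  colnames(expr_bad) <- paste0("x", 1:5)
  expect_error(assign_se_targets(ses, se_signal, expr_bad, genes),
               "stage grids")

  # miRNAs inside the window are all assigned
  mir <- data.frame(gene_id = "mirX", chrom = "cS", tss = 1e6 + 5000,
                    stringsAsFactors = FALSE)
  got4 <- assign_se_targets(ses, se_signal, expr[0, , drop = FALSE],
                            genes[0, ], mirna_tss = mir)
  expect_equal(got4$mode, "mirna_window")
  expect_equal(got4$distance, 0)
})

test_that("assignment correlations match the textbook formula", {
  set.seed(84)
  ses <- data.frame(chrom = "cS", start = 0, end = 10000)
  for (k in 1:25) {
    sig <- matrix(rlnorm(5), 1, 5, dimnames = list(NULL, paste0("s", 1:5)))
    e <- matrix(rlnorm(5), 1, 5,
                dimnames = list("g", paste0("s", 1:5)))
    genes <- data.frame(gene_id = "g", tx_id = "g", chrom = "cS",
                        strand = "+", tx_start = 20000, tx_end = 21000,
                        tss = 20000, exon_starts = I(list(20000)),
                        exon_ends = I(list(21000)), stringsAsFactors = FALSE)
    got <- assign_se_targets(ses, sig, e, genes, r_primary = -2,
                             r_fallback = -2, expr_min = 0)
    expect_equal(got$r, bf_pearson(sig[1, ], e[1, ]), tolerance = 1e-10)
  }
})

test_that("nearest-gene assignment reports minima and flags ties", {
  ses <- data.frame(chrom = "cS", start = 10000, end = 20000)
  mk <- function(id, tss, chrom = "cS") {
    data.frame(gene_id = id, tx_id = id, chrom = chrom, strand = "+",
               tx_start = tss, tx_end = tss + 100, tss = tss,
               exon_starts = I(list(tss)), exon_ends = I(list(tss + 100)),
               stringsAsFactors = FALSE)
  }
  inside <- rbind(mk("in", 15000), mk("near", 25000))
  got <- assign_nearest_gene(ses, inside)
  expect_equal(got$target, "in")
  expect_equal(got$distance, 0)

  two <- rbind(mk("at5k", 25000), mk("at8k", 28000))
  expect_equal(assign_nearest_gene(ses, two)$target, "at5k")

  tie <- rbind(mk("left", 5000), mk("right", 24999))
  got <- assign_nearest_gene(ses, tie)
  expect_equal(sort(got$target), c("left", "right"))
  expect_true(all(got$tie))
})
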