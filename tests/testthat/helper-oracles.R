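# Brute-force oracles and small-fixture helpers. Every oracle here is an
# independent, naive restatement of the operation it checks (per-base
# vectors, O(n^2) loops, textbook formulas) and never calls the package's
# own implementation.

gr0 <- function(chrom, start, end, ...) granges0(chrom, start, end, ...)

gr_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

sort_df <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random interval set on small coordinate space (per-base oracles stay fast)
random_intervals <- function(n, chroms = c("cA", "cB"), max_pos = 500,
                             max_len = 60) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) granges0(df$chrom, df$start, df$end)

# per-base region-level subtraction: drop every interval of a touching
# covered bases of b
bf_subtract <- function(a, b, space = 2000) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    bsub <- b[b$chrom == a$chrom[i], , drop = FALSE]
    cov <- logical(space)
    for (j in seq_len(nrow(bsub))) {
      cov[(bsub$start[j] + 1):bsub$end[j]] <- TRUE
    }
    keep[i] <- !any(cov[(a$start[i] + 1):a$end[i]])
  }
  sort_df(a[keep, , drop = FALSE])
}

# O(n^2) transitive merge of intervals with end-to-start gap <= max_gap:
# union-find over all interval pairs, repeated until stable
bf_merge <- function(df, max_gap) {
  if (nrow(df) == 0L) return(df)
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    g <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (g[i] == g[j]) next
          gap <- max(sub$start[i], sub$start[j]) -
            min(sub$end[i], sub$end[j])
          if (gap <= max_gap) {
            g[g == g[j]] <- g[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    for (grp in unique(g)) {
      idx <- which(g == grp)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(sub$start[idx]), end = max(sub$end[idx]),
        n = length(idx), stringsAsFactors = FALSE)
    }
  }
  sort_df(do.call(rbind, out))
}

# direct evaluation of the entropy formula, scalar arithmetic only
bf_entropy <- function(e) {
  tot <- sum(e)
  if (tot == 0) return(NA_real_)
  h <- 0
  for (v in e) {
    r <- v / tot
    if (r > 0) h <- h - r * log2(r)
  }
  h
}

# textbook Pearson correlation
bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# enhancer-universe stand-in for unit tests: fabricated z and rpkm matrices
make_universe <- function(df, z, rpkm = NULL, stages = colnames(z)) {
  regions <- df_to_gr(df)
  o <- order(df$chrom, df$start)      # granges0 sorts; align matrices
  z <- z[o, , drop = FALSE]
  if (is.null(rpkm)) rpkm <- pmax(z, 0) + 1
  else rpkm <- rpkm[o, , drop = FALSE]
  structure(list(
    regions = regions, stages = stages,
    rpkm = signal_matrix(regions, rpkm, stages = stages, unit = "rpkm",
                         lib_sizes = stats::setNames(rep(1e6, length(stages)),
                                                     stages)),
    zscore = signal_matrix(regions, z, stages = stages, unit = "zscore",
                           zscore_axis = "per_stage_across_regions")
  ), class = "enhancer_universe")
}

# compact simulation config for structural / determinism tests
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 400, n_per_stage = 4,
             n_ba_specific = 8, n_wa_specific = 8, n_common = 8,
             n_bmp7 = 6, n_se = 3, n_enh_per_stage = 6, n_typical = 60,
             n_weak_clusters = 3, n_lncrna = 60, n_lnc_per_stage = 3,
             n_lnc_lineage = 5, n_mirna = 40, n_mirna_per_stage = 3,
             reads_per_stage = 1e5, reads_per_stage_minor = 3e4, ...)
}
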