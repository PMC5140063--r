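#' Stitch active enhancers into super-enhancer candidates
#'
#' For a focal stage, takes the universe regions active in that stage
#' (z > `z_active`), transitively merges those within `gap` bases of each
#' other, and keeps stitched spans strictly larger than `min_span` bases
#' (the span is the merged genomic extent, gaps included). Per-stage RPKM
#' is then recomputed over the merged spans.
#'
#' @param u an `enhancer_universe` with both rpkm and zscore matrices.
#' @param stage focal stage label.
#' @param gap stitching gap in bases (default 12500).
#' @param min_span minimum span in bases, strict (default 12500).
#' @param z_active activity cutoff (default 0, strict).
#' @param reads optional per-stage read list; when given, candidate RPKM is
#'   re-quantified from reads over the merged spans, otherwise it is the
#'   width-weighted RPKM of the constituents.
#' @return A list of class `stitched_enhancers`: `regions` (`GRanges` with
#'   `n_constituents`), `rpkm` (`signal_matrix` over the spans), `stage`,
#'   `signal` (focal-stage RPKM per span).
#' @export
stitch_active_enhancers <- function(u, stage, gap = 12500, min_span = 12500,
                                    z_active = 0, reads = NULL) {
  z <- universe_zscore(u)
  if (!stage %in% z$stages) stop("unknown stage: ", stage)
  active <- z$values[, stage] > z_active
  out <- list(regions = GenomicRanges::GRanges(), rpkm = NULL,
              stage = stage, signal = numeric(0))
  class(out) <- "stitched_enhancers"
  if (!any(active)) return(out)
  act_gr <- z$regions[active]
  stitched <- merge_within_gap(act_gr, gap)
  keep <- GenomicRanges::width(stitched) > min_span
  stitched <- stitched[keep]
  if (length(stitched) == 0L) return(out)
  if (!is.null(reads)) {
    rp <- quantify_rpkm(drop_mcols(stitched), reads = reads)
  } else {
    # width-weighted aggregation of constituent RPKM over each span
    rpk <- u$rpkm
    if (is.null(rpk)) stop("universe carries no rpkm matrix")
    w <- GenomicRanges::width(act_gr)
    counts_like <- rpk$values[active, , drop = FALSE] * w
    ov <- GenomicRanges::findOverlaps(act_gr, stitched, ignore.strand = TRUE)
    grp <- integer(length(act_gr))
    grp[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
    keep_c <- grp > 0                     # constituents of retained spans
    agg <- rowsum(counts_like[keep_c, , drop = FALSE], group = grp[keep_c])
    vals <- agg / GenomicRanges::width(stitched)
    rp <- signal_matrix(drop_mcols(stitched), vals, stages = rpk$stages,
                        unit = "rpkm", lib_sizes = rpk$lib_sizes)
  }
  out$regions <- stitched
  out$rpkm <- rp
  out$signal <- rp$values[, stage]
  out
}

#' Rank super-enhancer candidates and cut by slope
#'
#' Candidates are sorted by ascending focal-stage signal; rank and signal
#' are each rescaled to the unit interval. Scanning from the low-rank end,
#' the cut sits at the first point whose forward discrete slope exceeds
#' `slope_threshold` and from which the remaining curve stays above the
#' line of that slope (so the crossing marks the entry into the high-signal
#' regime, not a local blip). Every candidate beyond the crossing is a
#' super-enhancer; the SE set is always a suffix of the ranked list.
#'
#' @param candidates a `stitched_enhancers` object (or a numeric vector of
#'   focal-stage signals).
#' @param slope_threshold slope cutoff on the unit square (default 0.5).
#' @return data.frame, one row per candidate in ascending signal order:
#'   `rank` (1 = weakest), `signal`, `rank_scaled`, `signal_scaled`,
#'   `is_se`, plus coordinates when a `stitched_enhancers` was given.
#'   With fewer than 2 candidates all are flagged non-SE with a warning.
#' @export
rank_and_cut <- function(candidates, slope_threshold = 0.5) {
  sig <- if (inherits(candidates, "stitched_enhancers")) {
    candidates$signal
  } else {
    as.numeric(candidates)
  }
  n <- length(sig)
  ord <- order(sig)
  out <- data.frame(rank = seq_len(n), signal = sig[ord])
  if (inherits(candidates, "stitched_enhancers") && n > 0) {
    gr <- candidates$regions[ord]
    out$chrom <- as.character(GenomicRanges::seqnames(gr))
    out$start <- GenomicRanges::start(gr) - 1L
    out$end <- GenomicRanges::end(gr)
  }
  if (n < 2L) {
    if (n > 0L) warning("fewer than 2 candidates; none called SE")
    out$rank_scaled <- if (n) 0 else numeric(0)
    out$signal_scaled <- if (n) 0 else numeric(0)
    out$is_se <- rep(FALSE, n)
    attr(out, "cut_index") <- NA_integer_
    return(out)
  }
  x <- (out$rank - 1) / (n - 1)
  rng <- range(out$signal)
  y <- if (diff(rng) > 0) (out$signal - rng[1]) / diff(rng) else rep(0, n)
  cut_idx <- se_slope_crossing(x, y, slope_threshold)
  out$rank_scaled <- x
  out$signal_scaled <- y
  out$is_se <- if (is.na(cut_idx)) rep(FALSE, n) else out$rank >= cut_idx
  attr(out, "cut_index") <- cut_idx
  out
}

# The slope-crossing geometry, isolated so alternative conventions can be
# swapped: returns the index of the first point of the high-signal regime,
# i.e. i+1 for the first i (scanning from rank 0) whose forward slope
# exceeds `thr` while every later point stays above the line through point
# i with slope `thr`. NA when no crossing exists.
se_slope_crossing <- function(x, y, thr) {
  n <- length(x)
  for (i in seq_len(n - 1)) {
    slope_fwd <- (y[i + 1] - y[i]) / (x[i + 1] - x[i])
    if (slope_fwd > thr) {
      later <- (i + 1):n
      if (all(y[later] > y[i] + thr * (x[later] - x[i]))) {
        return(i + 1L)
      }
    }
  }
  NA_integer_
}

#' Late-stage-specific super-enhancers
#'
#' Returns the day-7 SEs that do not overlap (by even one base) any SE
#' called at an earlier stage (BA: d-3, d0, 6h; WA: d-2/d-4, d0).
#'
#' @param d7_ses data.frame from [rank_and_cut()] for the d7 stage (rows
#'   with `is_se = TRUE` are considered; others are ignored).
#' @param early_ses list of data.frames from [rank_and_cut()] for the early
#'   stages.
#' @return The subset of `d7_ses` SE rows with no early-stage SE overlap.
#' @export
late_specific_ses <- function(d7_ses, early_ses) {
  d7 <- d7_ses[d7_ses$is_se, , drop = FALSE]
  if (nrow(d7) == 0L) return(d7)
  early <- do.call(rbind, lapply(early_ses, function(df) {
    if (!all(c("chrom", "start", "end") %in% names(df))) return(NULL)
    df[df$is_se, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (is.null(early) || nrow(early) == 0L) return(d7)
  # built unsorted so rows keep their correspondence with d7
  d7_gr <- GenomicRanges::GRanges(d7$chrom,
                                  IRanges::IRanges(d7$start + 1, d7$end))
  early_gr <- GenomicRanges::GRanges(early$chrom,
                                     IRanges::IRanges(early$start + 1,
                                                      early$end))
  hit <- suppressWarnings(
    IRanges::overlapsAny(d7_gr, early_gr, ignore.strand = TRUE))
  d7[!hit, , drop = FALSE]
}

#' Assign target genes to super-enhancers by expression correlation
#'
#' Candidate targets are expressed genes (FPKM > `expr_min` in at least one
#' stage) whose TSS lies within `window` bases of the SE span (distance 0
#' inside). Every candidate whose Pearson correlation between its FPKM
#' profile and the SE's per-stage RPKM exceeds `r_primary` is assigned
#' (mode `corr_primary`); if none qualifies, the single best candidate with
#' r above `r_fallback` is assigned (mode `corr_fallback`). miRNAs inside
#' the window are all assigned (mode `mirna_window`) when a miRNA TSS table
#' is supplied. Constant profiles have undefined correlation and are never
#' assigned.
#'
#' @param ses data.frame of SE rows (needs `chrom`, `start`, `end`; e.g.
#'   the `is_se` rows of [rank_and_cut()] output).
#' @param se_signal matrix of SE per-stage signal, rows parallel to `ses`.
#' @param expr gene x stage FPKM matrix (rownames = gene ids), same stage
#'   grid as `se_signal`.
#' @param genes gene-model data.frame (TSS positions for the genes in
#'   `expr`).
#' @param window maximum TSS-to-SE-edge distance in bases (default 1e5).
#' @param r_primary,r_fallback correlation cutoffs (defaults 0.75, 0.5,
#'   both strict).
#' @param expr_min expression cutoff (default 1 FPKM, strict).
#' @param mirna_tss optional gene-model-style data.frame of miRNA loci.
#' @return data.frame: `se_idx`, `chrom`, `start`, `end`, `target`, `r`,
#'   `mode`, `distance`.
#' @export
assign_se_targets <- function(ses, se_signal, expr, genes, window = 1e5,
                              r_primary = 0.75, r_fallback = 0.5,
                              expr_min = 1, mirna_tss = NULL) {
  se_signal <- as.matrix(se_signal)
  expr <- as.matrix(expr)
  if (!identical(colnames(se_signal), colnames(expr))) {
    stop("SE signal and expression matrices use different stage grids")
  }
  empty <- data.frame(se_idx = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      target = character(), r = numeric(),
                      mode = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(ses) == 0L) return(empty)
  expressed <- rownames(expr)[apply(expr, 1, max) > expr_min]
  g <- genes[genes$gene_id %in% expressed, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(ses))) {
    se_start <- ses$start[k]
    se_end <- ses$end[k]
    near <- g$chrom == ses$chrom[k] &
      g$tss >= se_start - window & g$tss < se_end + window
    cand <- g[near, , drop = FALSE]
    add_row <- function(target, r, mode, dist) {
      rows[[length(rows) + 1L]] <<- data.frame(
        se_idx = k, chrom = ses$chrom[k], start = se_start, end = se_end,
        target = target, r = r, mode = mode, distance = dist,
        stringsAsFactors = FALSE)
    }
    if (nrow(cand) > 0L) {
      rvals <- vapply(cand$gene_id, function(id) {
        pearson_or_na(se_signal[k, ], expr[id, ])
      }, 0)
      dists <- pmax(0, pmax(se_start - cand$tss, cand$tss - (se_end - 1)))
      primary <- which(!is.na(rvals) & rvals > r_primary)
      if (length(primary)) {
        for (i in primary) {
          add_row(cand$gene_id[i], rvals[i], "corr_primary", dists[i])
        }
      } else {
        ok <- which(!is.na(rvals) & rvals > r_fallback)
        if (length(ok)) {
          i <- ok[which.max(rvals[ok])]
          add_row(cand$gene_id[i], rvals[i], "corr_fallback", dists[i])
        }
      }
    }
    if (!is.null(mirna_tss)) {
      nearm <- mirna_tss$chrom == ses$chrom[k] &
        mirna_tss$tss >= se_start - window & mirna_tss$tss < se_end + window
      for (i in which(nearm)) {
        d <- max(0, max(se_start - mirna_tss$tss[i],
                        mirna_tss$tss[i] - (se_end - 1)))
        add_row(mirna_tss$gene_id[i], NA_real_, "mirna_window", d)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  out
}

# Pearson correlation; NA when either profile is constant (internal)
pearson_or_na <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Assign the nearest gene to each super-enhancer
#'
#' The gene whose TSS is closest to the SE span (distance 0 inside) is the
#' potential target; exact distance ties are all reported and flagged.
#'
#' @param ses data.frame of SE rows (`chrom`, `start`, `end`).
#' @param genes gene-model data.frame.
#' @return data.frame: `se_idx`, `chrom`, `start`, `end`, `target`,
#'   `distance`, `tie`.
#' @export
assign_nearest_gene <- function(ses, genes) {
  rows <- list()
  for (k in seq_len(nrow(ses))) {
    on_chrom <- genes[genes$chrom == ses$chrom[k], , drop = FALSE]
    if (nrow(on_chrom) == 0L) next
    d <- pmax(0, pmax(ses$start[k] - on_chrom$tss,
                      on_chrom$tss - (ses$end[k] - 1)))
    dmin <- min(d)
    hits <- which(d == dmin)
    rows[[length(rows) + 1L]] <- data.frame(
      se_idx = k, chrom = ses$chrom[k], start = ses$start[k],
      end = ses$end[k], target = on_chrom$gene_id[hits], distance = dmin,
      tie = length(hits) > 1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(se_idx = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      target = character(), distance = numeric(),
                      tie = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
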