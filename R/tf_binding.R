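#' Annotate TF peaks against genome elements
#'
#' Each peak is classified by its midpoint with the priority
#' promoter (TSS +- `promoter_pad`) > exon > intron >
#' TTS-proximal (transcript end +- `promoter_pad`) > intergenic, so every
#' peak receives exactly one class and the class fractions over a peak set
#' sum to 1.
#'
#' @param peaks a `GRanges` of TF peaks.
#' @param genes gene-model data.frame (exon structure required).
#' @param promoter_pad half-width of the promoter / TTS windows
#'   (default 2500).
#' @return A list: `annotation` (data.frame with `chrom`, `start`, `end`,
#'   `midpoint`, `class`, `host_gene`) and `fractions` (named class
#'   fractions).
#' @export
annotate_peaks <- function(peaks, genes, promoter_pad = 2500) {
  classes <- c("promoter", "exon", "intron", "tts_proximal", "intergenic")
  n <- length(peaks)
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  mid <- floor((start0 + end0) / 2)           # 0-based midpoint position
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  cls <- rep("intergenic", n)
  host <- rep(NA_character_, n)
  tts <- ifelse(genes$strand == "+", genes$tx_end, genes$tx_start)
  for (i in seq_len(n)) {
    p <- mid[i]
    # any class window lies within [tx_start - pad, tx_end + pad)
    on_chrom <- which(genes$chrom == chrom[i] &
                        p >= genes$tx_start - promoter_pad &
                        p < genes$tx_end + promoter_pad)
    hit_class <- "intergenic"
    hit_gene <- NA_character_
    best <- length(classes)                   # current priority (lower wins)
    for (gi in on_chrom) {
      cand <- NULL
      if (p >= genes$tss[gi] - promoter_pad &&
          p < genes$tss[gi] + promoter_pad) {
        cand <- "promoter"
      } else if (p >= genes$tx_start[gi] && p < genes$tx_end[gi]) {
        in_exon <- any(p >= genes$exon_starts[[gi]] &
                         p < genes$exon_ends[[gi]])
        cand <- if (in_exon) "exon" else "intron"
      } else if (p >= tts[gi] - promoter_pad && p < tts[gi] + promoter_pad) {
        cand <- "tts_proximal"
      }
      if (!is.null(cand)) {
        rank <- match(cand, classes)
        if (rank < best) {
          best <- rank
          hit_class <- cand
          hit_gene <- genes$gene_id[gi]
          if (best == 1L) break
        }
      }
    }
    cls[i] <- hit_class
    host[i] <- hit_gene
  }
  ann <- data.frame(chrom = chrom, start = start0, end = end0,
                    midpoint = mid, class = cls, host_gene = host,
                    stringsAsFactors = FALSE)
  frac <- as.numeric(table(factor(cls, levels = classes))) / max(n, 1L)
  names(frac) <- classes
  list(annotation = ann, fractions = frac)
}

#' TF peak enrichment at gene groups
#'
#' For each gene group, regulatory regions are the H3K27ac peaks within
#' `tss_window` of any group TSS; the enrichment is the number of TF peaks
#' overlapping those regions and the summed RPKM of those peaks.
#'
#' @param peaks `GRanges` of TF peaks.
#' @param peak_signal per-peak read counts (parallel to `peaks`), or `NULL`
#'   to count reads from `peak_reads`.
#' @param peak_reads optional `GRanges` of TF read intervals (used when
#'   `peak_signal` is `NULL`); also sets the library size.
#' @param lib_size total TF reads for the RPKM denominator (required with
#'   `peak_signal`).
#' @param h3k27ac `GRanges` of pooled H3K27ac peaks defining regulatory
#'   space.
#' @param groups named list of gene-id vectors.
#' @param genes gene-model data.frame.
#' @param tss_window TSS neighborhood in bases (default 1e5).
#' @return data.frame per group: `n_genes`, `n_regions`, `n_peaks`,
#'   `rpkm`, `flagged` (TRUE for empty groups).
#' @export
group_enrichment <- function(peaks, peak_signal = NULL, peak_reads = NULL,
                             lib_size = NULL, h3k27ac, groups, genes,
                             tss_window = 1e5) {
  if (is.null(peak_signal)) {
    if (is.null(peak_reads)) stop("supply peak_signal or peak_reads")
    peak_signal <- GenomicRanges::countOverlaps(peaks, peak_reads,
                                                ignore.strand = TRUE)
    if (is.null(lib_size)) lib_size <- length(peak_reads)
  }
  if (is.null(lib_size)) stop("lib_size required with precomputed signal")
  widths_kb <- GenomicRanges::width(peaks) / 1000
  peak_rpkm <- peak_signal / (widths_kb * lib_size / 1e6)
  rows <- lapply(names(groups), function(grp) {
    ids <- groups[[grp]]
    gsub <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(gsub) == 0L) {
      return(data.frame(group = grp, n_genes = 0L, n_regions = 0L,
                        n_peaks = 0L, rpkm = 0, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    win <- granges0(gsub$chrom, pmax(gsub$tss - tss_window, 0),
                    gsub$tss + tss_window)
    reg <- h3k27ac[IRanges::overlapsAny(h3k27ac, win,
                                              ignore.strand = TRUE)]
    hit <- IRanges::overlapsAny(peaks, reg, ignore.strand = TRUE)
    data.frame(group = grp, n_genes = nrow(gsub), n_regions = length(reg),
               n_peaks = sum(hit), rpkm = sum(peak_rpkm[hit]),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance from each gene's TSS to its closest TF peak
#'
#' @param gene_ids gene ids to score.
#' @param peaks non-empty `GRanges` of TF peaks.
#' @param genes gene-model data.frame.
#' @return data.frame: `gene_id`, `distance` (0 when the TSS lies inside a
#'   peak; `NA` when the gene's chromosome has no peak).
#' @export
nearest_peak_distance <- function(gene_ids, peaks, genes) {
  if (length(peaks) == 0L) stop("peak set is empty")
  gsub <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  tss <- GenomicRanges::GRanges(gsub$chrom,
                                IRanges::IRanges(gsub$tss + 1, gsub$tss + 1))
  data.frame(gene_id = gene_ids,
             distance = nearest_distance(tss, peaks),
             stringsAsFactors = FALSE)
}
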