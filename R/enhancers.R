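#' Build the candidate enhancer universe
#'
#' Pools H3K27ac peaks across all stages of a lineage (union-merge), pools
#' H3K4me3 peaks likewise, and removes every pooled H3K27ac region that
#' overlaps a pooled H3K4me3 region or any TSS +- `tss_pad` window by at
#' least one base. What remains is the distal candidate enhancer universe;
#' per-stage H3K27ac signal is then quantified over it when read data is
#' supplied.
#'
#' @param h3k27ac_peaks named list of per-stage `GRanges` peak sets.
#' @param h3k4me3_peaks named list of per-stage `GRanges` peak sets (may be
#'   empty list).
#' @param genes gene-model data.frame; every transcript TSS contributes an
#'   exclusion window.
#' @param tss_pad TSS exclusion half-width in bases (default 2500).
#' @param reads optional named per-stage list of read-interval `GRanges`
#'   (already extended); when given, the returned universe carries an rpkm
#'   and a zscore `signal_matrix`.
#' @param zscore_axis axis for [zscore_normalize()] (default per stage
#'   across regions).
#' @return A list of class `enhancer_universe`: `regions` (`GRanges`),
#'   `stages`, and (with reads) `rpkm`, `zscore`.
#' @export
build_enhancer_universe <- function(h3k27ac_peaks, h3k4me3_peaks, genes,
                                    tss_pad = 2500, reads = NULL,
                                    zscore_axis = "per_stage_across_regions") {
  if (length(h3k27ac_peaks) == 0L ||
      sum(lengths(h3k27ac_peaks)) == 0L) {
    stop("no H3K27ac peaks supplied")
  }
  pooled_ac <- merge_within_gap(
    do.call(c, unname(lapply(h3k27ac_peaks, drop_mcols))), 0)
  excl <- promoter_windows(genes, pad = tss_pad)
  if (length(h3k4me3_peaks) && sum(lengths(h3k4me3_peaks)) > 0L) {
    pooled_me3 <- merge_within_gap(
      do.call(c, unname(lapply(h3k4me3_peaks, drop_mcols))), 0)
    excl <- c(drop_mcols(pooled_me3), drop_mcols(excl))
  }
  universe <- subtract_regions(drop_mcols(pooled_ac), excl)
  out <- list(regions = universe, stages = names(h3k27ac_peaks),
              rpkm = NULL, zscore = NULL)
  class(out) <- "enhancer_universe"
  if (!is.null(reads)) {
    out$stages <- names(reads)
    out$rpkm <- quantify_rpkm(universe, reads = reads)
    out$zscore <- zscore_normalize(out$rpkm, axis = zscore_axis)
  }
  out
}

#' @export
print.enhancer_universe <- function(x, ...) {
  cat("enhancer_universe:", length(x$regions), "regions;",
      if (is.null(x$zscore)) "no signal quantified" else
        paste0("signal over stages ", paste(x$stages, collapse = ", ")),
      "\n")
  invisible(x)
}

# strip metadata columns (internal)
drop_mcols <- function(gr) {
  S4Vectors::mcols(gr) <- NULL
  gr
}

#' Call stage-specific enhancers
#'
#' A universe region is assigned to stage `s` when its z-scored H3K27ac
#' signal exceeds `z_high` in `s` and activity above `z_active` is seen in
#' at most `max_additional` other stages (strict inequalities). Regions may
#' be assigned to several stages.
#'
#' @param u an `enhancer_universe` with a z-scored signal matrix, or a
#'   `signal_matrix` in `zscore` units.
#' @param z_high z cutoff defining "highly active" (default 1).
#' @param z_active z cutoff defining "active" (default 0).
#' @param max_additional maximum additional active stages (default 3).
#' @return data.frame with one row per (region, stage) call: `region_idx`,
#'   `chrom`, `start`, `end` (0-based half-open), `stage`, `z`.
#' @export
call_stage_specific_enhancers <- function(u, z_high = 1, z_active = 0,
                                          max_additional = 3) {
  z <- universe_zscore(u)
  zm <- z$values
  n_active <- rowSums(zm > z_active)
  rows <- list()
  for (j in seq_len(ncol(zm))) {
    keep <- zm[, j] > z_high &
      (n_active - (zm[, j] > z_active)) <= max_additional
    if (any(keep)) {
      gr <- z$regions[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        region_idx = which(keep),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        stage = colnames(zm)[j],
        z = zm[keep, j],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_idx = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stage = character(), z = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# accept an enhancer_universe or a bare zscore signal_matrix (internal)
universe_zscore <- function(u) {
  z <- if (inherits(u, "enhancer_universe")) u$zscore else u
  if (is.null(z) || !inherits(z, "signal_matrix") || z$unit != "zscore") {
    stop("a z-scored signal matrix is required")
  }
  z
}

#' Concordance of H3K4me1 with called H3K27ac enhancers
#'
#' Independent-mark validation: per stage, compares mean H3K4me1 z at
#' called stage-specific enhancers with the universe-wide mean, and reports
#' the fraction of called enhancers whose H3K4me1 z is positive in their
#' assigned stage.
#'
#' @param h3k4me1 `signal_matrix` in `zscore` units over the same universe
#'   regions (row-parallel).
#' @param calls data.frame from [call_stage_specific_enhancers()].
#' @return data.frame per stage: `n_calls`, `mean_z_called`,
#'   `mean_z_universe`, `frac_concordant`.
#' @export
h3k4me1_concordance <- function(h3k4me1, calls) {
  if (is.null(h3k4me1)) stop("companion H3K4me1 signal matrix is missing")
  z <- universe_zscore(h3k4me1)
  if (nrow(calls) == 0L) {
    return(data.frame(stage = character(), n_calls = integer(),
                      mean_z_called = numeric(), mean_z_universe = numeric(),
                      frac_concordant = numeric(), stringsAsFactors = FALSE))
  }
  stages <- intersect(unique(calls$stage), z$stages)
  out <- lapply(stages, function(s) {
    idx <- calls$region_idx[calls$stage == s]
    zi <- z$values[idx, s]
    data.frame(stage = s, n_calls = length(idx),
               mean_z_called = mean(zi),
               mean_z_universe = mean(z$values[, s]),
               frac_concordant = mean(zi > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
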