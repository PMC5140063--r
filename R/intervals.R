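#' Build a GRanges from 0-based half-open coordinates
#'
#' All on-disk region formats used by this package (BED) are 0-based
#' half-open; the in-memory container is a [GenomicRanges::GRanges] (1-based
#' closed). This constructor converts between the two conventions.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open (`start >= 0`,
#'   `end > start`).
#' @param name,score,strand optional per-interval metadata; `strand` in
#'   `"+"`, `"-"`, `"*"`.
#' @return A `GRanges` object.
#' @export
granges0 <- function(chrom, start, end, name = NULL, score = NULL,
                     strand = NULL) {
  if (length(chrom) == 0L) return(GenomicRanges::GRanges())
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start (empty intervals not allowed)")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = if (is.null(strand)) "*" else strand
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  # canonical chromosome order (not first-appearance order) so sorting is
  # deterministic regardless of input row order
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Read a BED file into a GRanges
#'
#' Accepts BED3 to BED6 (tab-separated, 0-based half-open). `name`, `score`
#' and `strand` columns are preserved when present.
#'
#' @param path path to a BED file.
#' @return A sorted `GRanges`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path, ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path,
         ": non-numeric coordinates")
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path,
         ": end <= start (empty interval)")
  }
  name <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  score <- if (all(nf >= 5L)) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  } else NULL
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, "", 6L) else NULL
  if (!is.null(strand) && !all(strand %in% c("+", "-", "."))) {
    stop("malformed BED strand field in ", path)
  }
  if (!is.null(strand)) strand[strand == "."] <- "*"
  granges0(chrom, start, end, name = name, score = score, strand = strand)
}

#' Write a GRanges to a BED file
#'
#' Emits BED3, or BED6 when `name`/`score` metadata or strand information is
#' present. Coordinates are converted back to the 0-based half-open
#' convention. Output is sorted, so `read_bed(write_bed(x))` round-trips.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  md <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  has_extra <- "name" %in% names(md) || "score" %in% names(md) ||
    any(strand != "*")
  if (has_extra) {
    name <- if ("name" %in% names(md)) as.character(md$name) else "."
    score <- if ("score" %in% names(md)) md$score else 0
    strand[strand == "*"] <- "."
    out <- paste(chrom, start, end, name, score, strand, sep = "\t")
  } else {
    out <- paste(chrom, start, end, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a refFlat file
#'
#' Parses the 11-column refFlat dialect (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds;
#' coordinates 0-based half-open) into a gene-model table. The TSS is
#' `txStart` on the + strand and `txEnd` on the - strand.
#'
#' @param path path to a refFlat file.
#' @return A data.frame with columns `gene_id`, `tx_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss` (all coordinates 0-based half-open) and
#'   list columns `exon_starts`, `exon_ends`.
#' @export
read_refflat <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(x) < 11L) stop("refFlat file must have 11 columns")
  names(x)[1:11] <- c("gene_id", "tx_id", "chrom", "strand", "tx_start",
                      "tx_end", "cds_start", "cds_end", "exon_count",
                      "exon_starts", "exon_ends")
  tx_start <- as.numeric(x$tx_start)
  tx_end <- as.numeric(x$tx_end)
  n_exons <- as.integer(x$exon_count)
  parse_csv <- function(s) lapply(strsplit(s, ",", fixed = TRUE), as.numeric)
  ex_s <- parse_csv(x$exon_starts)
  ex_e <- parse_csv(x$exon_ends)
  bad <- which(lengths(ex_s) != n_exons | lengths(ex_e) != n_exons)
  if (length(bad)) {
    stop("refFlat row ", bad[1L], ": exonCount does not match exon lists")
  }
  if (!all(x$strand %in% c("+", "-"))) stop("refFlat strand must be + or -")
  for (i in seq_along(ex_s)) {
    if (any(ex_s[[i]] < tx_start[i]) || any(ex_e[[i]] > tx_end[i])) {
      stop("refFlat row ", i, ": exons outside [txStart, txEnd)")
    }
  }
  data.frame(
    gene_id = x$gene_id, tx_id = x$tx_id, chrom = x$chrom,
    strand = x$strand, tx_start = tx_start, tx_end = tx_end,
    tss = ifelse(x$strand == "+", tx_start, tx_end),
    exon_starts = I(ex_s), exon_ends = I(ex_e),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to a refFlat file
#'
#' Inverse of [read_refflat()]; the CDS columns are written as `tx_start`
#' (i.e. non-coding style) since the pipeline does not use them.
#'
#' @param genes a gene-model data.frame from [read_refflat()] or the
#'   simulator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(genes, path) {
  fmt_csv <- function(v) paste0(paste(format(v, scientific = FALSE, trim = TRUE),
                                      collapse = ","), ",")
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_id[i], genes$tx_id[i], genes$chrom[i], genes$strand[i],
          format(genes$tx_start[i], scientific = FALSE),
          format(genes$tx_end[i], scientific = FALSE),
          format(genes$tx_start[i], scientific = FALSE),
          format(genes$tx_start[i], scientific = FALSE),
          length(genes$exon_starts[[i]]),
          fmt_csv(genes$exon_starts[[i]]), fmt_csv(genes$exon_ends[[i]]),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' TSS positions of gene models as a GRanges
#'
#' @param genes gene-model data.frame (see [read_refflat()]).
#' @return A `GRanges` of width-1 TSS positions with a `gene_id` column.
#' @export
gene_tss <- function(genes) {
  granges0(genes$chrom, genes$tss, genes$tss + 1, name = genes$gene_id,
           strand = genes$strand)
}

#' Promoter windows around gene TSSs
#'
#' @param genes gene-model data.frame.
#' @param pad half-width of the window in bases (default 2500, i.e.
#'   TSS +- 2.5 kb).
#' @return A `GRanges` of promoter windows with a `gene_id` column, clipped
#'   at position 0.
#' @export
promoter_windows <- function(genes, pad = 2500) {
  granges0(genes$chrom, pmax(genes$tss - pad, 0), genes$tss + pad,
           name = genes$gene_id, strand = genes$strand)
}

#' Region-level subtraction of interval sets
#'
#' Removes every interval of `a` that overlaps `b` by at least one base.
#' The whole region is excluded, not just the intersecting bases: the
#' pipeline treats enhancers as discrete regions, so an H3K27ac region
#' touching an H3K4me3 region (or a TSS window) is dropped entirely.
#'
#' @param a,b `GRanges` objects.
#' @return The subset of `a` with zero-base overlap with `b`.
#' @export
subtract_regions <- function(a, b) {
  if (length(a) == 0L) return(a)
  if (length(b) == 0L) return(GenomicRanges::sort(a, ignore.strand = TRUE))
  hit <- IRanges::overlapsAny(a, b, ignore.strand = TRUE)
  GenomicRanges::sort(a[!hit], ignore.strand = TRUE)
}

#' Merge intervals whose gaps are at most a maximum size
#'
#' Transitively merges same-chromosome intervals whose end-to-start gap is
#' `<= max_gap` (the 12.5 kb stitching rule uses `max_gap = 12500`).
#' Overlapping and book-ended intervals always merge. Each output interval
#' records how many input intervals it absorbed (`n_constituents`).
#'
#' @param a a `GRanges`.
#' @param max_gap maximum tolerated gap in bases (`>= 0`).
#' @return A disjoint, sorted `GRanges` with an `n_constituents` column and
#'   a `revmap` list column of constituent indices into the sorted input.
#' @export
merge_within_gap <- function(a, max_gap) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (length(a) == 0L) return(a)
  a <- GenomicRanges::sort(a, ignore.strand = TRUE)
  m <- GenomicRanges::reduce(a, min.gapwidth = max_gap + 1L,
                             ignore.strand = TRUE, with.revmap = TRUE)
  S4Vectors::mcols(m)$n_constituents <- lengths(S4Vectors::mcols(m)$revmap)
  m
}

#' Extend reads to a fixed length from their 5' end
#'
#' Each mapped read is replaced by an interval of length `extension`
#' anchored at its 5' end in strand direction (the standard fragment-length
#' extension used before computing ChIP coverage). Intervals running off the
#' chromosome start are clipped at 0.
#'
#' @param reads a stranded `GRanges` of mapped read positions.
#' @param extension target length in bases (> 0; 300 is the conventional
#'   fragment size).
#' @return A `GRanges` of extended intervals.
#' @export
extend_reads <- function(reads, extension) {
  if (extension <= 0) stop("extension must be > 0")
  s <- as.character(GenomicRanges::strand(reads))
  if (any(s == "*")) stop("reads must be stranded to be extended")
  st0 <- GenomicRanges::start(reads) - 1   # 0-based
  en0 <- GenomicRanges::end(reads)
  plus <- s == "+"
  new_start <- ifelse(plus, st0, pmax(en0 - extension, 0))
  new_end <- ifelse(plus, st0 + extension, en0)
  GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(reads)),
    IRanges::IRanges(new_start + 1, new_end),
    strand = s
  )
}

#' Distance from gene TSSs to the nearest interval
#'
#' @param tss width-1 `GRanges` of TSS positions (see [gene_tss()]).
#' @param peaks a non-empty `GRanges`.
#' @return Numeric vector of distances, one per TSS: 0 when the TSS lies
#'   inside a peak, otherwise bases to the nearest peak edge (a TSS at
#'   position p and a peak starting at s > p are s - p apart). `NA` for a
#'   TSS on a chromosome without peaks.
#' @export
nearest_distance <- function(tss, peaks) {
  if (length(peaks) == 0L) stop("peak set is empty")
  d <- suppressWarnings(   # disjoint seqlevel sets simply yield NA rows
    GenomicRanges::distanceToNearest(tss, peaks, ignore.strand = TRUE))
  out <- rep(NA_real_, length(tss))
  # GenomicRanges counts the gap between ranges; the point-to-edge distance
  # is gap + 1 for disjoint pairs and 0 for containment.
  out[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance + 1
  inside <- suppressWarnings(
    IRanges::overlapsAny(tss, peaks, ignore.strand = TRUE))
  out[inside] <- 0
  out
}
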