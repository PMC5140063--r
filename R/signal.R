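#' Region-by-stage ChIP signal matrix
#'
#' Light container for quantified ChIP-seq signal over a fixed set of
#' regions across ordered stages. The `unit` field tracks the normalization
#' state and only the transitions raw_count -> rpkm -> zscore are legal.
#'
#' @param regions `GRanges` of quantified regions (one row per region).
#' @param values numeric matrix, regions x stages.
#' @param stages ordered stage labels (column names of `values`).
#' @param unit one of `"raw_count"`, `"rpkm"`, `"zscore"`.
#' @param lib_sizes named numeric vector of total mapped reads per stage
#'   (required to reach rpkm).
#' @param zscore_axis for zscore matrices, the axis that was standardized:
#'   `"per_stage_across_regions"` or `"per_region_across_stages"`.
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(regions, values, stages = colnames(values),
                          unit = c("raw_count", "rpkm", "zscore"),
                          lib_sizes = NULL, zscore_axis = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (length(regions) != nrow(values)) {
    stop("regions and value rows disagree")
  }
  if (is.null(stages)) stop("stage labels required")
  colnames(values) <- stages
  if (unit %in% c("raw_count", "rpkm") && any(values < 0)) {
    stop(unit, " values must be >= 0")
  }
  structure(
    list(regions = regions, values = values, stages = stages, unit = unit,
         lib_sizes = lib_sizes, zscore_axis = zscore_axis),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix: ", nrow(x$values), " regions x ", length(x$stages),
      " stages [", x$unit,
      if (!is.null(x$zscore_axis)) paste0(", ", x$zscore_axis) else "",
      "]\n", sep = "")
  cat("stages:", paste(x$stages, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Count reads overlapping each region
#'
#' A read counts toward a region when its (extended) interval overlaps it
#' by at least one base.
#'
#' @param regions `GRanges` of regions.
#' @param reads_per_stage named list of `GRanges`, one per stage, of
#'   (extended) read intervals.
#' @return A `signal_matrix` in `raw_count` units with library sizes taken
#'   from the number of reads per stage.
#' @export
count_reads <- function(regions, reads_per_stage) {
  stages <- names(reads_per_stage)
  if (is.null(stages)) stop("reads_per_stage must be a named list")
  counts <- vapply(reads_per_stage, function(r) {
    GenomicRanges::countOverlaps(regions, r, ignore.strand = TRUE)
  }, numeric(length(regions)))
  counts <- matrix(counts, nrow = length(regions),
                   dimnames = list(NULL, stages))
  signal_matrix(regions, counts, stages = stages, unit = "raw_count",
                lib_sizes = stats::setNames(lengths(reads_per_stage), stages))
}

#' RPKM normalization of region read counts
#'
#' Reads Per Kilobase of region per Million sequenced reads:
#' `count / (length_kb * library_size_millions)`.
#'
#' @param x either a `signal_matrix` in `raw_count` units (with
#'   `lib_sizes`), or a `GRanges` of regions when `counts` or `reads` is
#'   supplied.
#' @param counts optional region x stage count matrix (used with a
#'   `GRanges` first argument).
#' @param lib_sizes named total mapped reads per stage; must be > 0.
#'   Defaults to the read counts when `reads` is given.
#' @param reads optional named list of per-stage (extended) read interval
#'   `GRanges`; counted with [count_reads()].
#' @return A `signal_matrix` in `rpkm` units.
#' @export
quantify_rpkm <- function(x, counts = NULL, lib_sizes = NULL, reads = NULL) {
  if (!is.null(reads)) {
    cm <- count_reads(x, reads)
    regions <- cm$regions
    counts <- cm$values
    if (is.null(lib_sizes)) lib_sizes <- cm$lib_sizes
  } else if (inherits(x, "signal_matrix")) {
    if (x$unit != "raw_count") stop("quantify_rpkm needs raw_count input")
    regions <- x$regions
    counts <- x$values
    if (is.null(lib_sizes)) lib_sizes <- x$lib_sizes
  } else {
    regions <- x
    counts <- as.matrix(counts)
  }
  if (is.null(lib_sizes)) stop("library sizes required")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  widths <- GenomicRanges::width(regions)
  if (any(widths <= 0)) stop("region lengths must be > 0")
  stages <- colnames(counts)
  lib <- lib_sizes[stages]
  rpkm <- sweep(counts / (widths / 1000), 2, lib / 1e6, "/")
  signal_matrix(regions, rpkm, stages = stages, unit = "rpkm",
                lib_sizes = lib_sizes)
}

#' Z-score transformation of an RPKM matrix
#'
#' Standardizes `(x - mean) / sd` with the population standard deviation
#' over the chosen axis. The default, per stage across regions, puts each
#' stage's region signals on a common scale and thereby absorbs batch and
#' depth differences between stages. Degenerate slices (fewer than two
#' distinct values) map to 0 so downstream thresholds stay usable.
#'
#' @param m a `signal_matrix` in `rpkm` units.
#' @param axis `"per_stage_across_regions"` (default) or
#'   `"per_region_across_stages"`.
#' @return A `signal_matrix` in `zscore` units recording the axis used.
#' @export
zscore_normalize <- function(m, axis = c("per_stage_across_regions",
                                         "per_region_across_stages")) {
  axis <- match.arg(axis)
  if (!inherits(m, "signal_matrix") || m$unit != "rpkm") {
    stop("zscore_normalize needs a signal_matrix in rpkm units")
  }
  z <- if (axis == "per_stage_across_regions") {
    apply(m$values, 2, zscore_slice)
  } else {
    t(apply(m$values, 1, zscore_slice))
  }
  z <- matrix(z, nrow = nrow(m$values), dimnames = dimnames(m$values))
  signal_matrix(m$regions, z, stages = m$stages, unit = "zscore",
                lib_sizes = m$lib_sizes, zscore_axis = axis)
}

# population-sd z-score of one slice; constant slices -> 0
zscore_slice <- function(x) {
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) return(rep(0, length(x)))
  (x - mu) / sdev
}

#' Write a signal matrix to a TSV file
#'
#' First column is the region id (`chrom:start-end`, 0-based half-open),
#' remaining columns are the stages.
#'
#' @param m a `signal_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_tsv <- function(m, path) {
  ids <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(m$regions)),
                 GenomicRanges::start(m$regions) - 1L,
                 GenomicRanges::end(m$regions))
  df <- data.frame(region = ids, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
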