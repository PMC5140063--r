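#' Classify pooled day-7 stage-specific genes by lineage
#'
#' Applied to the pooled BA d7 + WA d7 stage-specific gene list. A gene is
#' BA-specific when its BA d7 expression is at least `min_fold` times the
#' WA d7 expression AND it is not highly expressed in WA d7
#' (`wa < other_max`); WA-specific by the mirrored rule; everything else in
#' the pool is a shared ("common") adipogenic gene. A zero denominator with
#' a positive numerator counts as passing the fold rule (the absolute
#' `other_max` bound already caps the low side).
#'
#' For lncRNAs use `min_fold = 5, other_max = Inf` (the 5-fold rule has no
#' absolute cap); [classify_d7_lineage_lncrna()] is a convenience wrapper.
#'
#' @param ba_d7,wa_d7 non-negative day-7 FPKM vectors (parallel; names =
#'   gene ids).
#' @param min_fold fold cutoff, inclusive (default 3).
#' @param other_max absolute cap on the opposite lineage, strict
#'   (default 10 FPKM).
#' @return data.frame: `feature_id`, `class` (`BA_specific`, `WA_specific`,
#'   `common`), `ba_d7`, `wa_d7`, `fold_ba`, `fold_wa`.
#' @export
classify_d7_lineage <- function(ba_d7, wa_d7, min_fold = 3, other_max = 10) {
  if (any(ba_d7 < 0) || any(wa_d7 < 0)) stop("FPKM must be >= 0")
  if (length(ba_d7) != length(wa_d7)) stop("input lengths differ")
  ids <- names(ba_d7)
  if (is.null(ids)) ids <- as.character(seq_along(ba_d7))
  ba_spec <- ba_d7 >= min_fold * wa_d7 & wa_d7 < other_max & ba_d7 > 0
  wa_spec <- wa_d7 >= min_fold * ba_d7 & ba_d7 < other_max & wa_d7 > 0
  # a gene passing both mirrored rules (only possible near zero/zero) is
  # left unresolved as common
  both <- ba_spec & wa_spec
  cls <- ifelse(ba_spec & !both, "BA_specific",
                ifelse(wa_spec & !both, "WA_specific", "common"))
  data.frame(
    feature_id = ids, class = cls, ba_d7 = ba_d7, wa_d7 = wa_d7,
    fold_ba = ifelse(wa_d7 > 0, ba_d7 / wa_d7, Inf),
    fold_wa = ifelse(ba_d7 > 0, wa_d7 / ba_d7, Inf),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @rdname classify_d7_lineage
#' @export
classify_d7_lineage_lncrna <- function(ba_d7, wa_d7, min_fold = 5) {
  classify_d7_lineage(ba_d7, wa_d7, min_fold = min_fold, other_max = Inf)
}

#' Confirm lineage calls against tissue and primary-cell expression
#'
#' Retains a BA_specific (WA_specific) call only when expression is also at
#' least `min_fold` higher in the concordant direction both in
#' differentiated primary SVF adipocytes and in adipose tissue; otherwise
#' the call is downgraded to `unclassified`. Calls without auxiliary data
#' pass through unchanged, flagged `validated = NA`.
#'
#' @param calls data.frame from [classify_d7_lineage()].
#' @param tissue_fold,primary_fold per-gene BA/WA fold vectors in the
#'   tissue and primary-cell data (values > 1 favour BA). `NA` = no data.
#' @param min_fold validation fold cutoff, inclusive (default 2.5).
#' @return `calls` with `class` updated and a `validated` logical column.
#' @export
apply_external_validation <- function(calls, tissue_fold = NULL,
                                      primary_fold = NULL, min_fold = 2.5) {
  n <- nrow(calls)
  if (is.null(tissue_fold)) tissue_fold <- rep(NA_real_, n)
  if (is.null(primary_fold)) primary_fold <- rep(NA_real_, n)
  validated <- rep(NA, n)
  for (i in seq_len(n)) {
    cls <- calls$class[i]
    if (!cls %in% c("BA_specific", "WA_specific")) next
    tf <- tissue_fold[i]
    pf <- primary_fold[i]
    if (is.na(tf) || is.na(pf)) next
    ok <- if (cls == "BA_specific") {
      tf >= min_fold && pf >= min_fold
    } else {
      (1 / tf) >= min_fold && (1 / pf) >= min_fold
    }
    validated[i] <- ok
    if (!ok) calls$class[i] <- "unclassified"
  }
  calls$validated <- validated
  calls
}

#' Gene groups for binding-enrichment analyses
#'
#' The absolute-threshold grouping used for TF-binding comparisons:
#' BA-specific genes have FPKM > 5 in BA d7 and FPKM < 5 in WA d7,
#' WA-specific genes the mirror, common genes FPKM > 5 in both; genes below
#' 5 in both lineages belong to no group.
#'
#' @param ba_d7,wa_d7 named day-7 FPKM vectors over the same genes.
#' @param expr_min the FPKM threshold (default 5, strict on both sides).
#' @return Named list of gene-id character vectors:
#'   `BA_specific`, `WA_specific`, `common`.
#' @export
gene_groups_for_binding <- function(ba_d7, wa_d7, expr_min = 5) {
  ids <- names(ba_d7)
  if (is.null(ids)) ids <- as.character(seq_along(ba_d7))
  list(
    BA_specific = ids[ba_d7 > expr_min & wa_d7 < expr_min],
    WA_specific = ids[wa_d7 > expr_min & ba_d7 < expr_min],
    common = ids[ba_d7 > expr_min & wa_d7 > expr_min]
  )
}

#' Promoter chromatin state by gene group, compared between lineages
#'
#' For each histone mark, gene group and stage, summarizes the z-scored
#' promoter RPKM distribution in each lineage and tests the between-lineage
#' difference with a Welch two-sample t-test. Groups with fewer than two
#' genes are summarized without a test and flagged.
#'
#' @param marks_ba,marks_wa named lists of `signal_matrix` objects (one per
#'   mark) in `zscore` units over promoter windows; rows must correspond to
#'   `gene_ids`.
#' @param gene_ids gene ids in promoter-row order (shared by both lineages).
#' @param groups named list of gene-id vectors (e.g. from
#'   [gene_groups_for_binding()] or lineage calls).
#' @return data.frame with one row per (mark, group, stage): group sizes,
#'   mean z per lineage, Welch `t` and two-sided `p`, and a `tested` flag.
#' @export
promoter_mark_summary <- function(marks_ba, marks_wa, gene_ids, groups) {
  stopifnot(identical(names(marks_ba), names(marks_wa)))
  rows <- list()
  for (mark in names(marks_ba)) {
    m_ba <- marks_ba[[mark]]
    m_wa <- marks_wa[[mark]]
    if (m_ba$unit != "zscore" || m_wa$unit != "zscore") {
      stop("promoter signal matrices must be in zscore units")
    }
    for (grp in names(groups)) {
      idx <- match(intersect(groups[[grp]], gene_ids), gene_ids)
      for (stage in intersect(m_ba$stages, m_wa$stages)) {
        x <- m_ba$values[idx, stage]
        y <- m_wa$values[idx, stage]
        tested <- length(idx) >= 2 &&
          (stats::sd(x) > 0 || stats::sd(y) > 0)
        if (tested) {
          tt <- stats::t.test(x, y, var.equal = FALSE)
          tstat <- unname(tt$statistic)
          p <- tt$p.value
        } else if (length(idx) >= 2) {
          # identical constant distributions: no difference by definition
          tstat <- 0
          p <- 1
          tested <- TRUE
        } else {
          tstat <- NA_real_
          p <- NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          mark = mark, group = grp, stage = stage, n = length(idx),
          mean_z_ba = mean(x), mean_z_wa = mean(y),
          t = tstat, p = p, tested = tested,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
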