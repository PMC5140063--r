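#' Default analysis parameters
#'
#' Every threshold of the comparative pipeline in one flat list, each with
#' its conventional default: entropy < 2 bits; FPKM > 5 (coding) / > 0.5
#' (lncRNA) / > 1 (SE targets) / < 10 (lineage cap); folds 3 (lineage
#' coding), 5 (lineage lncRNA), 2.5 (external validation), 2 (miRNA,
#' transient induction); TSS pad 2.5 kb; z > 1 / z > 0 with at most 3
#' additional stages; stitch gap and minimum span 12.5 kb; slope 0.5;
#' target window 100 kb with r > 0.75 / > 0.5; 300 bp read extension.
#'
#' @param ... overrides for individual parameters.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    entropy_max = 2, expr_min_coding = 5, expr_min_lnc = 0.5,
    max_additional_stages = 3,
    mirna_min_fold = 2, mirna_floor = 1,
    bmp7_up_fold = 2, bmp7_down_fold = 2, bmp7_expr_min = 5,
    lineage_min_fold = 3, lineage_other_max = 10, lnc_lineage_fold = 5,
    validation_fold = 2.5,
    binding_expr_min = 5,
    promoter_pad = 2500,
    tss_pad = 2500,
    z_high = 1, z_active = 0, enh_max_additional = 3,
    stitch_gap = 12500, min_span = 12500, slope = 0.5,
    target_window = 1e5, r_primary = 0.75, r_fallback = 0.5,
    target_expr_min = 1,
    read_extension = 300,
    zscore_axis = "per_stage_across_regions",
    tf_promoter_pad = 2500, tf_tss_window = 1e5,
    early_stages = list(BA = c("d-3", "d0", "6h"), WA = c("d-4", "d0"))
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter: ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Run the full comparative pipeline on a synthetic fixture
#'
#' Executes, in order: stage-specificity scoring and selection (coding,
#' lncRNA, miRNA, transient-induction genes), day-7 lineage classification
#' and promoter chromatin-state comparison, stage-specific enhancer
#' calling, super-enhancer stitching / ranking / late-specific filtering /
#' target assignment, and TF peak annotation and enrichment. All tabular
#' outputs plus a run manifest are written to `out_dir` when given;
#' identical inputs and parameters give byte-identical outputs.
#'
#' @param sim fixture from [simulate_all()] (or an equivalently shaped
#'   list of inputs).
#' @param params from [pipeline_params()].
#' @param out_dir optional output directory (created if needed).
#' @return A list of per-stage results, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(sim, params = pipeline_params(), out_dir = NULL) {
  res <- list(params = params)
  genes <- sim$layout$genes
  expr <- sim$expr
  if (is.null(expr$ba) || is.null(expr$wa)) {
    stop("stage_specificity: expression matrices missing")
  }

  ## 1. stage specificity ---------------------------------------------------
  res$stage_genes <- list(
    BA = select_stage_specific(expr$ba, "coding",
                               entropy_max = params$entropy_max,
                               expr_min = params$expr_min_coding,
                               max_additional_stages =
                                 params$max_additional_stages),
    WA = select_stage_specific(expr$wa, "coding",
                               entropy_max = params$entropy_max,
                               expr_min = params$expr_min_coding,
                               max_additional_stages =
                                 params$max_additional_stages)
  )
  res$stage_lnc <- list(
    BA = select_stage_specific(expr$lnc_ba, "lncRNA",
                               entropy_max = params$entropy_max,
                               expr_min = params$expr_min_lnc,
                               max_additional_stages =
                                 params$max_additional_stages),
    WA = select_stage_specific(expr$lnc_wa, "lncRNA",
                               entropy_max = params$entropy_max,
                               expr_min = params$expr_min_lnc,
                               max_additional_stages =
                                 params$max_additional_stages)
  )
  res$stage_mirna <- list(
    BA = select_stage_specific_mirna(quantile_normalize(expr$mirna_ba),
                                     min_fold = params$mirna_min_fold,
                                     floor = params$mirna_floor),
    WA = select_stage_specific_mirna(quantile_normalize(expr$mirna_wa),
                                     min_fold = params$mirna_min_fold,
                                     floor = params$mirna_floor)
  )
  res$bmp7_transient <- select_bmp7_transient(
    expr$ba, up_fold = params$bmp7_up_fold,
    down_fold = params$bmp7_down_fold, expr_min = params$bmp7_expr_min)

  ## 2. lineage analysis ----------------------------------------------------
  d7_ba <- colnames(expr$ba)[ncol(expr$ba)]
  d7_wa <- colnames(expr$wa)[ncol(expr$wa)]
  pooled <- union(
    res$stage_genes$BA$feature_id[res$stage_genes$BA$stage == d7_ba],
    res$stage_genes$WA$feature_id[res$stage_genes$WA$stage == d7_wa])
  res$lineage <- classify_d7_lineage(
    stats::setNames(expr$ba[pooled, d7_ba], pooled),
    expr$wa[pooled, d7_wa],
    min_fold = params$lineage_min_fold,
    other_max = params$lineage_other_max)
  pooled_lnc <- union(
    res$stage_lnc$BA$feature_id[res$stage_lnc$BA$stage == d7_ba],
    res$stage_lnc$WA$feature_id[res$stage_lnc$WA$stage == d7_wa])
  res$lineage_lnc <- classify_d7_lineage_lncrna(
    stats::setNames(expr$lnc_ba[pooled_lnc, d7_ba], pooled_lnc),
    expr$lnc_wa[pooled_lnc, d7_wa],
    min_fold = params$lnc_lineage_fold)
  res$binding_groups <- gene_groups_for_binding(
    stats::setNames(expr$ba[, d7_ba], rownames(expr$ba)),
    expr$wa[, d7_wa], expr_min = params$binding_expr_min)

  if (!is.null(sim$epi)) {
    prom <- promoter_windows(genes, pad = params$promoter_pad)
    prom_marks <- function(lin) {
      lapply(c(h3k4me1 = "h3k4me1", h3k27me3 = "h3k27me3"), function(mk) {
        rd <- sim$epi[[lin]]$reads[[mk]]
        if (is.null(rd)) stop("lineage_analysis: missing ", mk,
                              " reads for ", lin)
        ext <- lapply(rd, extend_reads, params$read_extension)
        zscore_normalize(quantify_rpkm(prom, reads = ext),
                         axis = params$zscore_axis)
      })
    }
    res$promoter_summary <- promoter_mark_summary(
      prom_marks("BA"), prom_marks("WA"), genes$gene_id,
      groups = res$binding_groups)
  }

  ## 3 + 4. enhancers and super-enhancers per lineage -----------------------
  if (!is.null(sim$epi)) {
    res$enhancers <- list()
    res$superenhancers <- list()
    for (lin in c("BA", "WA")) {
      epi <- sim$epi[[lin]]
      if (is.null(epi$peaks$h3k4me3)) {
        stop("enhancer_analysis: missing H3K4me3 peaks for ", lin)
      }
      if (is.null(epi$peaks$h3k27ac) || is.null(epi$reads$h3k27ac)) {
        stop("enhancer_analysis: missing H3K27ac input for ", lin)
      }
      ext <- lapply(epi$reads$h3k27ac, extend_reads,
                    params$read_extension)
      u <- build_enhancer_universe(epi$peaks$h3k27ac, epi$peaks$h3k4me3,
                                   genes, tss_pad = params$tss_pad,
                                   reads = ext,
                                   zscore_axis = params$zscore_axis)
      calls <- call_stage_specific_enhancers(
        u, z_high = params$z_high, z_active = params$z_active,
        max_additional = params$enh_max_additional)
      ext1 <- lapply(epi$reads$h3k4me1, extend_reads,
                     params$read_extension)
      k4me1 <- zscore_normalize(quantify_rpkm(u$regions, reads = ext1),
                                axis = params$zscore_axis)
      conc <- h3k4me1_concordance(k4me1, calls)
      res$enhancers[[lin]] <- list(universe = u, calls = calls,
                                   concordance = conc)

      stages <- epi$stages
      d7 <- stages[length(stages)]
      rank_stage <- function(st) {
        cand <- stitch_active_enhancers(u, st, gap = params$stitch_gap,
                                        min_span = params$min_span,
                                        z_active = params$z_active,
                                        reads = ext)
        ranked <- suppressWarnings(
          rank_and_cut(cand, slope_threshold = params$slope))
        list(cand = cand, ranked = ranked)
      }
      r_d7 <- rank_stage(d7)
      early <- intersect(params$early_stages[[lin]], stages)
      r_early <- lapply(early, function(s) rank_stage(s)$ranked)
      late <- late_specific_ses(r_d7$ranked, r_early)
      se_rows <- r_d7$ranked[r_d7$ranked$is_se, , drop = FALSE]
      expr_lin <- if (lin == "BA") expr$ba else expr$wa
      se_signal <- r_d7$cand$rpkm$values[
        match(paste(se_rows$chrom, se_rows$start),
              paste(as.character(GenomicRanges::seqnames(
                r_d7$cand$regions)),
                GenomicRanges::start(r_d7$cand$regions) - 1L)), ,
        drop = FALSE]
      targets <- assign_se_targets(
        se_rows, se_signal, expr_lin, genes,
        window = params$target_window, r_primary = params$r_primary,
        r_fallback = params$r_fallback,
        expr_min = params$target_expr_min)
      nearest <- assign_nearest_gene(se_rows, genes)
      res$superenhancers[[lin]] <- list(
        ranked_d7 = r_d7$ranked, late_specific = late,
        targets = targets, nearest = nearest)
    }
  }

  ## 5. TF binding ----------------------------------------------------------
  if (!is.null(sim$tf) && length(sim$tf$peaks) > 0) {
    res$tf <- list(
      annotation = annotate_peaks(sim$tf$peaks, genes,
                                  promoter_pad = params$tf_promoter_pad)
    )
    if (!is.null(sim$epi)) {
      k27_d7 <- merge_within_gap(c(
        drop_mcols(sim$epi$BA$peaks$h3k27ac[[length(sim$epi$BA$stages)]]),
        drop_mcols(sim$epi$WA$peaks$h3k27ac[[length(sim$epi$WA$stages)]])),
        0)
      res$tf$enrichment <- group_enrichment(
        sim$tf$peaks, peak_signal = sim$tf$signal,
        lib_size = sim$tf$lib_size, h3k27ac = k27_d7,
        groups = res$binding_groups, genes = genes,
        tss_window = params$tf_tss_window)
      group_ids <- unlist(res$binding_groups, use.names = FALSE)
      res$tf$distances <- nearest_peak_distance(group_ids, sim$tf$peaks,
                                                genes)
    }
  }

  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, sim, out_dir)
    return(invisible(res))
  }
  res
}

# write all tabular outputs plus the run manifest
write_pipeline_outputs <- function(res, sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (lin in c("BA", "WA")) {
    wt(res$stage_genes[[lin]], paste0("stage_genes_", lin, ".tsv"))
    wt(res$stage_lnc[[lin]], paste0("stage_lnc_", lin, ".tsv"))
    wt(res$stage_mirna[[lin]], paste0("stage_mirna_", lin, ".tsv"))
  }
  writeLines(res$bmp7_transient, file.path(out_dir, "bmp7_transient.txt"))
  wt(res$lineage, "lineage_calls.tsv")
  wt(res$lineage_lnc, "lineage_calls_lnc.tsv")
  if (!is.null(res$promoter_summary)) {
    wt(res$promoter_summary, "promoter_mark_summary.tsv")
  }
  counts <- list(seed = sim$cfg$seed)
  for (lin in names(res$enhancers)) {
    calls <- res$enhancers[[lin]]$calls
    wt(calls, paste0("stage_enhancers_", lin, ".tsv"))
    bed <- calls
    bed$score <- round(bed$z * 100)
    writeLines(paste(bed$chrom, bed$start, bed$end, bed$stage, bed$score,
                     sep = "\t"),
               file.path(out_dir, paste0("stage_enhancers_", lin, ".bed")))
    se <- res$superenhancers[[lin]]
    wt(se$ranked_d7, paste0("se_ranked_d7_", lin, ".tsv"))
    wt(se$late_specific, paste0("se_late_specific_", lin, ".tsv"))
    wt(se$targets, paste0("se_targets_", lin, ".tsv"))
    wt(se$nearest, paste0("se_nearest_gene_", lin, ".tsv"))
    counts[[paste0("n_stage_enhancer_calls_", lin)]] <- nrow(calls)
    counts[[paste0("n_se_d7_", lin)]] <- sum(se$ranked_d7$is_se)
    counts[[paste0("n_se_late_", lin)]] <- nrow(se$late_specific)
    counts[[paste0("n_stage_gene_calls_", lin)]] <-
      nrow(res$stage_genes[[lin]])
  }
  if (!is.null(res$tf)) {
    wt(res$tf$annotation$annotation, "tf_annotation.tsv")
    if (!is.null(res$tf$enrichment)) {
      wt(res$tf$enrichment, "tf_group_enrichment.tsv")
      wt(res$tf$distances, "tf_nearest_distance.tsv")
    }
  }
  counts$n_lineage_calls <- nrow(res$lineage)
  counts$n_bmp7 <- length(res$bmp7_transient)
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("adipodyn"))),
    vapply(names(counts), function(k) sprintf("%s: %s", k, counts[[k]]), ""),
    vapply(names(res$params), function(k) {
      v <- res$params[[k]]
      sprintf("param_%s: %s", k, paste(unlist(v), collapse = ","))
    }, "")
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Score pipeline output against the planted ground truth
#'
#' Compares the pipeline's calls with the expected calls implied by the
#' generator's noise-free profiles and placements.
#'
#' @param res result list from [run_pipeline()].
#' @param sim the fixture the pipeline ran on.
#' @return Named list of recovery metrics, all in `[0, 1]` (rates) or
#'   counts.
#' @export
recovery_report <- function(res, sim) {
  pr <- function(called, expected) {
    # called/expected: character keys
    tp <- length(intersect(called, expected))
    list(recall = if (length(expected)) tp / length(expected) else NA_real_,
         precision = if (length(called)) tp / length(called) else NA_real_)
  }
  key <- function(df, lin) paste(lin, df$feature_id, df$stage)

  exp_stage <- c(key(sim$truth$expected$stage_ba, "BA"),
                 key(sim$truth$expected$stage_wa, "WA"))
  got_stage <- c(key(res$stage_genes$BA, "BA"),
                 key(res$stage_genes$WA, "WA"))
  stage <- pr(got_stage, exp_stage)

  exp_lnc <- c(key(sim$truth$expected$stage_lnc_ba, "BA"),
               key(sim$truth$expected$stage_lnc_wa, "WA"))
  got_lnc <- c(key(res$stage_lnc$BA, "BA"), key(res$stage_lnc$WA, "WA"))
  lnc <- pr(got_lnc, exp_lnc)

  exp_lin <- paste(sim$truth$expected$lineage$feature_id,
                   sim$truth$expected$lineage$class)
  got_lin <- paste(res$lineage$feature_id, res$lineage$class)
  lineage <- pr(got_lin, exp_lin)

  # stage-specific enhancers: called (region, stage) vs planted, matched
  # by >= 1 base overlap
  enh_tp <- 0; enh_called <- 0; enh_exp <- 0
  for (lin in names(res$enhancers)) {
    planted <- sim$layout$enhancers
    planted <- planted[planted$role == paste0("ss_", tolower(lin)), ,
                       drop = FALSE]
    enh_exp <- enh_exp + nrow(planted)
    calls <- res$enhancers[[lin]]$calls
    enh_called <- enh_called + nrow(calls)
    if (nrow(calls) == 0L || nrow(planted) == 0L) next
    pg <- GenomicRanges::GRanges(planted$chrom,
                                 IRanges::IRanges(planted$start + 1,
                                                  planted$end))
    cg <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$start + 1,
                                                  calls$end))
    ov <- GenomicRanges::findOverlaps(pg, cg)
    match_stage <- planted$stage[S4Vectors::queryHits(ov)] ==
      calls$stage[S4Vectors::subjectHits(ov)]
    enh_tp <- enh_tp + length(unique(S4Vectors::queryHits(ov)[match_stage]))
  }

  # super-enhancer loci and target pairs
  se_exp <- 0; se_tp <- 0; pair_tp <- 0
  decoy_assigned <- 0; decoy_total <- 0
  for (lin in names(res$superenhancers)) {
    planted <- sim$layout$se[sim$layout$se$lineage == lin, , drop = FALSE]
    se_exp <- se_exp + nrow(planted)
    ranked <- res$superenhancers[[lin]]$ranked_d7
    ses <- ranked[ranked$is_se, , drop = FALSE]
    tg <- res$superenhancers[[lin]]$targets
    if (nrow(ses) == 0L) next
    sg <- GenomicRanges::GRanges(ses$chrom,
                                 IRanges::IRanges(ses$start + 1, ses$end))
    pg <- GenomicRanges::GRanges(planted$chrom,
                                 IRanges::IRanges(planted$span_start + 1,
                                                  planted$span_end))
    ov <- GenomicRanges::findOverlaps(pg, sg)
    se_tp <- se_tp + length(unique(S4Vectors::queryHits(ov)))
    # pair recovery + decoy assignment among corr-mode assignments
    decoys <- sim$truth$genes[sim$truth$genes$class == "decoy", ,
                              drop = FALSE]
    decoy_total <- decoy_total +
      sum(decoys$se_id %in% planted$se_id)
    for (qi in unique(S4Vectors::queryHits(ov))) {
      se_row_idx <- unique(S4Vectors::subjectHits(ov)[
        S4Vectors::queryHits(ov) == qi])
      keys <- paste(ses$chrom[se_row_idx], ses$start[se_row_idx])
      tg_sub <- tg[paste(tg$chrom, tg$start) %in% keys &
                     tg$mode %in% c("corr_primary", "corr_fallback"), ,
                   drop = FALSE]
      if (planted$target[qi] %in% tg_sub$target) pair_tp <- pair_tp + 1
      decoy_assigned <- decoy_assigned +
        sum(tg_sub$target %in%
              decoys$gene_id[decoys$se_id == planted$se_id[qi]])
    }
  }

  list(
    stage_gene_recall = stage$recall, stage_gene_precision = stage$precision,
    stage_lnc_recall = lnc$recall, stage_lnc_precision = lnc$precision,
    lineage_recall = lineage$recall, lineage_precision = lineage$precision,
    enhancer_recall = if (enh_exp) enh_tp / enh_exp else NA_real_,
    enhancer_precision = if (enh_called) {
      # a call is correct when it matches a planted (region, stage)
      enh_tp / enh_called
    } else NA_real_,
    se_recall = if (se_exp) se_tp / se_exp else NA_real_,
    se_target_recall = if (se_exp) pair_tp / se_exp else NA_real_,
    se_decoy_rate = if (decoy_total) decoy_assigned / decoy_total
      else NA_real_,
    n_stage_gene_calls = length(got_stage),
    n_lineage_calls = nrow(res$lineage),
    n_bmp7 = length(res$bmp7_transient)
  )
}

#' One-command synthetic end-to-end demo
#'
#' Generates the default synthetic fixture with the given seed, runs the
#' full pipeline on it, writes all outputs plus a recovery report
#' (precision / recall per planted class) to `out`, and returns the
#' report.
#'
#' @param seed integer seed for the fixture.
#' @param out output directory.
#' @param cfg optional [sim_config()] (its seed is overridden by `seed`).
#' @param params optional [pipeline_params()]. The demo scales the
#'   TF-enrichment TSS window down to 3 kb: the synthetic genome packs
#'   genes about thirty times more densely than a mammalian genome, so the
#'   100 kb default would span every neighbouring gene's regulatory space.
#' @return A list: `report` (recovery metrics), `res`, `sim`, invisibly.
#' @export
run_demo <- function(seed = 1, out = tempfile("adipodyn_demo"),
                     cfg = NULL, params = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed) else cfg$seed <- seed
  if (is.null(params)) params <- pipeline_params(tf_tss_window = 3000)
  sim <- simulate_all(cfg)
  res <- run_pipeline(sim, params = params, out_dir = out)
  report <- recovery_report(res, sim)
  rep_df <- data.frame(metric = names(report),
                       value = vapply(report, function(v)
                         sprintf("%.6f", v), ""),
                       stringsAsFactors = FALSE)
  utils::write.table(rep_df, file.path(out, "recovery_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(report = report, res = res, sim = sim, out = out))
}

#' Write a synthetic fixture to disk
#'
#' Emits the file-based part of a fixture: expression matrices (TSV),
#' gene models (refFlat), per-stage peak BEDs, TF peak BED, ground-truth
#' tables, and a `manifest.txt` of `key: value` pairs recording seed and
#' configuration. Read intervals are kept in memory (regenerate them with
#' the recorded seed); pass `write_reads = TRUE` to emit them as BED too.
#'
#' @param sim fixture from [simulate_all()].
#' @param dir output directory.
#' @param write_reads also write per-stage read BEDs (large).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir, write_reads = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(m, name) {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (nm in names(sim$expr)) wt(sim$expr[[nm]], paste0(nm, ".tsv"))
  write_refflat(sim$layout$genes, file.path(dir, "genes.refflat"))
  if (!is.null(sim$epi)) {
    for (lin in names(sim$epi)) {
      for (mark in names(sim$epi[[lin]]$peaks)) {
        pk <- sim$epi[[lin]]$peaks[[mark]]
        for (st in names(pk)) {
          write_bed(pk[[st]], file.path(dir, sprintf("peaks_%s_%s_%s.bed",
                                                     lin, mark, st)))
        }
      }
      if (write_reads) {
        for (mark in names(sim$epi[[lin]]$reads)) {
          rd <- sim$epi[[lin]]$reads[[mark]]
          for (st in names(rd)) {
            write_bed(rd[[st]], file.path(
              dir, sprintf("reads_%s_%s_%s.bed", lin, mark, st)))
          }
        }
      }
    }
  }
  if (!is.null(sim$tf) && length(sim$tf$peaks)) {
    write_bed(sim$tf$peaks, file.path(dir, "tf_peaks.bed"))
  }
  td <- sim$truth$genes
  utils::write.table(td, file.path(dir, "truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$layout$enhancers,
                     file.path(dir, "truth_enhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$layout$se, file.path(dir, "truth_se.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$cfg
  scalars <- cfg[vapply(cfg, function(v)
    is.atomic(v) && length(v) <= 5, TRUE)]
  manifest <- vapply(names(scalars), function(k) {
    sprintf("%s: %s", k, paste(scalars[[k]], collapse = ","))
  }, "")
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
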