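#' Configuration for the synthetic adipogenesis fixture
#'
#' Builds the parameter set for the synthetic-data generator. The defaults
#' define the standard fixture: two lineages sampled at five stages, 2,000
#' coding genes laid out over a two-chromosome genome, 200 planted
#' stage-specific genes per lineage (40 per stage), lineage-specific /
#' common / transiently induced gene groups, 200 planted stage-specific
#' enhancers per lineage, and 20 super-enhancer loci per lineage whose
#' H3K27ac signal co-varies with a planted target gene. Planted signal is a
#' 20-fold elevation over baseline, and every expression value carries
#' multiplicative lognormal noise (sd 0.2 on the log2 scale).
#'
#' The genome is laid out deterministically: chromosome 1 carries regular
#' gene slots (one distal enhancer position each) and chromosome 2 carries
#' the super-enhancer slots, each holding a target gene, an enhancer
#' cluster 15-41 kb downstream, and three expressed decoy genes inside the
#' 100 kb assignment window. Chromosome lengths are derived from the slot
#' counts (about 10.9 Mb and 10 Mb at defaults).
#'
#' @param seed integer random seed; recorded in every output.
#' @param n_genes total coding genes (default 2000).
#' @param n_per_stage planted stage-specific genes per stage per lineage
#'   (default 40).
#' @param n_ba_specific,n_wa_specific,n_common,n_bmp7 planted lineage-class
#'   group sizes (defaults 60, 60, 60, 50).
#' @param n_se super-enhancer loci per lineage (default 20).
#' @param n_enh_per_stage planted stage-specific enhancers per stage per
#'   lineage (default 40).
#' @param n_typical background (stage-independent) enhancers (default 1300).
#' @param n_weak_clusters weak stitched clusters of three adjacent
#'   enhancers, giving the ranked super-enhancer curve its low tail
#'   (default 10).
#' @param n_lncrna,n_lnc_per_stage,n_lnc_lineage lncRNA universe and
#'   planted sizes (defaults 300, 10, 20).
#' @param n_mirna,n_mirna_per_stage miRNA universe and planted sizes
#'   (defaults 150, 8).
#' @param baseline_log2_mean,baseline_log2_sd lognormal baseline FPKM
#'   parameters (defaults 3, 1: median 8 FPKM).
#' @param effect fold elevation of planted signal (default 20).
#' @param noise_sd multiplicative noise sd on the log2 scale (default 0.2).
#' @param reads_per_stage H3K27ac reads per stage per library
#'   (default 1e6).
#' @param reads_per_stage_minor reads per stage for H3K4me1 / H3K27me3
#'   (default 2e5).
#' @param stages_ba,stages_wa ordered stage labels.
#' @param tf_n_peaks,tf_proportions,tf_enrich TF peak simulation: number of
#'   peaks, element-class proportions (must sum to 1), and the placement
#'   enrichment factor for BA-specific/common genes (defaults 600,
#'   promoter/intron/exon/intergenic = .35/.25/.10/.30, 4).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 2000,
                       n_per_stage = 40,
                       n_ba_specific = 60, n_wa_specific = 60,
                       n_common = 60, n_bmp7 = 50,
                       n_se = 20,
                       n_enh_per_stage = 40,
                       n_typical = 1300,
                       n_weak_clusters = 10,
                       n_lncrna = 300, n_lnc_per_stage = 10,
                       n_lnc_lineage = 20,
                       n_mirna = 150, n_mirna_per_stage = 8,
                       baseline_log2_mean = 3, baseline_log2_sd = 1,
                       effect = 20, noise_sd = 0.2,
                       reads_per_stage = 1e6,
                       reads_per_stage_minor = 2e5,
                       stages_ba = c("d-3", "d0", "6h", "d2", "d7"),
                       stages_wa = c("d-4", "d0", "6h", "d2", "d7"),
                       tf_n_peaks = 600,
                       tf_proportions = c(promoter = 0.35, intron = 0.25,
                                          exon = 0.10, intergenic = 0.30),
                       tf_enrich = 4) {
  # fixed geometry (bases)
  slot1 <- 6200          # chr1 gene slot: gene + one distal enhancer site
  slot_se <- 250000      # chr2 SE slot: target + cluster + decoys
  n_se_slots <- 2 * n_se
  genes_per_se_slot <- 6 # target + 3 decoys + 2 fillers
  n_chr2_genes <- n_se_slots * genes_per_se_slot
  n_chr1 <- n_genes - n_chr2_genes
  n_stages <- length(stages_ba)
  cfg <- list(
    seed = as.integer(seed),
    n_genes = n_genes, n_chr1 = n_chr1,
    n_per_stage = n_per_stage,
    n_ba_specific = n_ba_specific, n_wa_specific = n_wa_specific,
    n_common = n_common, n_bmp7 = n_bmp7,
    n_se = n_se, n_se_slots = n_se_slots,
    genes_per_se_slot = genes_per_se_slot,
    n_enh_per_stage = n_enh_per_stage, n_typical = n_typical,
    n_weak_clusters = n_weak_clusters,
    n_lncrna = n_lncrna, n_lnc_per_stage = n_lnc_per_stage,
    n_lnc_lineage = n_lnc_lineage,
    n_mirna = n_mirna, n_mirna_per_stage = n_mirna_per_stage,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    effect = effect, noise_sd = noise_sd,
    reads_per_stage = reads_per_stage,
    reads_per_stage_minor = reads_per_stage_minor,
    stages_ba = stages_ba, stages_wa = stages_wa,
    tf_n_peaks = tf_n_peaks, tf_proportions = tf_proportions,
    tf_enrich = tf_enrich,
    slot1 = slot1, slot_se = slot_se,
    read_len = 36, bg_frac = 0.15,
    chrom_lengths = c(chr1 = n_chr1 * slot1,
                      chr2 = n_se_slots * slot_se)
  )
  n_stage_specific <- 2 * n_stages * n_per_stage
  n_planted <- n_stage_specific + n_ba_specific + n_wa_specific +
    n_common + n_bmp7
  if (n_planted > n_chr1) {
    stop("planted gene groups (", n_planted, ") exceed the ", n_chr1,
         " chromosome-1 gene slots")
  }
  if (2 * n_stages * n_enh_per_stage + n_typical +
      6 * n_weak_clusters > n_chr1) {
    stop("enhancer placements exceed chromosome-1 slots")
  }
  if (abs(sum(tf_proportions) - 1) > 1e-9) {
    stop("tf_proportions must sum to 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

# ---- deterministic genome layout (no randomness) -------------------------

# gene-model table plus enhancer / SE placements implied by the config
layout_genome <- function(cfg) {
  s1 <- cfg$slot1
  # chromosome 1: short two-exon genes, one enhancer site per slot
  slot_start1 <- (seq_len(cfg$n_chr1) - 1) * s1
  g1 <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_chr1)),
    tx_id = sprintf("tx%04d", seq_len(cfg$n_chr1)),
    chrom = "chr1", strand = "+",
    tx_start = slot_start1 + 1000, tx_end = slot_start1 + 3000,
    stringsAsFactors = FALSE
  )
  g1$tss <- g1$tx_start
  g1$exon_starts <- lapply(slot_start1, function(s) c(s + 1000, s + 2200))
  g1$exon_ends <- lapply(slot_start1, function(s) c(s + 1800, s + 3000))
  g1$role <- "regular"
  g1$se_id <- NA_character_

  # chromosome 2: SE slots, six longer three-exon genes each
  offs <- c(1000, 60000, 78000, 96000, 150000, 200000)
  roles <- c("se_target", "decoy", "decoy", "decoy", "filler", "filler")
  strands <- c("+", "+", "-", "+", "-", "+")
  slot_start2 <- rep((seq_len(cfg$n_se_slots) - 1) * cfg$slot_se,
                     each = cfg$genes_per_se_slot)
  off2 <- rep(offs, cfg$n_se_slots)
  strand2 <- rep(strands, cfg$n_se_slots)
  idx2 <- cfg$n_chr1 + seq_len(cfg$n_se_slots * cfg$genes_per_se_slot)
  body_start <- slot_start2 + off2
  g2 <- data.frame(
    gene_id = sprintf("g%04d", idx2),
    tx_id = sprintf("tx%04d", idx2),
    chrom = "chr2", strand = strand2,
    tx_start = body_start, tx_end = body_start + 6000,
    stringsAsFactors = FALSE
  )
  g2$tss <- ifelse(g2$strand == "+", g2$tx_start, g2$tx_end)
  g2$exon_starts <- lapply(body_start, function(s) c(s, s + 3000, s + 5400))
  g2$exon_ends <- lapply(body_start, function(s) c(s + 600, s + 3600, s + 6000))
  g2$role <- rep(roles, cfg$n_se_slots)
  se_lineage <- rep(c("BA", "WA"), each = cfg$n_se)
  se_ids <- sprintf("%s_se%02d", se_lineage,
                    c(seq_len(cfg$n_se), seq_len(cfg$n_se)))
  g2$se_id <- rep(se_ids, each = cfg$genes_per_se_slot)
  g2$se_id[g2$role == "filler"] <- NA_character_

  genes <- rbind(g1, g2)
  rownames(genes) <- NULL

  # enhancer sites: one per chr1 slot at [3600, 4600), outside every
  # TSS +- 2.5 kb window
  enh_start <- slot_start1 + 3600
  n_st <- length(cfg$stages_ba)
  n_ss <- n_st * cfg$n_enh_per_stage
  role_enh <- rep("unused", cfg$n_chr1)
  role_enh[seq_len(n_ss)] <- "ss_ba"
  role_enh[n_ss + seq_len(n_ss)] <- "ss_wa"
  role_enh[2 * n_ss + seq_len(cfg$n_typical)] <- "typical"
  # weak clusters: 3 adjacent sites (stitchable, 5.2 kb gaps) separated by
  # 3 empty slots (17.6 kb, beyond the stitch gap) so clusters stay apart
  base_wk <- 2 * n_ss + cfg$n_typical
  wk <- base_wk + as.vector(vapply(seq_len(cfg$n_weak_clusters),
                                   function(j) (j - 1L) * 6L + 1:3,
                                   integer(3)))
  role_enh[wk] <- "weak"
  enh <- data.frame(
    chrom = "chr1", start = enh_start, end = enh_start + 1000,
    role = role_enh,
    stage = NA_character_, weak_cluster = NA_integer_,
    stringsAsFactors = FALSE
  )
  # round-robin stage assignment keeps same-stage enhancers ~31 kb apart,
  # so they never stitch into a common span at their own stage
  enh$stage[seq_len(n_ss)] <-
    rep(cfg$stages_ba, times = cfg$n_enh_per_stage)
  enh$stage[n_ss + seq_len(n_ss)] <-
    rep(cfg$stages_wa, times = cfg$n_enh_per_stage)
  enh$weak_cluster[wk] <- rep(seq_len(cfg$n_weak_clusters), each = 3)
  enh <- enh[enh$role != "unused", , drop = FALSE]

  # SE constituent clusters: four 2 kb constituents, 6 kb gaps, spanning
  # slot + [15000, 41000)
  con_off <- c(15000, 23000, 31000, 39000)
  se_slot_start <- (seq_len(cfg$n_se_slots) - 1) * cfg$slot_se
  se <- data.frame(
    se_id = se_ids,
    lineage = se_lineage,
    chrom = "chr2",
    span_start = se_slot_start + con_off[1],
    span_end = se_slot_start + con_off[4] + 2000,
    target = genes$gene_id[genes$role == "se_target"],
    stringsAsFactors = FALSE
  )
  cons <- data.frame(
    se_id = rep(se_ids, each = 4),
    lineage = rep(se_lineage, each = 4),
    chrom = "chr2",
    start = rep(se_slot_start, each = 4) + rep(con_off, cfg$n_se_slots),
    stringsAsFactors = FALSE
  )
  cons$end <- cons$start + 2000
  list(genes = genes, enhancers = enh, se = se, constituents = cons)
}

# ---- expression ----------------------------------------------------------

# stage-shape templates on the multiplicative scale
ramp_shape <- c(1, 2, 4, 8, 16)
decoy_shapes <- list(c(1, 1.4, 0.7, 1.2, 0.9),
                     c(1.2, 0.8, 1.3, 0.9, 1.1),
                     c(0.9, 1.2, 1.1, 0.7, 1.3))

#' Simulate expression matrices with planted ground truth
#'
#' Generates FPKM matrices (coding and lncRNA) and miRNA array-signal
#' matrices for both lineages. Background features are stage-independent
#' lognormal; planted stage-specific features are elevated
#' (baseline x effect) in one stage and near-zero elsewhere;
#' lineage-specific genes are elevated at d7 of one lineage only; common
#' genes at d7 of both; transiently induced genes at d0 of the BA lineage
#' only; super-enhancer target genes follow a rising ramp peaking at d7.
#' All values carry multiplicative lognormal noise.
#'
#' The returned ground truth records the planted class of every feature
#' and the expected stage / lineage calls implied by the noise-free mean
#' profiles (evaluated with the same selection predicates the pipeline
#' uses, so recovery can be scored fairly for genes whose construction
#' makes them legitimately selectable, e.g. d7-elevated lineage genes).
#'
#' @param cfg a [sim_config()].
#' @return A list: `expr` (matrices `ba`, `wa`, `lnc_ba`, `lnc_wa`,
#'   `mirna_ba`, `mirna_wa`), `clean` (noise-free mean matrices), `truth`
#'   (see details), `layout`, `cfg`.
#' @export
simulate_expression <- function(cfg) {
  set.seed(cfg$seed)
  lay <- layout_genome(cfg)
  genes <- lay$genes
  n <- nrow(genes)
  n_st <- length(cfg$stages_ba)
  base <- 2^stats::rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)

  # assign planted expression classes to chr1 genes, sequentially
  cls <- rep("background", n)
  stage_of <- rep(NA_character_, n)
  lineage_of <- rep(NA_character_, n)
  pos <- 0
  take <- function(k) {
    out <- pos + seq_len(k)
    pos <<- pos + k
    out
  }
  for (lin in c("BA", "WA")) {
    stages <- if (lin == "BA") cfg$stages_ba else cfg$stages_wa
    for (s in stages) {
      idx <- take(cfg$n_per_stage)
      cls[idx] <- "stage_specific"
      stage_of[idx] <- s
      lineage_of[idx] <- lin
    }
  }
  idx <- take(cfg$n_ba_specific); cls[idx] <- "ba_specific"
  idx <- take(cfg$n_wa_specific); cls[idx] <- "wa_specific"
  idx <- take(cfg$n_common);      cls[idx] <- "common"
  idx <- take(cfg$n_bmp7);        cls[idx] <- "bmp7_transient"
  cls[genes$role == "se_target"] <- "se_target"
  lineage_of[genes$role == "se_target"] <-
    lay$se$lineage[match(genes$se_id[genes$role == "se_target"],
                         lay$se$se_id)]
  cls[genes$role == "decoy"] <- "decoy"

  # noise-free mean profiles per lineage
  off <- function(k) stats::runif(k, 0.05, 1)   # near-zero FPKM
  clean_ba <- matrix(0, n, n_st, dimnames = list(genes$gene_id,
                                                 cfg$stages_ba))
  clean_wa <- matrix(0, n, n_st, dimnames = list(genes$gene_id,
                                                 cfg$stages_wa))
  d7 <- n_st  # last stage index
  d0 <- 2L
  for (i in seq_len(n)) {
    flat_ba <- rep(base[i], n_st)
    flat_wa <- rep(base[i], n_st)
    low_ba <- off(n_st)
    low_wa <- off(n_st)
    hi <- base[i] * cfg$effect
    profs <- switch(cls[i],
      background = list(flat_ba, flat_wa),
      stage_specific = {
        if (lineage_of[i] == "BA") {
          p <- low_ba; p[match(stage_of[i], cfg$stages_ba)] <- hi
          list(p, low_wa)
        } else {
          p <- low_wa; p[match(stage_of[i], cfg$stages_wa)] <- hi
          list(low_ba, p)
        }
      },
      ba_specific = {
        p <- low_ba; p[d7] <- hi
        list(p, low_wa)
      },
      wa_specific = {
        p <- low_wa; p[d7] <- hi
        list(low_ba, p)
      },
      common = {
        p <- low_ba; p[d7] <- hi
        q <- low_wa; q[d7] <- hi * 2^stats::runif(1, -0.5, 0.5)
        list(p, q)
      },
      bmp7_transient = {
        p <- low_ba; p[d0] <- hi
        list(p, low_wa)
      },
      se_target = {
        if (lineage_of[i] == "BA") list(base[i] * ramp_shape, low_wa)
        else list(low_ba, base[i] * ramp_shape)
      },
      decoy = {
        shape <- decoy_shapes[[1L + (i %% 3L)]]
        list(base[i] * shape, base[i] * shape)
      },
      list(flat_ba, flat_wa)
    )
    clean_ba[i, ] <- profs[[1L]]
    clean_wa[i, ] <- profs[[2L]]
  }

  noisy <- function(m) m * 2^matrix(stats::rnorm(length(m), 0, cfg$noise_sd),
                                    nrow(m))
  ba <- noisy(clean_ba)
  wa <- noisy(clean_wa)

  # lncRNAs: lower baseline, same planting scheme (stage-specific +
  # d7 lineage-specific); threshold downstream is FPKM > 0.5
  ln <- cfg$n_lncrna
  lnc_ids <- sprintf("lnc%03d", seq_len(ln))
  lbase <- 2^stats::rnorm(ln, 1, 0.8)
  lcls <- rep("background", ln)
  lstage <- rep(NA_character_, ln)
  llin <- rep(NA_character_, ln)
  pos <- 0
  for (lin in c("BA", "WA")) {
    stages <- if (lin == "BA") cfg$stages_ba else cfg$stages_wa
    for (s in stages) {
      idx <- take(cfg$n_lnc_per_stage)
      lcls[idx] <- "stage_specific"; lstage[idx] <- s; llin[idx] <- lin
    }
  }
  idx <- take(cfg$n_lnc_lineage); lcls[idx] <- "ba_specific"
  idx <- take(cfg$n_lnc_lineage); lcls[idx] <- "wa_specific"
  loff <- function(k) stats::runif(k, 0.01, 0.3)
  clean_lba <- matrix(0, ln, n_st, dimnames = list(lnc_ids, cfg$stages_ba))
  clean_lwa <- matrix(0, ln, n_st, dimnames = list(lnc_ids, cfg$stages_wa))
  for (i in seq_len(ln)) {
    hi <- lbase[i] * cfg$effect
    lb <- loff(n_st); lw <- loff(n_st)
    if (lcls[i] == "background") {
      clean_lba[i, ] <- lbase[i]; clean_lwa[i, ] <- lbase[i]
    } else if (lcls[i] == "stage_specific") {
      if (llin[i] == "BA") {
        lb[match(lstage[i], cfg$stages_ba)] <- hi
      } else {
        lw[match(lstage[i], cfg$stages_wa)] <- hi
      }
      clean_lba[i, ] <- lb; clean_lwa[i, ] <- lw
    } else if (lcls[i] == "ba_specific") {
      lb[d7] <- hi
      clean_lba[i, ] <- lb; clean_lwa[i, ] <- lw
    } else {
      lw[d7] <- hi
      clean_lba[i, ] <- lb; clean_lwa[i, ] <- lw
    }
  }
  lnc_ba <- noisy(clean_lba)
  lnc_wa <- noisy(clean_lwa)

  # miRNA array signal: lognormal background, planted 5-fold spikes
  nm <- cfg$n_mirna
  mir_ids <- sprintf("mir%03d", seq_len(nm))
  mbase <- 2^stats::rnorm(nm, 6, 0.8)
  mcls <- rep("background", nm)
  mstage <- rep(NA_character_, nm)
  mlin <- rep(NA_character_, nm)
  pos <- 0
  for (lin in c("BA", "WA")) {
    stages <- if (lin == "BA") cfg$stages_ba else cfg$stages_wa
    for (s in stages) {
      idx <- take(cfg$n_mirna_per_stage)
      mcls[idx] <- "stage_specific"; mstage[idx] <- s; mlin[idx] <- lin
    }
  }
  clean_mba <- matrix(mbase, nm, n_st, dimnames = list(mir_ids,
                                                       cfg$stages_ba))
  clean_mwa <- matrix(mbase, nm, n_st, dimnames = list(mir_ids,
                                                       cfg$stages_wa))
  for (i in which(mcls == "stage_specific")) {
    if (mlin[i] == "BA") {
      clean_mba[i, match(mstage[i], cfg$stages_ba)] <- mbase[i] * 5
    } else {
      clean_mwa[i, match(mstage[i], cfg$stages_wa)] <- mbase[i] * 5
    }
  }
  mirna_ba <- noisy(clean_mba)
  mirna_wa <- noisy(clean_mwa)

  truth <- list(
    genes = data.frame(gene_id = genes$gene_id, class = cls,
                       stage = stage_of, lineage = lineage_of,
                       role = genes$role, se_id = genes$se_id,
                       stringsAsFactors = FALSE),
    lnc = data.frame(feature_id = lnc_ids, class = lcls, stage = lstage,
                     lineage = llin, stringsAsFactors = FALSE),
    mirna = data.frame(feature_id = mir_ids, class = mcls, stage = mstage,
                       lineage = mlin, stringsAsFactors = FALSE),
    expected = expected_calls(clean_ba, clean_wa, clean_lba, clean_lwa),
    seed = cfg$seed
  )
  list(
    expr = list(ba = ba, wa = wa, lnc_ba = lnc_ba, lnc_wa = lnc_wa,
                mirna_ba = mirna_ba, mirna_wa = mirna_wa),
    clean = list(ba = clean_ba, wa = clean_wa, lnc_ba = clean_lba,
                 lnc_wa = clean_lwa, mirna_ba = clean_mba,
                 mirna_wa = clean_mwa),
    truth = truth, layout = lay, cfg = cfg
  )
}

# expected stage-specific and lineage calls implied by noise-free profiles,
# evaluated with an inline restatement of the selection predicates
expected_calls <- function(clean_ba, clean_wa, clean_lba, clean_lwa) {
  stage_calls <- function(m, thr) {
    h <- entropy_score(m)
    high <- m > thr
    n_high <- rowSums(high)
    out <- list()
    for (j in seq_len(ncol(m))) {
      keep <- !is.na(h) & h < 2 & high[, j] & (n_high - 1) <= 3
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          feature_id = rownames(m)[keep], stage = colnames(m)[j],
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- data.frame(feature_id = character(),
                                        stage = character())
    res
  }
  st_ba <- stage_calls(clean_ba, 5)
  st_wa <- stage_calls(clean_wa, 5)
  # expected lineage classes over the pooled clean d7 stage-specific genes
  d7_ba <- st_ba$feature_id[st_ba$stage == colnames(clean_ba)[ncol(clean_ba)]]
  d7_wa <- st_wa$feature_id[st_wa$stage == colnames(clean_wa)[ncol(clean_wa)]]
  pooled <- union(d7_ba, d7_wa)
  ba7 <- clean_ba[pooled, ncol(clean_ba)]
  wa7 <- clean_wa[pooled, ncol(clean_wa)]
  ba_s <- ba7 >= 3 * wa7 & wa7 < 10 & ba7 > 0
  wa_s <- wa7 >= 3 * ba7 & ba7 < 10 & wa7 > 0
  lin_cls <- ifelse(ba_s & !wa_s, "BA_specific",
                    ifelse(wa_s & !ba_s, "WA_specific", "common"))
  list(
    stage_ba = st_ba, stage_wa = st_wa,
    stage_lnc_ba = stage_calls(clean_lba, 0.5),
    stage_lnc_wa = stage_calls(clean_lwa, 0.5),
    lineage = data.frame(feature_id = pooled, class = lin_cls,
                         row.names = NULL, stringsAsFactors = FALSE)
  )
}

# ---- epigenome -----------------------------------------------------------

# draw reads for one stage: multinomial over weighted regions plus uniform
# background over the genome
sample_stage_reads <- function(regions, weights, depth, cfg) {
  w <- weights * (regions$end - regions$start) / 1000   # rate per kb -> mass
  bg <- sum(w) * cfg$bg_frac / (1 - cfg$bg_frac)
  counts <- as.vector(stats::rmultinom(1, depth, c(w, bg)))
  n_reg <- nrow(regions)
  reg_counts <- counts[seq_len(n_reg)]
  ri <- rep.int(seq_len(n_reg), reg_counts)
  span <- regions$end[ri] - regions$start[ri] - cfg$read_len
  starts <- regions$start[ri] + floor(stats::runif(length(ri)) * pmax(span, 1))
  # background reads
  n_bg <- counts[n_reg + 1L]
  chr_len <- cfg$chrom_lengths
  bg_chr <- sample(names(chr_len), n_bg, replace = TRUE,
                   prob = chr_len / sum(chr_len))
  bg_start <- floor(stats::runif(n_bg) * (chr_len[bg_chr] - cfg$read_len))
  chrom <- c(regions$chrom[ri], bg_chr)
  start <- c(starts, bg_start)
  strand <- sample(c("+", "-"), length(start), replace = TRUE)
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1, width = cfg$read_len),
    strand = strand,
    seqlengths = chr_len
  )
}

#' Simulate the per-lineage epigenome
#'
#' Places H3K27ac and H3K4me3 peaks and samples per-stage ChIP read
#' intervals for one lineage, given the expression simulation (whose
#' profiles drive promoter activity and super-enhancer signal):
#' H3K27ac/H3K4me3 at promoters of expressed genes, H3K27ac at planted
#' stage-specific distal enhancers (signal concentrated in their stage), at
#' background enhancers (flat), and at SE constituent clusters whose
#' per-stage depth follows the planted target's ramp profile. H3K4me1
#' reads are co-placed with distal H3K27ac and additionally elevated at
#' BA-specific gene promoters in the BA lineage only; H3K27me3 reads are
#' spread uniformly over promoters in both lineages.
#'
#' @param sim output of [simulate_expression()].
#' @param lineage `"BA"` or `"WA"`.
#' @return A list: `peaks` (`h3k27ac`, `h3k4me3`: per-stage `GRanges`
#'   lists), `reads` (`h3k27ac`, `h3k4me1`, `h3k27me3`), `stages`.
#' @export
simulate_epigenome <- function(sim, lineage = c("BA", "WA")) {
  lineage <- match.arg(lineage)
  cfg <- sim$cfg
  set.seed(cfg$seed + 1L + (lineage == "WA"))
  lay <- sim$layout
  genes <- lay$genes
  stages <- if (lineage == "BA") cfg$stages_ba else cfg$stages_wa
  n_st <- length(stages)
  clean <- if (lineage == "BA") sim$clean$ba else sim$clean$wa
  active_gene <- apply(clean, 1, max) > 1

  base_rate <- 8
  hi_rate <- base_rate * cfg$effect

  # region table: promoters (active genes), this lineage's stage-specific
  # enhancers, typical + weak enhancers, this lineage's SE constituents
  prom <- genes[active_gene, , drop = FALSE]
  prom_df <- data.frame(chrom = prom$chrom,
                        start = pmax(prom$tss - 1000, 0),
                        end = prom$tss + 1000,
                        stringsAsFactors = FALSE)
  enh <- lay$enhancers
  own_ss <- enh[enh$role == paste0("ss_", tolower(lineage)), , drop = FALSE]
  typ <- enh[enh$role %in% c("typical", "weak"), , drop = FALSE]
  cons <- lay$constituents[lay$constituents$lineage == lineage, ,
                           drop = FALSE]
  regions <- rbind(
    prom_df,
    own_ss[, c("chrom", "start", "end")],
    typ[, c("chrom", "start", "end")],
    cons[, c("chrom", "start", "end")]
  )

  # per-stage rate matrix (rate per kb)
  w <- matrix(0, nrow(regions), n_st)
  n_prom <- nrow(prom_df)
  w[seq_len(n_prom), ] <- base_rate
  off_ss <- n_prom
  for (i in seq_len(nrow(own_ss))) {
    w[off_ss + i, ] <- base_rate * 0.05
    w[off_ss + i, match(own_ss$stage[i], stages)] <- hi_rate
  }
  off_typ <- off_ss + nrow(own_ss)
  typ_rate <- ifelse(typ$role == "weak", base_rate * 2, base_rate)
  w[off_typ + seq_len(nrow(typ)), ] <-
    typ_rate * 2^stats::rnorm(nrow(typ) * n_st, 0, cfg$noise_sd)
  off_con <- off_typ + nrow(typ)
  ramp <- ramp_shape / max(ramp_shape)
  # constituent rate peaks well above the background enhancers (so the
  # stitched spans rank clearly above the weak clusters) but below the
  # z > 1 band of the stage-specific enhancers: a super-enhancer is a
  # broad cluster of moderately active constituents, not a single
  # hyper-active peak
  se_rate <- base_rate * 3.75
  for (i in seq_len(nrow(cons))) {
    w[off_con + i, ] <- se_rate * ramp
  }

  # peaks: a region is peak-called at a stage when its rate is substantial
  peak_at <- w >= base_rate * 0.5
  k27ac_peaks <- lapply(seq_len(n_st), function(j) {
    r <- regions[peak_at[, j], , drop = FALSE]
    granges0(r$chrom, r$start, r$end)
  })
  names(k27ac_peaks) <- stages
  k4me3_peaks <- lapply(stages, function(s) {
    granges0(prom_df$chrom, prom_df$start, prom_df$end)
  })
  names(k4me3_peaks) <- stages

  k27ac_reads <- lapply(seq_len(n_st), function(j) {
    sample_stage_reads(regions, w[, j], cfg$reads_per_stage, cfg)
  })
  names(k27ac_reads) <- stages

  # H3K4me1: co-placed with distal H3K27ac; BA-specific promoters carry
  # extra H3K4me1 in the BA lineage only
  w1 <- w
  w1[seq_len(n_prom), ] <- base_rate * 0.5
  if (lineage == "BA") {
    ba_spec <- sim$truth$genes$gene_id[sim$truth$genes$class == "ba_specific"]
    boost <- prom$gene_id %in% ba_spec
    w1[seq_len(n_prom)[boost], ] <- base_rate * 4
  }
  k4me1_reads <- lapply(seq_len(n_st), function(j) {
    sample_stage_reads(regions, w1[, j], cfg$reads_per_stage_minor, cfg)
  })
  names(k4me1_reads) <- stages

  # H3K27me3: uniform over all promoters, identical scheme in both lineages
  all_prom <- data.frame(chrom = genes$chrom,
                         start = pmax(genes$tss - 1000, 0),
                         end = genes$tss + 1000, stringsAsFactors = FALSE)
  k27me3_reads <- lapply(seq_len(n_st), function(j) {
    sample_stage_reads(all_prom, rep(base_rate, nrow(all_prom)),
                       cfg$reads_per_stage_minor, cfg)
  })
  names(k27me3_reads) <- stages

  list(
    peaks = list(h3k27ac = k27ac_peaks, h3k4me3 = k4me3_peaks),
    reads = list(h3k27ac = k27ac_reads, h3k4me1 = k4me1_reads,
                 h3k27me3 = k27me3_reads),
    stages = stages, lineage = lineage
  )
}

#' Simulate TF binding peaks
#'
#' Places `tf_n_peaks` peaks into promoter / intron / exon / intergenic
#' space with the configured proportions. Promoter peaks preferentially
#' target BA-specific and common genes (factor `tf_enrich` relative to
#' other genes), emulating a brown-lineage TF. Each peak carries a read
#' count (its signal), doubled at the enriched promoters.
#'
#' @param sim output of [simulate_expression()].
#' @return A list: `peaks` (`GRanges` with `name` = class), `signal`
#'   (per-peak read counts), `lib_size`, `truth` (placement table).
#' @export
simulate_tf_peaks <- function(sim) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 3L)
  genes <- sim$layout$genes
  props <- cfg$tf_proportions
  if (abs(sum(props) - 1) > 1e-9) stop("tf_proportions must sum to 1")
  n <- cfg$tf_n_peaks
  if (n == 0L) {
    return(list(peaks = GenomicRanges::GRanges(), signal = numeric(0),
                lib_size = 0, truth = NULL))
  }
  n_cls <- round(props * n)
  n_cls[1] <- n - sum(n_cls[-1])
  cls_truth <- sim$truth$genes$class

  # promoter peaks: weighted gene choice, peak centred on the TSS
  wgt <- ifelse(cls_truth %in% c("ba_specific", "common"), cfg$tf_enrich, 1)
  gi <- sample(nrow(genes), n_cls["promoter"], replace = TRUE, prob = wgt)
  prom_peaks <- data.frame(chrom = genes$chrom[gi],
                           start = pmax(genes$tss[gi] - 200, 0),
                           end = genes$tss[gi] + 200,
                           class = "promoter", host = genes$gene_id[gi],
                           stringsAsFactors = FALSE)
  enriched <- cls_truth[gi] %in% c("ba_specific", "common")

  # intron / exon peaks on the long chr2 gene bodies (their intron and
  # middle-exon space lies outside every promoter window)
  chr2 <- which(genes$chrom == "chr2" & genes$strand == "+")
  gi2 <- sample(chr2, n_cls["intron"], replace = TRUE)
  intr_peaks <- data.frame(chrom = genes$chrom[gi2],
                           start = genes$tx_start[gi2] + 2600,
                           end = genes$tx_start[gi2] + 2900,
                           class = "intron", host = genes$gene_id[gi2],
                           stringsAsFactors = FALSE)
  gi3 <- sample(chr2, n_cls["exon"], replace = TRUE)
  exon_peaks <- data.frame(chrom = genes$chrom[gi3],
                           start = genes$tx_start[gi3] + 3100,
                           end = genes$tx_start[gi3] + 3500,
                           class = "exon", host = genes$gene_id[gi3],
                           stringsAsFactors = FALSE)

  # intergenic peaks: the [106 kb, 146 kb) stretch of each chr2 SE slot is
  # clear of gene bodies and of every TSS / TTS window
  slot <- sample(cfg$n_se_slots, n_cls["intergenic"], replace = TRUE)
  slot_start <- (slot - 1) * cfg$slot_se
  int_off <- 106000 + floor(stats::runif(n_cls["intergenic"]) * 40000)
  int_peaks <- data.frame(chrom = "chr2",
                          start = slot_start + int_off,
                          end = slot_start + int_off + 400,
                          class = "intergenic", host = NA_character_,
                          stringsAsFactors = FALSE)

  pk <- rbind(prom_peaks, intr_peaks, exon_peaks, int_peaks)
  signal <- stats::rpois(nrow(pk), 100)
  signal[seq_len(nrow(prom_peaks))][enriched] <-
    stats::rpois(sum(enriched), 200)
  gr <- GenomicRanges::GRanges(pk$chrom,
                               IRanges::IRanges(pk$start + 1, pk$end),
                               name = pk$class)
  list(peaks = gr, signal = signal, lib_size = sum(signal),
       truth = pk)
}

#' Generate the complete synthetic fixture
#'
#' One-call wrapper: expression for both lineages, per-lineage epigenomes,
#' and TF peaks, with the shared ground truth.
#'
#' @param cfg a [sim_config()].
#' @return A list: everything from [simulate_expression()] plus `epi`
#'   (`$BA`, `$WA`) and `tf`.
#' @export
simulate_all <- function(cfg) {
  sim <- simulate_expression(cfg)
  sim$epi <- list(BA = simulate_epigenome(sim, "BA"),
                  WA = simulate_epigenome(sim, "WA"))
  sim$tf <- simulate_tf_peaks(sim)
  sim
}
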