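#' Shannon-entropy stage-specificity score
#'
#' For a feature with expression `Ei` across `N` ordered stages, the
#' relative expression is `Ri = Ei / sum(E)` and the specificity score is
#' `H = -sum(Ri * log2(Ri))` (with `0 * log2(0) = 0`). `H` ranges from 0
#' (expressed in a single stage) to `log2(N)` (uniform expression), so low
#' entropy marks stage-specific features.
#'
#' @param e non-negative expression vector (one feature across stages) or a
#'   feature x stage matrix.
#' @return For a vector, a list with `H` (entropy in bits; `NA` when the
#'   feature is entirely silent, `sum(E) == 0`) and `R` (relative
#'   expression). For a matrix, a numeric vector of `H` per row.
#' @export
entropy_score <- function(e) {
  if (is.matrix(e)) {
    if (any(e < 0)) stop("expression values must be >= 0")
    tot <- rowSums(e)
    r <- e / ifelse(tot > 0, tot, NA_real_)
    lg <- ifelse(r > 0, log2(r), 0)
    h <- -rowSums(r * lg)
    h[tot == 0] <- NA_real_
    return(h)
  }
  if (any(e < 0)) stop("expression values must be >= 0")
  tot <- sum(e)
  if (tot == 0) return(list(H = NA_real_, R = rep(NA_real_, length(e))))
  r <- e / tot
  h <- -sum(r[r > 0] * log2(r[r > 0]))
  list(H = h, R = r)
}

#' Select stage-specific features by entropy and expression breadth
#'
#' A feature is assigned to stage `s` when (1) its entropy is below
#' `entropy_max`, (2) it is highly expressed in `s`
#' (`E > expr_min`), and (3) high expression is seen in at most
#' `max_additional_stages` other stages. A feature can be assigned to
#' several stages; silent features (all-zero) are never assigned.
#'
#' Default expression cutoffs by feature class: FPKM > 5 for coding genes,
#' FPKM > 0.5 for lncRNAs. All inequalities are strict.
#'
#' @param expr feature x stage matrix (FPKM), rownames = feature ids.
#' @param feature_class `"coding"`, `"lncRNA"`, or a per-feature vector.
#' @param entropy_max entropy cutoff in bits (default 2).
#' @param expr_min expression cutoff; default by `feature_class`.
#' @param max_additional_stages maximum number of additional stages allowed
#'   above `expr_min` (default 3).
#' @return A data.frame with one row per (feature, assigned stage):
#'   `feature_id`, `class`, `stage`, `H`, `expr`.
#' @export
select_stage_specific <- function(expr, feature_class = "coding",
                                  entropy_max = 2, expr_min = NULL,
                                  max_additional_stages = 3) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) rownames(expr) <- seq_len(nrow(expr))
  if (length(feature_class) == 1L) {
    feature_class <- rep(feature_class, nrow(expr))
  }
  known <- c(coding = 5, lncRNA = 0.5, miRNA = NA_real_)
  if (!all(feature_class %in% names(known))) {
    stop("unknown feature class: ",
         paste(setdiff(feature_class, names(known)), collapse = ", "))
  }
  thr <- if (is.null(expr_min)) known[feature_class] else
    rep_len(expr_min, nrow(expr))
  if (any(is.na(thr))) {
    stop("no default expression cutoff for this class; supply expr_min")
  }
  h <- entropy_score(expr)
  high <- expr > thr                      # feature x stage logical
  n_high <- rowSums(high)
  out <- vector("list", ncol(expr))
  for (j in seq_len(ncol(expr))) {
    keep <- !is.na(h) & h < entropy_max & high[, j] &
      (n_high - 1) <= max_additional_stages
    if (any(keep)) {
      out[[j]] <- data.frame(
        feature_id = rownames(expr)[keep],
        class = feature_class[keep],
        stage = colnames(expr)[j],
        H = h[keep],
        expr = expr[keep, j],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(feature_id = character(), class = character(),
                      stage = character(), H = numeric(), expr = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[order(match(res$stage, colnames(expr)), res$feature_id), ,
      drop = FALSE]
}

#' Quantile-normalize a microRNA array signal matrix
#'
#' Makes the per-stage signal distributions identical: values are replaced
#' by the mean, across stages, of the values at the same rank; ties receive
#' the mean of their spanned ranks.
#'
#' @param m feature x stage matrix of array signals.
#' @return Matrix of the same shape, quantile-normalized.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Select stage-specific microRNAs by fold variation
#'
#' Applied to quantile-normalized array signals: a miRNA is selected when
#' its maximum signal exceeds `min_fold` times its minimum (strictly,
#' "more than two-fold"), with the minimum floored at `floor` to avoid
#' unstable folds at the detection limit. Each selected miRNA is assigned
#' to its single maximum-expression stage; ties go to the earliest stage
#' and are flagged.
#'
#' @param m quantile-normalized feature x stage matrix.
#' @param min_fold fold-variation cutoff (default 2, strict).
#' @param floor detection floor applied to the minimum (default 1).
#' @return data.frame: `feature_id`, `stage`, `fold`, `tie`.
#' @export
select_stage_specific_mirna <- function(m, min_fold = 2, floor = 1) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  hi <- apply(m, 1, max)
  lo <- pmax(apply(m, 1, min), floor)
  fold <- hi / lo
  keep <- fold > min_fold
  if (!any(keep)) {
    return(data.frame(feature_id = character(), stage = character(),
                      fold = numeric(), tie = logical(),
                      stringsAsFactors = FALSE))
  }
  idx <- apply(m[keep, , drop = FALSE], 1, which.max)
  tie <- apply(m[keep, , drop = FALSE], 1, function(x) sum(x == max(x)) > 1)
  data.frame(
    feature_id = rownames(m)[keep],
    stage = colnames(m)[idx],
    fold = fold[keep],
    tie = tie,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select genes transiently induced by BMP7 pre-treatment
#'
#' During brown-lineage commitment the BMP7 window runs from d-3 (before
#' treatment) to d0 (after 3 days of treatment). A gene is called a
#' transient BMP7 target when it is induced at d0 relative to d-3
#' (`up_fold`), falls back again afterwards (`down_fold` against the
#' maximum of the later comparison stages), and is expressed at d0.
#'
#' @param expr BA feature x stage matrix containing the stages named in
#'   `pre`, `post` and `later`.
#' @param pre,post stage labels before/after treatment (defaults `"d-3"`,
#'   `"d0"`).
#' @param later stage labels used for the transience check (default
#'   `c("6h", "d2")`).
#' @param up_fold,down_fold induction / fall-back fold cutoffs (default 2).
#' @param expr_min minimum d0 expression (default 5 FPKM).
#' @return Character vector of selected gene ids.
#' @export
select_bmp7_transient <- function(expr, pre = "d-3", post = "d0",
                                  later = c("6h", "d2"),
                                  up_fold = 2, down_fold = 2, expr_min = 5) {
  expr <- as.matrix(expr)
  need <- c(pre, post, later)
  if (!all(need %in% colnames(expr))) {
    stop("required stages absent: ",
         paste(setdiff(need, colnames(expr)), collapse = ", "))
  }
  if (is.null(rownames(expr))) rownames(expr) <- seq_len(nrow(expr))
  e_pre <- expr[, pre]
  e_post <- expr[, post]
  e_later <- apply(expr[, later, drop = FALSE], 1, max)
  keep <- e_post >= up_fold * e_pre &
    e_post >= down_fold * e_later &
    e_post > expr_min
  rownames(expr)[keep]
}
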