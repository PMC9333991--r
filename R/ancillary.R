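#' Cylinder-rearing paw-use asymmetry
#'
#' `(% left paw use - % right paw use) / (% left paw use + % right paw use)`
#' with percentages computed from single-paw wall-contact times (both-paw
#' contacts enter neither numerator nor denominator).
#'
#' @param t_left,t_right,t_both contact times, s (vectorized);
#'   alternatively a data.frame with those columns as `t_left`.
#' @return asymmetry scores in [-1, 1]; `NA` when no single-paw contact was
#'   recorded.
#' @export
asymmetry_score <- function(t_left, t_right = NULL, t_both = NULL) {
  if (is.data.frame(t_left)) {
    d <- t_left; t_left <- d$t_left; t_right <- d$t_right
  }
  if (any(c(t_left, t_right) < 0, na.rm = TRUE)) stop("contact times must be >= 0")
  tot <- t_left + t_right
  ifelse(tot > 0, (t_left - t_right) / tot, NA_real_)
}

#' Baseline asymmetry exclusion
#'
#' Drops mice whose baseline paw-use asymmetry exceeds 50% toward either
#' limb (strict: |score| > 0.5).
#'
#' @param scores named numeric vector of per-mouse baseline scores.
#' @return the kept subset (same names).
#' @export
baseline_exclusion <- function(scores) {
  scores[!is.na(scores) & abs(scores) <= 0.5]
}

#' Infarct volume from serial sections
#'
#' Total infarct cross-sectional area times the section spacing
#' (300 um default).
#'
#' @param areas infarct area per section, mm^2.
#' @param spacing section spacing, mm (default 0.3).
#' @return volume in mm^3.
#' @export
infarct_volume <- function(areas, spacing = 0.3) {
  if (any(areas < 0)) stop("section areas must be non-negative")
  sum(areas) * spacing
}

#' Comparative Ct (2^-ddCt) relative expression
#'
#' Per sample, `dCt = Ct_gene - Ct_reference`; `ddCt` subtracts the mean dCt
#' of the control group per gene; relative level is `2^-ddCt` (control-group
#' geometric mean 1 by construction).  The reference gene itself maps to 1
#' for every sample.
#'
#' @param table an `expression_table` (see [simulate_expression()]) or a
#'   list with `ct` (genes x samples, including the reference row),
#'   `ref_gene`, `meta` (`sample`, `group`).
#' @param control_group label of the calibrator group.
#' @return list of class `relative_expression`: `levels` (genes x samples
#'   2^-ddCt matrix, reference row included), `ddct`, `meta`.
#' @export
comparative_ct <- function(table, control_group) {
  ct <- table$ct
  if (!table$ref_gene %in% rownames(ct)) stop("reference gene missing from table")
  if (!control_group %in% table$meta$group) stop("control group not present")
  dct <- sweep(ct, 2, ct[table$ref_gene, ])
  ctrl <- table$meta$group == control_group
  ddct <- dct - rowMeans(dct[, ctrl, drop = FALSE])
  structure(list(levels = 2^(-ddct), ddct = ddct, meta = table$meta,
                 ref_gene = table$ref_gene),
            class = "relative_expression")
}

#' Row normalization for expression clustering
#'
#' Per gene: subtract the cross-group mean and divide by the cross-group SD.
#' Genes with zero SD are excluded with a message.
#'
#' @param levels genes x groups matrix (e.g. group-mean relative levels).
#' @return normalized matrix (possibly fewer rows); attribute `excluded`
#'   lists dropped genes.
#' @export
normalize_for_clustering <- function(levels) {
  if (ncol(levels) < 2) stop("need at least 2 groups per gene")
  sds <- apply(levels, 1, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop))
    message(sum(drop), " constant gene(s) excluded from clustering")
  lv <- levels[!drop, , drop = FALSE]
  out <- (lv - rowMeans(lv)) / apply(lv, 1, stats::sd)
  attr(out, "excluded") <- rownames(levels)[drop]
  out
}

#' Hierarchical clustering of genes
#'
#' Average-linkage agglomerative clustering on Euclidean distances of the
#' normalized rows (`stats::hclust`).  The leaf order is canonicalized with
#' `reorder()` using content-based weights (each row's first-column value;
#' row means are zero after normalization), so permuting the input rows
#' yields the same tree topology and leaf sequence.
#'
#' @param mat normalized genes x groups matrix.
#' @return list of class `gene_clustering`: `hclust`, `leaf_order`
#'   (row names in display order).
#' @export
hierarchical_cluster <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 rows to cluster")
  hc <- stats::hclust(stats::dist(mat), method = "average")
  dd <- stats::reorder(stats::as.dendrogram(hc),
                       mat[, 1], agglo.FUN = mean)
  ord <- order.dendrogram(dd)
  list_out <- list(hclust = hc, leaf_order = rownames(mat)[ord],
                   order = ord)
  structure(list_out, class = "gene_clustering")
}

#' Fold-change table with Welch t and FDR flags
#'
#' Per gene (and tissue), the fold change of the treated group over the
#' control group on the relative-expression scale
#' (mean(2^-ddCt treated) / mean(2^-ddCt control)), with a two-tailed Welch
#' t-test on the log-scale ddCt values and Benjamini-Hochberg adjusted
#' q-values flagged at `q_flag`.
#'
#' @param rel a `relative_expression` from [comparative_ct()].
#' @param treated,control group labels.
#' @param q_flag FDR flag level (default 0.1).
#' @return data.frame: `gene`, `tissue`, `fold`, `t`, `dof`, `p`, `q`,
#'   `significant`.
#' @export
fold_change_table <- function(rel, treated, control, q_flag = 0.1) {
  genes <- setdiff(rownames(rel$levels), rel$ref_gene)
  tissues <- unique(rel$meta$tissue %||% "all")
  rows <- do.call(rbind, lapply(tissues, function(ts) {
    in_ts <- if (is.null(rel$meta$tissue)) rep(TRUE, nrow(rel$meta))
             else rel$meta$tissue == ts
    a <- in_ts & rel$meta$group == treated
    b <- in_ts & rel$meta$group == control
    if (sum(a) < 2 || sum(b) < 2) stop("need >= 2 samples per cell")
    do.call(rbind, lapply(genes, function(g) {
      tt <- welch_t(rel$ddct[g, a], rel$ddct[g, b])
      data.frame(gene = g, tissue = ts,
                 fold = mean(rel$levels[g, a]) / mean(rel$levels[g, b]),
                 t = tt$statistic, dof = tt$dof, p = tt$p)
    }))
  }))
  fdr <- bh_fdr(rows$p, q_flag)
  rows$q <- fdr$adjusted
  rows$significant <- fdr$flag
  rownames(rows) <- NULL
  rows
}
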