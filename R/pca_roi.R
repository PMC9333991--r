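#' Spatial PCA of a correlation (difference) matrix
#'
#' Column mean-centres the matrix, symmetrizes the result, and
#' eigendecomposes it.  Components are ordered by decreasing eigenvalue
#' magnitude; `variance_explained` is `|lambda| / sum(|lambda|)`.  The sum of
#' the (signed) eigenvalues equals the trace of the centred matrix.
#'
#' @param diff a `corr_matrix` or a symmetric numeric matrix; the diagonal
#'   (NA by convention) is treated as 0.
#' @return object of class `pc_result`: `components` (unit-norm eigenvector
#'   matrix, one column per PC), `eigenvalues` (signed, ordered by |.|),
#'   `variance_explained`, `index` (unit bookkeeping when available).
#' @export
spatial_pca <- function(diff) {
  index <- NULL
  M <- if (inherits(diff, "corr_matrix")) { index <- diff$index; diff$z } else diff
  M <- as.matrix(M)
  diag(M)[is.na(diag(M))] <- 0
  if (any(!is.finite(M))) stop("correlation difference matrix has non-finite entries")
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1))
    stop("input matrix is not symmetric")
  Mc <- sweep(M, 2, colMeans(M))
  S <- (Mc + t(Mc)) / 2
  e <- eigen(S, symmetric = TRUE)
  o <- order(abs(e$values), decreasing = TRUE)
  ev <- e$values[o]
  structure(list(components = e$vectors[, o, drop = FALSE],
                 eigenvalues = ev,
                 variance_explained = abs(ev) / sum(abs(ev)),
                 index = index),
            class = "pc_result")
}

#' Reshape a principal component to an image
#'
#' @param pc a `pc_result` whose `index` carries pixel `row`/`col`.
#' @param which component number.
#' @param dim_image optional `c(height, width)`.
#' @return matrix image (`NA` where no unit maps).
#' @export
pc_image <- function(pc, which = 1, dim_image = NULL) {
  if (is.null(pc$index) || is.null(pc$index$row))
    stop("pc_result has no pixel index; cannot reshape to an image")
  h <- dim_image[1] %||% max(pc$index$row)
  w <- dim_image[2] %||% max(pc$index$col)
  img <- matrix(NA_real_, h, w)
  img[cbind(pc$index$row, pc$index$col)] <- pc$components[, which]
  img
}

#' Permutation test for PCA eigenvalues
#'
#' Builds the null distribution of the first two eigenvalue magnitudes of
#' the group-mean correlation difference matrix by repeatedly shuffling the
#' group labels across mice; observed eigenvalues exceeding the null
#' percentile (default 90th) are flagged significant.
#'
#' @param mouse_matrices list of per-mouse `corr_matrix` objects (or plain
#'   symmetric matrices) with identical indices.
#' @param labels group label per mouse (exactly 2 levels, >= 3 mice each).
#' @param n permutation iterations (default 3000).
#' @param percentile criterion percentile of the null (default 90).
#' @param seed integer seed for the label shuffles.
#' @return object of class `permutation_result`: `observed` (2 eigenvalue
#'   magnitudes), `null_eigenvalues` (n x 2), `criterion` (null percentiles),
#'   `significant` (2 logicals), `n_iterations`, `percentile`, `seed`.
#' @export
permutation_eigen_test <- function(mouse_matrices, labels, n = 3000,
                                   percentile = 90, seed = 1) {
  zs <- lapply(mouse_matrices, function(m)
    if (inherits(m, "corr_matrix")) m$z else m)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly 2 groups are required")
  if (min(table(labels)) < 3) stop("at least 3 mice per group are required")
  if (choose(length(labels), sum(labels == levels(labels)[1])) < n)
    warning("fewer than n distinct permutations exist; ",
            "random relabelings are sampled with replacement")
  k <- length(zs)
  A <- vapply(zs, function(z) { z <- as.matrix(z); diag(z)[is.na(diag(z))] <- 0
                                as.vector(z) }, numeric(length(zs[[1]])))
  p <- nrow(zs[[1]])
  top2 <- function(lab) {
    gA <- rowMeans(A[, lab == levels(labels)[1], drop = FALSE])
    gB <- rowMeans(A[, lab == levels(labels)[2], drop = FALSE])
    pc <- spatial_pca(matrix(gA - gB, p, p))
    abs(pc$eigenvalues[1:2])
  }
  observed <- top2(labels)
  set.seed(as.integer(seed))
  null_ev <- t(vapply(seq_len(n), function(i) top2(sample(labels)), numeric(2)))
  crit <- apply(null_ev, 2, stats::quantile, probs = percentile / 100,
                names = FALSE)
  structure(list(observed = observed, null_eigenvalues = null_ev,
                 criterion = crit, significant = observed > crit,
                 n_iterations = n, percentile = percentile,
                 seed = as.integer(seed)),
            class = "permutation_result")
}

# truncated, renormalized separable Gaussian smoothing
.gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    out <- stats::filter(c(rep(0, r), v, rep(0, r)), k, sides = 2)
    wts <- stats::filter(c(rep(0, r), rep(1, n), rep(0, r)), k, sides = 2)
    (out / wts)[(r + 1):(r + n)]
  }
  sm <- apply(img, 2, pad_conv)
  t(apply(sm, 1, pad_conv))
}

# 8-connected component labelling by flood fill
.label_components <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w); cur <- 0L
  todo <- which(bin)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (px - 1L) %% h + 1L; c <- (px - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (bin[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

#' Derive ROIs from a principal-component map
#'
#' Symmetrizes the PC map about the atlas midline (average with its mirror),
#' smooths it with a Gaussian kernel, and keeps pixels at or above 85% of
#' the positive maximum together with pixels at or below 85% of the negative
#' minimum.  Eight-connected components, split at the midline, become ROIs,
#' one hemisphere each.
#'
#' @param pc_map matrix image of PC loadings (`NA` outside the mask).
#' @param atlas an `atlas_spec` (midline and mask).
#' @param smooth_sigma Gaussian smoothing SD in pixels (default 2).
#' @param threshold_frac fraction of the positive max / negative min kept
#'   (default 0.85).
#' @param source_pc label stored with each ROI.
#' @return object of class `roi_set`: list `rois` of logical matrices with
#'   attributes `hemisphere`, `sign`, `source_pc`; plus per-hemisphere
#'   counts.  Empty (with a warning) if nothing survives the threshold.
#' @export
derive_rois <- function(pc_map, atlas, smooth_sigma = 2,
                        threshold_frac = 0.85, source_pc = 1L) {
  m <- pc_map
  m[is.na(m)] <- 0
  sym <- (m + mirror_lr(m)) / 2
  sm <- .gauss_smooth(sym, smooth_sigma)
  sm[!atlas$brain_mask] <- 0
  keep <- matrix(FALSE, nrow(sm), ncol(sm))
  signs <- matrix(0L, nrow(sm), ncol(sm))
  if (any(sm > 0)) {
    pos <- sm >= threshold_frac * max(sm)
    keep <- keep | pos; signs[pos] <- 1L
  }
  if (any(sm < 0)) {
    neg <- sm <= threshold_frac * min(sm)
    keep <- keep | neg; signs[neg] <- -1L
  }
  if (!any(keep)) {
    warning("no pixels survive the ", threshold_frac, " threshold")
    return(structure(list(rois = list(), n_left = 0L, n_right = 0L),
                     class = "roi_set"))
  }
  lh <- left_hemisphere(atlas)
  rois <- list()
  for (hemi in c("L", "R")) {
    hm <- if (hemi == "L") keep & lh else keep & !lh
    for (sgn in c(1L, -1L)) {
      lab <- .label_components(hm & signs == sgn)
      for (cc in seq_len(max(lab))) {
        roi <- lab == cc
        attr(roi, "hemisphere") <- hemi
        attr(roi, "sign") <- sgn
        attr(roi, "source_pc") <- source_pc
        rois[[sprintf("pc%d_%s_%s%d", source_pc, hemi,
                      if (sgn > 0) "pos" else "neg", cc)]] <- roi
      }
    }
  }
  hs <- vapply(rois, attr, "", which = "hemisphere")
  structure(list(rois = rois, n_left = sum(hs == "L"), n_right = sum(hs == "R")),
            class = "roi_set")
}

#' ROI centroids
#'
#' @param roiset a `roi_set`.
#' @return data.frame `roi`, `row`, `col` (pixel centroid of each ROI).
#' @export
roi_centroids <- function(roiset) {
  do.call(rbind, lapply(names(roiset$rois), function(nm) {
    w <- which(roiset$rois[[nm]], arr.ind = TRUE)
    data.frame(roi = nm, row = mean(w[, 1]), col = mean(w[, 2]))
  }))
}

#' Regional RSFC recovery matrix
#'
#' Change in connectivity magnitude between two sessions:
#' elementwise group-mean `|z_week4| - |z_week1|` over matched mice.
#'
#' @param week4,week1 lists (same mice, same order) of regional
#'   `corr_matrix` objects.
#' @return object of class `recovery_matrix`: `values` (ROI x ROI), `deltas`
#'   (per-mouse |z4|-|z1| matrices), `index`.
#' @export
recovery_matrix <- function(week4, week1) {
  if (length(week4) != length(week1)) stop("mouse lists differ in length")
  idx <- week4[[1]]$index
  deltas <- lapply(seq_along(week4), function(i) {
    if (!identical(week4[[i]]$index$unit, idx$unit) ||
        !identical(week1[[i]]$index$unit, idx$unit))
      stop("ROI indices differ across matrices")
    abs(week4[[i]]$z) - abs(week1[[i]]$z)
  })
  structure(list(values = Reduce(`+`, deltas) / length(deltas),
                 deltas = deltas, index = idx),
            class = "recovery_matrix")
}

#' Group difference of recovery matrices with edge significance
#'
#' Elementwise `groupA - groupB` recovery difference.  Per edge, the
#' group-by-time interaction is tested as a Welch t-test between the two
#' groups' per-mouse recovery values (`|z4| - |z1|`), then
#' Benjamini-Hochberg corrected; significant edges are emitted as a signed
#' edge list (with ROI centroid coordinates when supplied).
#'
#' @param groupA,groupB `recovery_matrix` objects with shared indices.
#' @param q FDR level for edge significance (default 0.05).
#' @param centroids optional data.frame from [roi_centroids()].
#' @return list of class `recovery_difference`: `values` (difference
#'   matrix), `p`, `q` (matrices), `edges` (data.frame `roi_a`, `roi_b`,
#'   `delta_z`, `p_value`, `q_value`, `sign`, centroid coordinates).
#' @export
recovery_difference <- function(groupA, groupB, q = 0.05, centroids = NULL) {
  if (!identical(groupA$index$unit, groupB$index$unit))
    stop("recovery matrices have different ROI indices")
  vals <- groupA$values - groupB$values
  p <- nrow(vals)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  pv <- apply(ut, 1, function(ij) {
    a <- vapply(groupA$deltas, function(d) d[ij[1], ij[2]], 0)
    b <- vapply(groupB$deltas, function(d) d[ij[1], ij[2]], 0)
    welch_t(a, b)$p
  })
  qv <- bh_fdr(pv, q)$adjusted
  pmat <- qmat <- matrix(NA_real_, p, p, dimnames = dimnames(vals))
  pmat[ut] <- pv; pmat[ut[, 2:1]] <- pv
  qmat[ut] <- qv; qmat[ut[, 2:1]] <- qv
  sig <- which(qv < q)
  edges <- data.frame(roi_a = groupA$index$unit[ut[sig, 1]],
                      roi_b = groupA$index$unit[ut[sig, 2]],
                      delta_z = vals[ut[sig, , drop = FALSE]],
                      p_value = pv[sig], q_value = qv[sig],
                      sign = sign(vals[ut[sig, , drop = FALSE]]))
  if (!is.null(centroids) && nrow(edges)) {
    ca <- centroids[match(edges$roi_a, centroids$roi), c("row", "col")]
    cb <- centroids[match(edges$roi_b, centroids$roi), c("row", "col")]
    edges$row_a <- ca$row; edges$col_a <- ca$col
    edges$row_b <- cb$row; edges$col_b <- cb$col
  }
  structure(list(values = vals, p = pmat, q = qmat, edges = edges),
            class = "recovery_difference")
}
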