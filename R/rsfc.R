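#' ROI mean time course
#'
#' Unweighted mean over the ROI's pixels at each time point.
#'
#' @param movie a `hemo_movie` (HbT contrast).
#' @param roi logical matrix (a seed ROI); intersected with the movie mask.
#' @return numeric time series.
#' @export
roi_timecourse <- function(movie, roi) {
  sel <- roi & movie$mask
  if (!any(sel)) stop("ROI does not intersect the brain mask")
  d <- dim(movie$hbt)
  colMeans(matrix(movie$hbt, d[1] * d[2], d[3])[as.vector(sel), , drop = FALSE])
}

#' Fisher z transform
#'
#' `z = atanh(r)`, variance-stabilizing for correlation coefficients.
#' Values with `|r| >= 1` are clipped to `1 - 1e-7` in magnitude with a
#' warning.
#'
#' @param r correlations.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clipped to 1 - 1e-7 before Fisher z")
    r <- pmax(pmin(r, 1 - 1e-7), -1 + 1e-7)
  }
  atanh(r)
}

#' Seed-based functional connectivity map
#'
#' Correlates the ROI mean time course with every pixel trace in the mask
#' and Fisher-z transforms the result.
#'
#' @param movie a `hemo_movie`.
#' @param roi logical matrix.
#' @return matrix of Fisher-z correlations (`NA` outside the mask and at
#'   zero-variance pixels).
#' @export
seed_map <- function(movie, roi) {
  seed <- roi_timecourse(movie, roi)
  if (stats::var(seed) == 0) stop("seed trace has zero variance")
  d <- dim(movie$hbt)
  m <- matrix(movie$hbt, d[1] * d[2], d[3])
  z <- rep(NA_real_, d[1] * d[2])
  idx <- which(as.vector(movie$mask))
  v <- apply(m[idx, , drop = FALSE], 1, stats::var)
  ok <- idx[v > 0]
  r <- as.vector(stats::cor(seed, t(m[ok, , drop = FALSE])))
  z[ok] <- suppressWarnings(fisher_z(r))
  # exact self-correlations (single-pixel seeds) clip silently by convention
  z[ok][abs(r) >= 1] <- atanh(sign(r[abs(r) >= 1]) * (1 - 1e-7))
  matrix(z, d[1], d[2])
}

#' Whole-cortex / regional correlation matrix
#'
#' Pairwise zero-lag Pearson correlations between units (mask pixels,
#' optionally spatially downsampled, or ROI mean traces), Fisher-z
#' transformed.  The diagonal is set to `NA` and excluded from downstream
#' statistics.
#'
#' @param movie a `hemo_movie`.
#' @param rois optional named list of logical ROI matrices; when omitted the
#'   units are mask pixels.
#' @param spatial_step pixel subsampling step for pixelwise matrices
#'   (default 2; every `spatial_step`-th row/column, to bound memory).
#' @return object of class `corr_matrix`: `z` (symmetric, `NA` diagonal),
#'   `index` (data.frame of unit labels; for pixels: `row`, `col`,
#'   `hemisphere`), `kind` ("pixel" or "roi").
#' @export
corr_matrix <- function(movie, rois = NULL, spatial_step = 2) {
  d <- dim(movie$hbt)
  if (is.null(rois)) {
    keep <- matrix(FALSE, d[1], d[2])
    keep[seq(1, d[1], by = spatial_step), seq(1, d[2], by = spatial_step)] <- TRUE
    keep <- keep & movie$mask
    idx <- which(as.vector(keep))
    m <- matrix(movie$hbt, d[1] * d[2], d[3])[idx, , drop = FALSE]
    rc <- cbind(row = (idx - 1) %% d[1] + 1, col = (idx - 1) %/% d[1] + 1)
    index <- data.frame(unit = paste0("px_", rc[, 1], "_", rc[, 2]),
                        row = rc[, 1], col = rc[, 2],
                        hemisphere = ifelse(rc[, 2] <= d[2] / 2, "L", "R"))
    kind <- "pixel"
  } else {
    m <- do.call(rbind, lapply(rois, function(r) roi_timecourse(movie, r)))
    index <- data.frame(unit = names(rois))
    kind <- "roi"
  }
  if (nrow(m) < 2) stop("need at least 2 units to correlate")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) warning(sum(v == 0), " zero-variance unit(s) flagged (NA rows)")
  r <- suppressWarnings(stats::cor(t(m)))
  r[!is.finite(r)] <- NA
  z <- suppressWarnings(fisher_z(r))
  z[abs(r) >= 1 & !is.na(r)] <- atanh((1 - 1e-7) * sign(r[abs(r) >= 1 & !is.na(r)]))
  diag(z) <- NA_real_
  dimnames(z) <- list(index$unit, index$unit)
  structure(list(z = z, index = index, kind = kind), class = "corr_matrix")
}

#' Global node degree
#'
#' For every unit, the number of other units whose Fisher-z correlation with
#' it reaches `thr_z` (inclusive; negative correlations never count).
#'
#' @param cm a `corr_matrix` (pixelwise for degree maps).
#' @param thr_z Fisher-z threshold (default 0.4).
#' @return object of class `node_degree_map`: `degree` (integer vector named
#'   by unit; also `image` when the matrix is pixelwise), `threshold_z`.
#' @export
node_degree <- function(cm, thr_z = 0.4) {
  B <- cm$z >= thr_z
  B[is.na(B)] <- FALSE
  diag(B) <- FALSE
  deg <- as.integer(rowSums(B))
  names(deg) <- cm$index$unit
  img <- NULL
  if (cm$kind == "pixel") {
    img <- matrix(NA_real_, max(cm$index$row), max(cm$index$col))
    img[cbind(cm$index$row, cm$index$col)] <- deg
  }
  structure(list(degree = deg, image = img, threshold_z = thr_z),
            class = "node_degree_map")
}

#' Group difference of correlation matrices
#'
#' Elementwise mean of group A minus mean of group B.
#'
#' @param groupA,groupB lists of `corr_matrix` objects with identical
#'   indices.
#' @return a `corr_matrix` of differences (`NA` diagonal).
#' @export
difference_matrix <- function(groupA, groupB) {
  idx <- groupA[[1]]$index
  for (cm in c(groupA, groupB))
    if (!identical(cm$index$unit, idx$unit)) stop("matrix indices differ")
  mean_of <- function(g) Reduce(`+`, lapply(g, `[[`, "z")) / length(g)
  z <- mean_of(groupA) - mean_of(groupB)
  structure(list(z = z, index = idx, kind = groupA[[1]]$kind),
            class = "corr_matrix")
}
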