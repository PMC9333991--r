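#' Slice a movie into stimulation blocks
#'
#' Cuts the movie into `n_blocks` windows of `block_s` seconds each
#' (half-open `[block start, block end)`), with the stimulus onset `pre_s`
#' seconds into each block.  An incomplete final block is dropped with a
#' warning.
#'
#' @param movie a `hemo_movie` (HbT is the analysed contrast).
#' @param paradigm a `stim_paradigm`.
#' @return object of class `block_stack`: `blocks` (block x pixel x time
#'   array of HbT), `onsets_s` (stimulus onsets in movie time), `paradigm`,
#'   `frame_rate`, `mask`, `dim_image`.
#' @export
extract_blocks <- function(movie, paradigm) {
  fs <- movie$frame_rate
  len <- round(paradigm$block_s * fs)
  nt <- dim(movie$hbt)[3]
  n_full <- min(paradigm$n_blocks, nt %/% len)
  if (n_full < paradigm$n_blocks)
    warning("movie holds ", n_full, " of ", paradigm$n_blocks,
            " blocks; truncated blocks dropped")
  d <- dim(movie$hbt)
  m <- matrix(movie$hbt, d[1] * d[2], nt)
  blocks <- array(0, c(n_full, d[1] * d[2], len))
  for (b in seq_len(n_full))
    blocks[b, , ] <- m[, ((b - 1) * len + 1):(b * len)]
  structure(list(blocks = blocks,
                 onsets_s = paradigm$pre_s +
                   (seq_len(n_full) - 1) * paradigm$block_s,
                 paradigm = paradigm, frame_rate = fs, mask = movie$mask,
                 dim_image = d[1:2]),
            class = "block_stack")
}

# frame indices (within a block) of a half-open time window [t0, t1) in
# seconds relative to block start
.block_frames <- function(stack, t0, t1) {
  fs <- stack$frame_rate
  len <- if (!is.null(stack$blocks)) dim(stack$blocks)[3] else ncol(stack$avg)
  if (t1 > len / fs + 1e-9) stop("window exceeds block length")
  i <- which((seq_len(len) - 1) / fs >= t0 & (seq_len(len) - 1) / fs < t1)
  if (!length(i)) stop("empty time window [", t0, ", ", t1, ") s")
  i
}

# one block as a pixel x time matrix, robust to single-pixel movies
.block_matrix <- function(stack, b) {
  matrix(stack$blocks[b, , ], dim(stack$blocks)[2], dim(stack$blocks)[3])
}

#' Baseline-subtracted block average
#'
#' For each block, the mean image over the baseline window 1-5 s before
#' stimulus onset is subtracted from every frame of the block; the
#' baseline-corrected blocks are then averaged.
#'
#' @param stack a `block_stack`.
#' @param baseline_window `c(start, end)` in seconds before stimulus onset
#'   (default `c(5, 1)`: the window `[onset - 5 s, onset - 1 s)`).
#' @return object of class `block_average`: `avg` (pixel x time matrix),
#'   plus geometry/paradigm bookkeeping.
#' @export
block_average <- function(stack, baseline_window = c(5, 1)) {
  if (dim(stack$blocks)[1] < 1) stop("no blocks to average")
  pre <- stack$paradigm$pre_s
  bl <- .block_frames(stack, pre - baseline_window[1], pre - baseline_window[2])
  nb <- dim(stack$blocks)[1]
  acc <- 0
  for (b in seq_len(nb)) {
    blk <- .block_matrix(stack, b)
    acc <- acc + (blk - rowMeans(blk[, bl, drop = FALSE]))
  }
  structure(list(avg = acc / nb, n_blocks = nb, paradigm = stack$paradigm,
                 frame_rate = stack$frame_rate, mask = stack$mask,
                 dim_image = stack$dim_image),
            class = "block_average")
}

#' Peak response map
#'
#' Averages the block-averaged response over the peak window, 2 s before
#' through 2 s after stimulus offset, per pixel.
#'
#' @param avg a `block_average`.
#' @param window `c(before, after)` seconds around stimulus offset
#'   (default `c(2, 2)`).
#' @return height x width matrix (M).
#' @export
peak_map <- function(avg, window = c(2, 2)) {
  off <- avg$paradigm$pre_s + avg$paradigm$stim_s
  i <- .block_frames(avg, off - window[1], off + window[2])
  matrix(rowMeans(avg$avg[, i, drop = FALSE]),
         avg$dim_image[1], avg$dim_image[2])
}

#' Group response threshold
#'
#' The response threshold used for all mice and all time points: 75% of the
#' maximum of the group-averaged baseline peak map (within the mask, if
#' given).
#'
#' @param baseline_peak_maps list of per-mouse baseline peak maps.
#' @param frac threshold fraction of maximum (default 0.75).
#' @param mask optional logical matrix restricting the maximum.
#' @return scalar threshold (M).
#' @export
group_threshold <- function(baseline_peak_maps, frac = 0.75, mask = NULL) {
  if (!length(baseline_peak_maps)) stop("no baseline maps supplied")
  gm <- Reduce(`+`, baseline_peak_maps) / length(baseline_peak_maps)
  mx <- if (is.null(mask)) max(gm) else max(gm[mask])
  frac * mx
}

#' Activation magnitude and area
#'
#' Magnitude is the maximum of the peak map over pixels at or above the
#' threshold (explicitly missing, `NA`, when no pixel qualifies — a
#' non-response); area is the count of suprathreshold pixels.  When
#' `fallback_region` is supplied (typically the baseline suprathreshold
#' footprint), a missing magnitude is replaced by the map maximum inside
#' that region so that strongly attenuated (>75% loss) responses remain
#' quantifiable; area is unaffected.
#'
#' @param peak peak map (matrix, M).
#' @param threshold scalar from [group_threshold()].
#' @param baseline_magnitude,baseline_area group baseline means used for
#'   normalization (optional).
#' @param mask optional logical matrix.
#' @param fallback_region optional logical matrix; see Description.
#' @return object of class `evoked_map`: `magnitude`, `area`,
#'   `magnitude_norm`, `area_norm`, `threshold`.
#' @export
response_metrics <- function(peak, threshold, baseline_magnitude = NULL,
                             baseline_area = NULL, mask = NULL,
                             fallback_region = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  sel <- peak >= threshold
  if (!is.null(mask)) sel <- sel & mask
  area <- sum(sel)
  magnitude <- if (area > 0) max(peak[sel]) else NA_real_
  if (is.na(magnitude) && !is.null(fallback_region)) {
    reg <- if (is.null(mask)) fallback_region else fallback_region & mask
    if (any(reg)) magnitude <- max(peak[reg])
  }
  structure(list(magnitude = magnitude, area = area, threshold = threshold,
                 magnitude_norm = if (!is.null(baseline_magnitude))
                   magnitude / baseline_magnitude else NA_real_,
                 area_norm = if (!is.null(baseline_area))
                   area / baseline_area else NA_real_),
            class = "evoked_map")
}

#' Activation incidence map
#'
#' Per pixel, the fraction of mice whose peak map reaches the threshold.
#'
#' @param peak_maps list of per-mouse peak maps.
#' @param threshold scalar.
#' @return matrix of fractions in `{0, 1/n, ..., 1}`.
#' @export
incidence_map <- function(peak_maps, threshold) {
  if (!length(peak_maps)) stop("no maps supplied")
  Reduce(`+`, lapply(peak_maps, function(p) (p >= threshold) + 0)) /
    length(peak_maps)
}

#' Per-mouse evoked-response T-map
#'
#' One-sample t statistic, per pixel, of the per-block peak-window means
#' against zero, with `n_blocks - 1` degrees of freedom.  Pixels with zero
#' across-block variance are `NA`.
#'
#' @param stack a `block_stack`.
#' @param window peak window around stimulus offset as in [peak_map()].
#' @param baseline_window as in [block_average()].
#' @return object of class `t_map`: `t` (matrix), `dof`.
#' @export
t_map <- function(stack, window = c(2, 2), baseline_window = c(5, 1)) {
  nb <- dim(stack$blocks)[1]
  if (nb < 2) stop("at least 2 blocks are required for a T-map")
  pre <- stack$paradigm$pre_s
  bl <- .block_frames(stack, pre - baseline_window[1], pre - baseline_window[2])
  off <- pre + stack$paradigm$stim_s
  pk <- .block_frames(stack, off - window[1], off + window[2])
  vals <- sapply(seq_len(nb), function(b) {
    blk <- .block_matrix(stack, b)
    rowMeans(blk[, pk, drop = FALSE]) - rowMeans(blk[, bl, drop = FALSE])
  })
  vals <- matrix(vals, ncol = nb)             # pixel x block
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  t <- mu / (sdv / sqrt(nb))
  t[sdv == 0] <- NA_real_
  structure(list(t = matrix(t, stack$dim_image[1], stack$dim_image[2]),
                 dof = nb - 1L),
            class = "t_map")
}

#' Group effect-size (Cohen's D) map from mouse-level T-maps
#'
#' Computes, per pixel, Cohen's D between two groups of mouse-level T values
#' (group A minus group B, pooled SD with n-1 weights).  Pixels are included
#' when the mean T exceeds `t_include` in either group; excluded or
#' degenerate pixels are `NA`.
#'
#' @param tmaps_A,tmaps_B lists of `t_map` objects (>= 2 mice each).
#' @param t_include inclusion threshold on the group-mean T (default 2).
#' @return object of class `effect_size_map`: `d` (matrix),
#'   `inclusion_mask` (logical matrix).
#' @export
cohens_d_map <- function(tmaps_A, tmaps_B, t_include = 2) {
  if (length(tmaps_A) < 2 || length(tmaps_B) < 2)
    stop("at least 2 mice per group are required")
  stackT <- function(tm) sapply(tm, function(x) as.vector(x$t))
  A <- stackT(tmaps_A); B <- stackT(tmaps_B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  include <- (mA > t_include) | (mB > t_include)
  nA <- ncol(A); nB <- ncol(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  sp <- sqrt(((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2))
  d <- (mA - mB) / sp
  d[!include | !is.finite(d)] <- NA_real_
  dm <- dim(tmaps_A[[1]]$t)
  structure(list(d = matrix(d, dm[1], dm[2]),
                 inclusion_mask = matrix(include & is.finite(mA - mB), dm[1], dm[2])),
            class = "effect_size_map")
}
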