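#' Run-level quality control
#'
#' Screens a set of imaging runs before spectroscopic analysis.  For each run
#' the variance of the global-mean trace and the largest absolute
#' frame-to-frame jump of that trace are computed; a run is rejected when its
#' variance exceeds `var_mult` times the median run variance or its jump
#' exceeds `jump_mult` times the median of the runs' median absolute frame
#' differences.  Deterministic: no randomness, median-based and
#' order-independent.
#'
#' @param runs list of runs; each a `hemo_movie`, a `reflectance_stack`
#'   (its first wavelength is screened) or a `height x width x time` array.
#' @param var_mult,jump_mult rejection multiples (defaults 5 and 10).
#' @param mask optional logical matrix; defaults to each run's own mask.
#' @return data.frame of class `qc_report`: `run`, `variance`, `max_jump`,
#'   `kept`, `reason`.
#' @export
quality_check <- function(runs, var_mult = 5, jump_mult = 10, mask = NULL) {
  if (length(runs) == 0)
    return(structure(data.frame(run = integer(), variance = numeric(),
                                max_jump = numeric(), kept = logical(),
                                reason = character()),
                     class = c("qc_report", "data.frame")))
  gtrace <- lapply(runs, function(r) {
    if (inherits(r, "hemo_movie")) { a <- r$hbt; m <- mask %||% r$mask }
    else if (inherits(r, "reflectance_stack")) { a <- r$data[[1]]; m <- mask %||% r$mask }
    else { a <- r; m <- mask %||% matrix(TRUE, dim(r)[1], dim(r)[2]) }
    colMeans(matrix(a, prod(dim(a)[1:2]), dim(a)[3])[as.vector(m), , drop = FALSE])
  })
  v <- vapply(gtrace, stats::var, 0)
  jump <- vapply(gtrace, function(g) max(abs(diff(g))), 0)
  med_jump <- stats::median(vapply(gtrace, function(g)
    stats::median(abs(diff(g))), 0))
  kept <- (v <= var_mult * stats::median(v)) & (jump <= jump_mult * med_jump)
  reason <- ifelse(kept, "",
                   ifelse(v > var_mult * stats::median(v),
                          "global variance above threshold",
                          "frame-to-frame jump above threshold"))
  structure(data.frame(run = seq_along(runs), variance = v, max_jump = jump,
                       kept = kept, reason = reason),
            class = c("qc_report", "data.frame"))
}

# apply a per-pixel time-series function to every pixel of a movie component
.map_time <- function(arr, fn, n_out = dim(arr)[3]) {
  d <- dim(arr)
  m <- matrix(arr, d[1] * d[2], d[3])
  out <- t(apply(m, 1, fn))
  array(out, c(d[1], d[2], n_out))
}

#' Temporal downsampling by block averaging
#'
#' Reduces the frame rate by averaging non-overlapping blocks of
#' `frame_rate / target_rate` consecutive frames (anti-aliasing by
#' integration rather than decimation).  Trailing frames that do not fill a
#' block are dropped.
#'
#' @param movie a `hemo_movie`.
#' @param target_rate Hz; must divide the movie's frame rate.
#' @return a `hemo_movie` at `target_rate`.
#' @export
downsample <- function(movie, target_rate) {
  fac <- movie$frame_rate / target_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("target_rate must divide the frame rate (ratio ", fac, ")")
  fac <- as.integer(round(fac))
  n_out <- dim(movie$hbo)[3] %/% fac
  block_mean <- function(x)
    colMeans(matrix(x[seq_len(n_out * fac)], fac, n_out))
  movie$hbo <- .map_time(movie$hbo, block_mean, n_out)
  movie$hbr <- .map_time(movie$hbr, block_mean, n_out)
  movie$frame_rate <- target_rate
  .assert_hbt(movie)
}

#' Zero-phase band-pass filtering
#'
#' Applies a 5th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`, zero phase) to every pixel trace, then removes any
#' residual mean.  Standard bands: 0.009-0.08 Hz for resting-state analysis
#' and 0.009-0.5 Hz for task sessions.
#'
#' @param movie a `hemo_movie`.
#' @param low,high band edges, Hz; `0 < low < high < frame_rate / 2`.
#' @param order filter order (default 5).
#' @return the filtered `hemo_movie` (zero-mean traces).
#' @export
bandpass <- function(movie, low, high, order = 5) {
  ny <- movie$frame_rate / 2
  if (!(low > 0 && low < high && high < ny))
    stop("band edges must satisfy 0 < low < high < Nyquist (", ny, " Hz)")
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  # demean before filtering to suppress edge transients of the low cutoff
  filt <- function(x) { y <- signal::filtfilt(bf, x - mean(x)); y - mean(y) }
  movie$hbo <- .map_time(movie$hbo, filt)
  movie$hbr <- .map_time(movie$hbr, filt)
  .assert_hbt(movie)
}

#' Global signal regression
#'
#' Computes the brain-wide mean trace over the mask and replaces every pixel
#' trace by its residual after ordinary least-squares projection onto the
#' global signal and a constant.  Residuals are orthogonal to the global
#' signal; applying the operation twice equals applying it once.
#'
#' @param movie a `hemo_movie`.
#' @param mask optional logical matrix (defaults to the movie's mask).
#' @return the regressed `hemo_movie`.
#' @export
global_signal_regress <- function(movie, mask = NULL) {
  mask <- mask %||% movie$mask
  if (!any(mask)) stop("mask is empty")
  gsr_one <- function(arr) {
    d <- dim(arr)
    m <- matrix(arr, d[1] * d[2], d[3])
    if (all(m == 0)) return(arr)             # nothing to regress
    g <- colMeans(m[as.vector(mask), , drop = FALSE])
    if (stats::var(g) < .Machine$double.eps) {
      warning("global signal has zero variance; returning mean-centered movie")
      res <- m - rowMeans(m)
    } else {
      X <- cbind(1, g)                       # n_t x 2 design
      beta <- solve(crossprod(X), crossprod(X, t(m)))   # 2 x npx
      res <- m - t(X %*% beta)
    }
    array(res, d)
  }
  movie$hbo <- gsr_one(movie$hbo)
  movie$hbr <- gsr_one(movie$hbr)
  .assert_hbt(movie)
}

#' Fit a 2-D affine transform from three landmark pairs
#'
#' Solves the six-parameter system exactly so that the three source landmarks
#' map onto the three targets.
#'
#' @param source,target lists (or 3 x 2 matrices) of three `c(row, col)`
#'   points; must not be collinear.
#' @return object of class `affine_transform`: `matrix` is the 2 x 3 map
#'   `[row'; col'] = A [row; col; 1]`.
#' @export
fit_affine <- function(source, target) {
  as_m <- function(p) if (is.matrix(p)) p else do.call(rbind, p)
  S <- as_m(source); Tg <- as_m(target)
  stopifnot(nrow(S) == 3, nrow(Tg) == 3)
  X <- cbind(S, 1)
  if (abs(det(X)) < 1e-9 * max(abs(S), 1)^2)
    stop("landmarks are collinear; affine transform is degenerate")
  A <- t(solve(X, Tg))                       # 2 x 3
  if (abs(det(A[, 1:2])) < 1e-12)
    stop("degenerate affine transform (non-invertible linear part)")
  structure(list(matrix = A, source_landmarks = S, target_landmarks = Tg),
            class = "affine_transform")
}

# map points (n x 2, row/col) through an affine_transform
.affine_points <- function(t, pts) {
  cbind(pts, 1) %*% t(t$matrix)
}

#' Resample a movie through an affine transform
#'
#' Maps every output pixel back through the inverse transform and bilinearly
#' interpolates the source movie; the mask is transformed with
#' nearest-neighbour lookup and re-binarized.  Output pixels falling outside
#' the source image are zero (mask: `FALSE`).
#'
#' @param movie a `hemo_movie` (or a single matrix image).
#' @param t an `affine_transform` (source pixel -> atlas pixel).
#' @param out_shape `c(height, width)` of the atlas space; defaults to the
#'   input shape.
#' @return a `hemo_movie` in atlas space (or the resampled image).
#' @export
apply_affine <- function(movie, t, out_shape = NULL) {
  if (is.matrix(movie)) {
    d <- dim(movie); out_shape <- out_shape %||% d
    return(.warp_frames(array(movie, c(d, 1)), t, out_shape)[, , 1])
  }
  out_shape <- out_shape %||% dim(movie$hbo)[1:2]
  movie$hbo <- .warp_frames(movie$hbo, t, out_shape)
  movie$hbr <- .warp_frames(movie$hbr, t, out_shape)
  # nearest-neighbour mask transform, re-binarized
  mwarp <- .warp_frames(array(movie$mask + 0, c(dim(movie$mask), 1)), t,
                        out_shape, nearest = TRUE)[, , 1]
  movie$mask <- mwarp >= 0.5
  movie$space <- "atlas"
  .assert_hbt(movie)
}

.warp_frames <- function(arr, t, out_shape, nearest = FALSE) {
  h <- out_shape[1]; w <- out_shape[2]
  inv <- solve(rbind(t$matrix, c(0, 0, 1)))[1:2, ]
  out_pts <- cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h))
  src <- cbind(out_pts, 1) %*% t(inv)        # source row/col per output pixel
  sh <- dim(arr)[1]; sw <- dim(arr)[2]; nt <- dim(arr)[3]
  if (nearest) { src <- round(src) }
  r0 <- floor(src[, 1]); c0 <- floor(src[, 2])
  fr <- src[, 1] - r0;   fc <- src[, 2] - c0
  ok <- r0 >= 1 & c0 >= 1 & (r0 + 1) <= sh & (c0 + 1) <= sw
  # clamp edge case: points exactly on the last row/col
  edge <- src[, 1] >= 1 & src[, 2] >= 1 & src[, 1] <= sh & src[, 2] <= sw
  r0[edge & r0 == sh] <- sh - 1; fr[edge & src[, 1] == sh] <- 1
  c0[edge & c0 == sw] <- sw - 1; fc[edge & src[, 2] == sw] <- 1
  ok <- ok | edge
  idx <- function(r, c) (c - 1) * sh + r
  out <- array(0, c(h, w, nt))
  m <- matrix(arr, sh * sw, nt)
  io <- which(ok)
  if (length(io)) {
    i00 <- idx(r0[io], c0[io]);     i10 <- idx(r0[io] + 1, c0[io])
    i01 <- idx(r0[io], c0[io] + 1); i11 <- idx(r0[io] + 1, c0[io] + 1)
    w00 <- (1 - fr[io]) * (1 - fc[io]); w10 <- fr[io] * (1 - fc[io])
    w01 <- (1 - fr[io]) * fc[io];       w11 <- fr[io] * fc[io]
    om <- matrix(0, h * w, nt)
    om[io, ] <- w00 * m[i00, , drop = FALSE] + w10 * m[i10, , drop = FALSE] +
      w01 * m[i01, , drop = FALSE] + w11 * m[i11, , drop = FALSE]
    out <- array(om, c(h, w, nt))
  }
  out
}

#' Intersection of brain masks
#'
#' @param masks list of logical matrices of identical shape.
#' @return elementwise logical AND.
#' @export
shared_mask <- function(masks) {
  stopifnot(length(masks) >= 1)
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("mask shapes differ")
  Reduce(`&`, masks)
}
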