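#' Build a synthetic dorsal-cortex atlas
#'
#' Constructs a left-right symmetric, roughly elliptical dorsal-cortex brain
#' mask together with a midline column and three skull landmarks (the anterior
#' vessel junction over the olfactory bulbs, a midline suture point, and
#' lambda).  The geometry emulates a tandem-lens macroscope field of view of
#' about 1 cm^2 imaged at 128 x 128 after 4 x 4 on-camera binning.
#'
#' @param width,height image dimensions in pixels (>= 32).
#' @param pixel_size edge length of one pixel in mm.
#' @return An object of class `atlas_spec`: a list with `width`, `height`,
#'   `brain_mask` (height x width logical matrix), `midline_col` (columns
#'   `1:midline_col` form the left hemisphere; the mask is mirror-symmetric
#'   about the vertical centre line), `landmarks` (named list of `c(row, col)`
#'   points) and `pixel_size`.
#' @examples
#' atl <- make_atlas(64, 64, 0.156)
#' sum(atl$brain_mask) * atl$pixel_size^2  # mask area in mm^2
#' @export
make_atlas <- function(width = 128L, height = 128L, pixel_size = 0.078) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 32L || height < 32L)
    stop("atlas dimensions must be at least 32 x 32 to place landmarks")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")

  cx <- (width + 1) / 2          # mirror axis (between columns for even width)
  cy <- (height + 1) / 2
  col <- matrix(rep(seq_len(width), each = height), height, width)
  row <- matrix(rep(seq_len(height), times = width), height, width)
  # dorsal cortex outline: ellipse slightly taller than wide, with a gentle
  # anterior taper toward the olfactory bulbs
  a <- 0.44 * width
  b <- 0.47 * height
  taper <- 1 - 0.15 * pmax(0, (cy - row) / cy)^2
  mask <- ((col - cx) / (a * taper))^2 + ((row - cy) / b)^2 <= 1
  # enforce exact mirror symmetry
  mask <- mask | mask[, width:1]

  midline_col <- width %/% 2L
  rows_in <- which(apply(mask, 1, any))
  top <- min(rows_in); bottom <- max(rows_in)
  mid <- as.integer(round(cx))
  landmarks <- list(
    anterior_junction = c(row = top + as.integer(round(0.06 * height)), col = mid),
    midline_suture    = c(row = as.integer(round(cy)), col = mid),
    lambda            = c(row = bottom - as.integer(round(0.06 * height)), col = mid)
  )
  for (lm in landmarks)
    if (!mask[lm["row"], lm["col"]])
      stop("atlas too small: landmark fell outside the brain mask")

  structure(list(width = width, height = height, brain_mask = mask,
                 midline_col = midline_col, landmarks = landmarks,
                 pixel_size = pixel_size),
            class = "atlas_spec")
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat("<atlas_spec> ", x$width, "x", x$height, " px, ",
      format(sum(x$brain_mask) * x$pixel_size^2, digits = 3),
      " mm^2 brain mask, midline after column ", x$midline_col, "\n", sep = "")
  invisible(x)
}

#' Mirror an image about the atlas midline
#'
#' @param img height x width matrix.
#' @return the left-right flipped matrix.
#' @export
mirror_lr <- function(img) img[, ncol(img):1, drop = FALSE]

#' Hemisphere membership of each column
#'
#' @param atlas an `atlas_spec`.
#' @return height x width logical matrix, `TRUE` on the left hemisphere
#'   (columns `1:midline_col`).
#' @export
left_hemisphere <- function(atlas) {
  m <- matrix(FALSE, atlas$height, atlas$width)
  m[, seq_len(atlas$midline_col)] <- TRUE
  m
}

#' Disc mask around a centre pixel
#'
#' @param atlas an `atlas_spec` (or any list with `height`/`width`).
#' @param center `c(row, col)`.
#' @param radius radius in pixels; pixels with Euclidean distance <= radius
#'   are included.
#' @return height x width logical matrix.
#' @export
disc_mask <- function(atlas, center, radius) {
  col <- matrix(rep(seq_len(atlas$width), each = atlas$height),
                atlas$height, atlas$width)
  row <- matrix(rep(seq_len(atlas$height), times = atlas$width),
                atlas$height, atlas$width)
  (row - center[1])^2 + (col - center[2])^2 <= radius^2
}

# unit-peak isotropic Gaussian footprint centred at `center`
gaussian_footprint <- function(atlas, center, sigma) {
  col <- matrix(rep(seq_len(atlas$width), each = atlas$height),
                atlas$height, atlas$width)
  row <- matrix(rep(seq_len(atlas$height), times = atlas$width),
                atlas$height, atlas$width)
  exp(-((row - center[1])^2 + (col - center[2])^2) / (2 * sigma^2))
}
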