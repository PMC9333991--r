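#' Hemoglobin extinction coefficients
#'
#' Linearly interpolates the bundled compilation of HbO/HbR molar extinction
#' coefficients (see `inst/extdata/hb_extinction.tsv` for provenance) at the
#' requested wavelengths.
#'
#' @param wavelengths nm, each within the tabulated range (450-660 nm).
#' @return length(wavelengths) x 2 matrix, columns `HbO`, `HbR`, in 1/(M cm).
#' @export
extinction_table <- function(wavelengths) {
  tab <- .hb_table()
  if (any(wavelengths < min(tab$wavelength_nm)) ||
      any(wavelengths > max(tab$wavelength_nm)))
    stop("wavelength outside tabulated range [",
         min(tab$wavelength_nm), ", ", max(tab$wavelength_nm), "] nm")
  cbind(HbO = stats::approx(tab$wavelength_nm, tab$eps_hbo, wavelengths)$y,
        HbR = stats::approx(tab$wavelength_nm, tab$eps_hbr, wavelengths)$y)
}

#' Differential pathlength factors
#'
#' @param wavelengths nm, within 450-660 nm.
#' @return pathlength in cm per wavelength (linear interpolation of the
#'   bundled table).
#' @export
pathlength_table <- function(wavelengths) {
  tab <- utils::read.delim(system.file("extdata", "pathlength.tsv",
                                       package = "mesomap"),
                           comment.char = "#")
  if (any(wavelengths < min(tab$wavelength_nm)) ||
      any(wavelengths > max(tab$wavelength_nm)))
    stop("wavelength outside tabulated pathlength range")
  stats::approx(tab$wavelength_nm, tab$pathlength_cm, wavelengths)$y
}

.hb_table <- function() {
  utils::read.delim(system.file("extdata", "hb_extinction.tsv",
                                package = "mesomap"),
                    comment.char = "#")
}

#' Multi-wavelength reflectance stack
#'
#' @param data named list, one `height x width x time` array per wavelength
#'   (names = wavelength in nm), reflectance relative to baseline.
#' @param wavelengths nm, strictly increasing, matching `names(data)`.
#' @param frame_rate per-wavelength frame rate, Hz.
#' @param mask brain mask (logical matrix).
#' @return object of class `reflectance_stack`.
#' @export
reflectance_stack <- function(data, wavelengths, frame_rate, mask) {
  stopifnot(is.list(data), length(data) == length(wavelengths))
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  d <- dim(data[[1]])
  for (a in data) if (!identical(dim(a), d)) stop("wavelength arrays differ in shape")
  if (!identical(dim(mask), d[1:2])) stop("mask shape does not match data")
  names(data) <- as.character(wavelengths)
  structure(list(data = data, wavelengths = wavelengths,
                 frame_rate = frame_rate, mask = mask),
            class = "reflectance_stack")
}

#' Hemoglobin concentration movie
#'
#' Container for pixelwise changes in oxy- (HbO), deoxy- (HbR) and total
#' (HbT = HbO + HbR) hemoglobin concentration.  The HbT identity is enforced
#' at construction and re-asserted after every transform in the package.
#'
#' @param hbo,hbr `height x width x time` arrays of concentration change, M.
#' @param frame_rate Hz.
#' @param mask brain mask.
#' @param space "camera" or "atlas".
#' @return object of class `hemo_movie` with elements `hbo`, `hbr`, `hbt`.
#' @export
hemo_movie <- function(hbo, hbr, frame_rate, mask, space = "camera") {
  stopifnot(identical(dim(hbo), dim(hbr)), frame_rate > 0)
  if (!identical(dim(mask), dim(hbo)[1:2])) stop("mask shape mismatch")
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                 frame_rate = frame_rate, mask = mask, space = space),
            class = "hemo_movie")
}

#' @export
print.hemo_movie <- function(x, ...) {
  d <- dim(x$hbo)
  cat("<hemo_movie> ", d[1], "x", d[2], " px, ", d[3], " frames @ ",
      x$frame_rate, " Hz (", x$space, " space)\n", sep = "")
  invisible(x)
}

# internal: rebuild hbt and sanity-check the identity
.assert_hbt <- function(movie) {
  movie$hbt <- movie$hbo + movie$hbr
  movie
}

#' Ratiometric normalization of raw reflectance
#'
#' Divides each pixel's trace by its own temporal mean, separately per
#' wavelength, yielding reflectance relative to baseline (temporal mean 1 at
#' every pixel).
#'
#' @param stack a `reflectance_stack` of raw intensities.
#' @return a `reflectance_stack` of relative reflectance.
#' @export
normalize_reflectance <- function(stack) {
  for (w in names(stack$data)) {
    a <- stack$data[[w]]
    if (any(a[stack$mask] <= 0))
      stop("nonpositive raw intensity inside the brain mask at ", w, " nm")
    m <- rowMeans(matrix(a, prod(dim(a)[1:2]), dim(a)[3]))
    stack$data[[w]] <- array(matrix(a, length(m)) / m, dim(a))
  }
  stack
}

#' Modified Beer-Lambert inversion
#'
#' Converts relative reflectance at >= 2 wavelengths to pixelwise changes in
#' HbO and HbR concentration.  Per pixel and time point the absorption change
#' is `dmu_a(lambda) = -ln R(lambda) / L(lambda)`; the overdetermined linear
#' system `E [dHbO, dHbR]' = dmu_a` is solved by least squares (QR) across
#' wavelengths.  The condition number of the weighted design is reported via
#' `message()` once per call.
#'
#' @param stack a normalized `reflectance_stack` (values relative to baseline).
#' @param optics an `optics_model` whose wavelengths match the stack.
#' @param quiet suppress the conditioning message.
#' @return a `hemo_movie` in camera space.
#' @export
invert_beer_lambert <- function(stack, optics, quiet = FALSE) {
  if (!isTRUE(all.equal(stack$wavelengths, optics$wavelengths)))
    stop("stack and optics wavelengths differ")
  E <- optics$extinction
  if (qr(E)$rank < 2) stop("extinction matrix is rank deficient; inversion undetermined")
  kap <- kappa(E, exact = TRUE)
  if (!quiet)
    message(sprintf("Beer-Lambert inversion: %d wavelengths, condition number %.2f",
                    nrow(E), kap))
  d <- dim(stack$data[[1]]); npx <- prod(d[1:2])
  # dmu_a: wavelength x (pixel*time)
  M <- matrix(0, length(stack$wavelengths), npx * d[3])
  for (k in seq_along(stack$wavelengths)) {
    R <- stack$data[[k]]
    if (any(R[rep(stack$mask, d[3])] <= 0))
      stop("nonpositive reflectance inside the brain mask")
    M[k, ] <- -log(as.vector(R)) / optics$pathlength[k]
  }
  sol <- qr.solve(E, M)   # 2 x (pixel*time), least squares via QR
  hemo_movie(hbo = array(sol[1, ], d), hbr = array(sol[2, ], d),
             frame_rate = stack$frame_rate, mask = stack$mask,
             space = "camera")
}
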