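#' Photostimulation target site
#'
#' @param center `c(row, col)` atlas pixel of the stimulated site.
#' @param radius seed disc radius in pixels (default 4, about 310 um at the
#'   default pixel size).
#' @param laser metadata list (nm, mW, Hz, pulse ms).
#' @return object of class `stim_target`.
#' @export
stim_target <- function(center, radius = 4,
                        laser = list(nm = 473, mW = 0.5, hz = 10, pulse_ms = 5)) {
  if (radius <= 0) stop("radius must be positive")
  structure(list(center = center, radius = radius, laser = laser),
            class = "stim_target")
}

#' Block average for photostimulation sessions
#'
#' Shared code path with the electrical-stimulus analysis: slices the 10-Hz
#' hemodynamic movie into blocks (default 30 blocks of 10 s stimulation +
#' 50 s rest) and returns the baseline-subtracted block average.  Block
#' averaging, not band-pass filtering, is the denoiser for stimulus-locked
#' traces.
#'
#' @param movie a `hemo_movie` (typically 10 Hz).
#' @param paradigm a `stim_paradigm` (default the optogenetic design).
#' @return a `block_average`.
#' @export
photostim_block_average <- function(movie, paradigm = stim_paradigm("optogenetic")) {
  stack <- extract_blocks(movie, paradigm)
  message("photostim block average over ", dim(stack$blocks)[1], " blocks")
  block_average(stack)
}

#' Mean evoked trace at the photostimulated site
#'
#' Unweighted mean of the block-averaged time courses over all pixels within
#' `radius` pixels (Euclidean) of the target centre, intersected with the
#' mask.
#'
#' @param avg a `block_average`.
#' @param target a `stim_target`.
#' @return numeric time series.
#' @export
target_seed_trace <- function(avg, target) {
  atlas_like <- list(height = avg$dim_image[1], width = avg$dim_image[2])
  disc <- disc_mask(atlas_like, target$center, target$radius) & avg$mask
  if (!any(disc)) stop("target disc does not intersect the mask")
  colMeans(avg$avg[as.vector(disc), , drop = FALSE])
}

#' Photostimulus effective-connectivity map
#'
#' Pearson correlation (raw r, not Fisher-z: downstream thresholding at 0 is
#' sign-based) between the stimulated-site trace and every pixel's
#' block-averaged time course.
#'
#' @param avg a `block_average`.
#' @param seed seed time series from [target_seed_trace()].
#' @return matrix of correlation coefficients (`NA` outside the mask or at
#'   zero-variance pixels).
#' @export
effective_connectivity_map <- function(avg, seed) {
  if (stats::var(seed) == 0) stop("seed trace has zero variance")
  r <- rep(NA_real_, nrow(avg$avg))
  idx <- which(as.vector(avg$mask))
  v <- apply(avg$avg[idx, , drop = FALSE], 1, stats::var)
  ok <- idx[v > 0]
  r[ok] <- as.vector(stats::cor(seed, t(avg$avg[ok, , drop = FALSE])))
  matrix(r, avg$dim_image[1], avg$dim_image[2])
}

#' Global inhibition index
#'
#' Counts the mask pixels anticorrelated with the photostimulated seed
#' (`r < 0`, strict; `r = 0` and `NA` pixels do not count).  An optional
#' magnitude mode returns `sum(|r|)` over those pixels instead.
#'
#' @param map correlation map from [effective_connectivity_map()].
#' @param mask logical matrix.
#' @param mode "count" (default) or "magnitude".
#' @param pixel_size optional mm/pixel; when given, `area_mm2` is reported.
#' @return object of class `inhibition_index`: `value`, `mode`, `n_mask`,
#'   optional `area_mm2`.
#' @export
inhibition_index <- function(map, mask, mode = c("count", "magnitude"),
                             pixel_size = NULL) {
  mode <- match.arg(mode)
  sel <- mask & !is.na(map) & map < 0
  value <- if (mode == "count") sum(sel) else sum(abs(map[sel]))
  structure(list(value = value, mode = mode, n_mask = sum(mask),
                 area_mm2 = if (!is.null(pixel_size) && mode == "count")
                   sum(sel) * pixel_size^2 else NULL),
            class = "inhibition_index")
}

#' Simulate a photostimulation session with an anticorrelated surround
#'
#' Generates a 10-Hz hemodynamic movie containing a driven response at the
#' stimulated site plus a spatially extended surround whose evoked time
#' course is scaled by `surround_weight` (negative values emulate
#' stimulus-locked surround inhibition).  Noise is drawn once per seed, so
#' sweeping `surround_weight` at a fixed seed is a paired, common-random-
#' numbers experiment.
#'
#' @param atlas an `atlas_spec`.
#' @param target a `stim_target`.
#' @param paradigm a `stim_paradigm` (default optogenetic).
#' @param amplitude peak driven HbT amplitude, M.
#' @param surround_weight surround coupling weight in [-1, 1] (0 = none).
#' @param surround_sigma spatial SD of the surround footprint, pixels.
#' @param center_sigma spatial SD of the driven response, pixels.
#' @param noise_sd pixel noise SD, M (0 = noise-free dynamics).
#' @param sampling_rate Hz (default 10).
#' @param seed integer seed.
#' @param hb_coupling dHbR/dHbO ratio.
#' @return list with `movie` and `truth` (planted waveform and weights).
#' @export
simulate_photostim <- function(atlas, target,
                               paradigm = stim_paradigm("optogenetic"),
                               amplitude = 5e-6, surround_weight = 0,
                               surround_sigma = 12, center_sigma = 3,
                               noise_sd = 0.2e-6, sampling_rate = 10,
                               seed = 1, hb_coupling = -0.4) {
  set.seed(as.integer(seed))
  fs <- sampling_rate
  n_t <- round(paradigm$n_blocks * paradigm$block_s * fs)
  t <- (seq_len(n_t) - 1) / fs
  onsets <- paradigm$pre_s + (seq_len(paradigm$n_blocks) - 1) * paradigm$block_s
  box <- rep(0, n_t)
  for (o in onsets) box[t >= o & t < o + paradigm$stim_s] <- 1
  irf <- gamma_irf(seq(0, 30, by = 1 / fs))
  wav <- stats::convolve(box, rev(irf), type = "open")[seq_len(n_t)]
  wav <- wav / max(wav)
  amp_hbo <- amplitude / (1 + hb_coupling)

  fp_c <- as.vector(gaussian_footprint(atlas, target$center, center_sigma))
  # annular surround: broad Gaussian minus the core, non-negative
  fp_s <- as.vector(gaussian_footprint(atlas, target$center, surround_sigma))
  fp_s <- pmax(fp_s - fp_c, 0)
  npx <- atlas$height * atlas$width
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(npx * n_t, sd = noise_sd), npx) else 0
  mat <- (fp_c + surround_weight * fp_s) %*% t(wav * amp_hbo)
  mat <- mat + noise
  movie <- .finish_movie(atlas, mat, n_t, fs, hb_coupling)
  truth <- structure(list(waveform = wav, amplitude = amplitude,
                          surround_weight = surround_weight,
                          center_footprint = fp_c, surround_footprint = fp_s,
                          block_onsets_s = onsets, rng_seed = as.integer(seed)),
                     class = "ground_truth")
  list(movie = movie, truth = truth)
}
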