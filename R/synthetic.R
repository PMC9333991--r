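#' Gamma-variate hemodynamic impulse response
#'
#' Unit-peak gamma-variate kernel `h(t) = (t/tp)^a exp(a (1 - t/tp))` used to
#' convolve boxcar stimuli into evoked hemodynamic responses.  Defaults peak
#' at 2 s with a full width at half maximum of about 3 s.
#'
#' @param t time grid, s (t >= 0).
#' @param peak_s time to peak, s.
#' @param shape dimensionless shape `a`; larger is narrower
#'   (FWHM ~ 2.355 * peak_s / sqrt(shape)).
#' @return kernel values, max 1 at `t = peak_s`.
#' @export
gamma_irf <- function(t, peak_s = 2, shape = 2.5) {
  h <- ifelse(t <= 0, 0, (t / peak_s)^shape * exp(shape * (1 - t / peak_s)))
  h
}

# eigen-based symmetric square root of a PSD correlation matrix
.corr_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("target correlation matrix is not PSD")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# shared machinery: resting-state node dynamics rendered to a pixel movie.
# Returns list(mat = npx x T HbO matrix, node_tc = n_nodes x T, n_t).
.simulate_core <- function(atlas, network, n_t) {
  C <- target_corr_matrix(network)
  n <- nrow(C)
  Z <- matrix(stats::rnorm(n * n_t), n, n_t)
  X <- (.corr_sqrt(C) %*% Z) * network$signal_sd       # node time courses
  F <- sapply(seq_len(n), function(k)
    as.vector(gaussian_footprint(atlas, c(network$nodes$row[k],
                                          network$nodes$col[k]),
                                 network$nodes$sigma[k])))
  mat <- F %*% X
  if (network$global_sd > 0) {
    g <- stats::rnorm(n_t, sd = network$global_sd)
    mat <- mat + rep(g, each = nrow(mat))
  }
  if (network$noise_sd > 0)
    mat <- mat + matrix(stats::rnorm(length(mat), sd = network$noise_sd),
                        nrow(mat))
  list(mat = mat, node_tc = X, n_t = n_t)
}

.finish_movie <- function(atlas, hbo_mat, n_t, frame_rate, hb_coupling) {
  d <- c(atlas$height, atlas$width, n_t)
  hbo <- array(hbo_mat, d)
  hemo_movie(hbo = hbo, hbr = hb_coupling * hbo, frame_rate = frame_rate,
             mask = atlas$brain_mask, space = "atlas")
}

#' Simulate resting-state cortical hemodynamics
#'
#' Draws zero-mean node time courses with the network's target correlation
#' matrix (via its symmetric matrix square root), renders them through the
#' nodes' spatial Gaussian footprints, and adds an optional brain-wide shared
#' fluctuation plus independent white pixel noise.  HbR is coupled to HbO by
#' a fixed ratio (`hb_coupling`), so HbT = (1 + hb_coupling) * HbO carries the
#' same correlation structure.
#'
#' @param atlas an `atlas_spec`.
#' @param network a `network_spec`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param hb_coupling ratio dHbR/dHbO (default -0.4: activation raises HbT).
#' @return list with `movie` (a `hemo_movie` in atlas space) and `truth`
#'   (class `ground_truth`: planted node time courses, network, seed).
#' @export
simulate_resting <- function(atlas, network, seed, hb_coupling = -0.4) {
  set.seed(as.integer(seed))
  n_t <- round(network$duration * network$sampling_rate)
  core <- .simulate_core(atlas, network, n_t)
  movie <- .finish_movie(atlas, core$mat, n_t, network$sampling_rate, hb_coupling)
  truth <- structure(list(hbo = movie$hbo, hbr = movie$hbr,
                          node_timecourses = core$node_tc, network = network,
                          lesion = NULL, evoked_amplitude = NULL,
                          block_onsets_s = NULL, rng_seed = as.integer(seed)),
                     class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' Simulate a block-design evoked-response session
#'
#' Superimposes on resting dynamics a stimulus-evoked response at one node:
#' a boxcar over each stimulation window convolved with [gamma_irf()], scaled
#' so its peak equals `amplitude` in HbT.  A `lesion_spec` attenuates the
#' response of any node whose centre lies inside the lesion disc and, from
#' `remap_onset_session` on, adds a remapped response at the perilesional
#' remap site at the attenuated node's residual-complement amplitude.
#'
#' @param atlas,network,seed as in [simulate_resting()].
#' @param paradigm a `stim_paradigm`; session duration is
#'   `n_blocks * block_s`.
#' @param target_node name of the stimulated node.
#' @param amplitude peak evoked HbT amplitude, M (e.g. 5e-6 for 5 uM).
#' @param lesion optional `lesion_spec`.
#' @param session session label (e.g. "baseline", "week1", "week4") compared
#'   against `lesion$remap_onset_session`.
#' @param remap_gain fraction of the original amplitude expressed at the
#'   remapped site once remapping is active.
#' @param hb_coupling dHbR/dHbO ratio.
#' @return list with `movie` and `truth`; `truth$block_onsets_s` records the
#'   stimulus onset of every block.
#' @export
simulate_evoked <- function(atlas, network, paradigm, target_node, amplitude,
                            seed, lesion = NULL, session = "baseline",
                            remap_gain = 0.6, hb_coupling = -0.4) {
  k <- match(target_node, network$nodes$name)
  if (is.na(k)) stop("unknown target node: ", target_node)
  set.seed(as.integer(seed))
  fs <- network$sampling_rate
  n_t <- round(paradigm$n_blocks * paradigm$block_s * fs)
  core <- .simulate_core(atlas, network, n_t)

  # unit-peak evoked waveform: boxcar (*) gamma IRF, one per block
  t <- (seq_len(n_t) - 1) / fs
  onsets <- paradigm$pre_s + (seq_len(paradigm$n_blocks) - 1) * paradigm$block_s
  box <- rep(0, n_t)
  for (o in onsets) box[t >= o & t < o + paradigm$stim_s] <- 1
  irf <- gamma_irf(seq(0, 30, by = 1 / fs))
  wav <- stats::convolve(box, rev(irf), type = "open")[seq_len(n_t)]
  wav <- wav / max(wav)

  center <- c(network$nodes$row[k], network$nodes$col[k])
  amp_hbt <- amplitude
  gain <- 1
  if (!is.null(lesion) &&
      sum((center - lesion$center)^2) <= lesion$radius^2)
    gain <- 1 - lesion$attenuation
  # amplitude is specified in HbT; plant in HbO so HbT peaks at `amplitude`
  amp_hbo <- amp_hbt / (1 + hb_coupling)
  fp <- as.vector(gaussian_footprint(atlas, center, network$nodes$sigma[k]))
  mat <- core$mat + fp %*% t(wav * amp_hbo * gain)

  if (!is.null(lesion) && !is.null(lesion$remap_center) &&
      !is.null(lesion$remap_onset_session) &&
      session %in% lesion$remap_onset_session) {
    fp2 <- as.vector(gaussian_footprint(atlas, lesion$remap_center,
                                        network$nodes$sigma[k]))
    mat <- mat + fp2 %*% t(wav * amp_hbo * remap_gain)
  }

  movie <- .finish_movie(atlas, mat, n_t, fs, hb_coupling)
  truth <- structure(list(hbo = movie$hbo, hbr = movie$hbr,
                          node_timecourses = core$node_tc, network = network,
                          lesion = lesion, evoked_amplitude = amp_hbt,
                          block_onsets_s = onsets, rng_seed = as.integer(seed)),
                     class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' Forward Beer-Lambert model: hemoglobin to reflectance
#'
#' Renders concentration-change movies to multi-wavelength relative
#' reflectance: `R_lambda(t) = exp(-[eps_HbO dHbO + eps_HbR dHbR] L(lambda))`
#' with baseline reflectance 1 by convention.  Inverse of
#' [invert_beer_lambert()].
#'
#' @param hbo,hbr `height x width x time` arrays (M), or a `hemo_movie` as
#'   `hbo` with `hbr` missing.
#' @param optics an `optics_model`.
#' @param frame_rate Hz (taken from the movie if one is supplied).
#' @param mask brain mask (ditto).
#' @return a `reflectance_stack`.
#' @export
reflectance_forward <- function(hbo, hbr = NULL, optics = optics_model(),
                                frame_rate = NULL, mask = NULL) {
  if (inherits(hbo, "hemo_movie")) {
    movie <- hbo
    hbo <- movie$hbo; hbr <- movie$hbr
    frame_rate <- frame_rate %||% movie$frame_rate
    mask <- mask %||% movie$mask
  }
  if (!identical(dim(hbo), dim(hbr))) stop("hbo and hbr dimensions differ")
  if (is.null(mask)) mask <- matrix(TRUE, dim(hbo)[1], dim(hbo)[2])
  if (is.null(frame_rate)) frame_rate <- 1
  d <- dim(hbo)
  data <- lapply(seq_along(optics$wavelengths), function(k) {
    mu <- optics$extinction[k, "HbO"] * hbo + optics$extinction[k, "HbR"] * hbr
    array(exp(-mu * optics$pathlength[k]), d)
  })
  reflectance_stack(data, optics$wavelengths, frame_rate, mask)
}

#' Simulate cylinder-rearing paw-contact tables
#'
#' Draws per-mouse forelimb-use asymmetry from group/session normal effects
#' and converts it to left/right/both wall-contact times such that the
#' asymmetry score `(L - R) / (L + R)` (single-paw times) equals the drawn
#' value.
#'
#' @param group_effects data.frame with columns `group`, `session`,
#'   `mean`, `sd` (asymmetry scale, dimensionless in [-1, 1]).
#' @param n_mice mice per group.
#' @param seed integer seed.
#' @param single_paw_s total single-paw contact time per session, s.
#' @param both_mean_s mean both-paw contact time, s.
#' @return data.frame: `mouse`, `group`, `session`, `t_left`, `t_right`,
#'   `t_both`, `true_asymmetry`.
#' @export
simulate_behavior <- function(group_effects, n_mice, seed,
                              single_paw_s = 30, both_mean_s = 10) {
  stopifnot(all(c("group", "session", "mean", "sd") %in% names(group_effects)))
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(nrow(group_effects)), function(i) {
    g <- group_effects[i, ]
    a <- pmax(-0.999, pmin(0.999, stats::rnorm(n_mice, g$mean, g$sd)))
    data.frame(mouse = sprintf("%s_m%02d", g$group, seq_len(n_mice)),
               group = g$group, session = g$session,
               t_left = single_paw_s * (1 + a) / 2,
               t_right = single_paw_s * (1 - a) / 2,
               t_both = pmax(0, stats::rnorm(n_mice, both_mean_s, 2)),
               true_asymmetry = a)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR Ct table with planted group effects
#'
#' Generates threshold-cycle values for `n_genes` target genes plus a
#' reference gene (Gapdh) across groups, with group effects planted on the
#' log2 expression scale: a +1 log2 effect lowers the target Ct by 1 cycle.
#'
#' @param n_genes number of target genes.
#' @param group_log2_effects `n_genes x n_groups` matrix of log2 fold effects
#'   relative to the first (control) column; column names are group labels.
#' @param sd per-sample Ct noise SD (cycles).
#' @param seed integer seed.
#' @param n_per_group samples per group.
#' @param tissue optional tissue label recycled over groups (stored in
#'   metadata).
#' @return list of class `expression_table`: `ct` (genes + reference row x
#'   samples matrix), `ref_gene`, and `meta` (data.frame `sample`, `group`,
#'   `tissue`).
#' @export
simulate_expression <- function(n_genes, group_log2_effects, sd, seed,
                                n_per_group = 5, tissue = "perilesional") {
  group_log2_effects <- as.matrix(group_log2_effects)
  stopifnot(nrow(group_log2_effects) == n_genes)
  groups <- colnames(group_log2_effects)
  if (is.null(groups)) groups <- paste0("grp", seq_len(ncol(group_log2_effects)))
  set.seed(as.integer(seed))
  genes <- sprintf("gene%02d", seq_len(n_genes))
  base_dct <- stats::runif(n_genes, 4, 10)     # gene-specific baseline dCt
  samples <- character(0); grp <- character(0)
  ct <- NULL
  for (j in seq_along(groups)) {
    for (s in seq_len(n_per_group)) {
      ref_ct <- stats::rnorm(1, 18, 0.2)
      tgt <- ref_ct + base_dct - group_log2_effects[, j] +
        stats::rnorm(n_genes, 0, sd)
      ct <- cbind(ct, c(tgt, ref_ct))
      samples <- c(samples, sprintf("%s_s%02d", groups[j], s))
      grp <- c(grp, groups[j])
    }
  }
  rownames(ct) <- c(genes, "Gapdh"); colnames(ct) <- samples
  structure(list(ct = ct, ref_gene = "Gapdh",
                 meta = data.frame(sample = samples, group = grp,
                                   tissue = rep_len(tissue, length(samples)))),
            class = "expression_table")
}
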