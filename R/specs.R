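#' Resting-state network specification
#'
#' Defines the nodes (cortical regions modelled as Gaussian activity
#' footprints) and the target zero-lag correlation structure of the synthetic
#' resting-state dynamics.  Typical configurations pair homotopic nodes at
#' r ~ 0.7 and anticorrelate anterior (motor/somatosensory) with posterior
#' (visual) nodes at r ~ -0.4.
#'
#' @param nodes data.frame with columns `name`, `row`, `col`, `sigma`
#'   (footprint SD in pixels) and `hemisphere` ("L"/"R").
#' @param edges data.frame with columns `from`, `to`, `r` (target Pearson
#'   correlation in (-1, 1)); unlisted pairs default to r = 0.
#' @param noise_sd SD of independent white pixel noise, same units as the
#'   node signal (molar when used for hemoglobin dynamics).
#' @param global_sd SD of an optional brain-wide shared fluctuation added to
#'   every mask pixel (what global signal regression removes); 0 disables it.
#' @param signal_sd SD of each node time course (molar); node signals are
#'   zero-mean.
#' @param sampling_rate Hz.
#' @param duration s.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(nodes, edges = NULL, noise_sd = 0.05e-6,
                         global_sd = 0, signal_sd = 1e-6,
                         sampling_rate = 1, duration = 300) {
  stopifnot(is.data.frame(nodes),
            all(c("name", "row", "col", "sigma", "hemisphere") %in% names(nodes)))
  if (anyDuplicated(nodes$name)) stop("node names must be unique")
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(), r = numeric())
  stopifnot(all(c("from", "to", "r") %in% names(edges)))
  if (nrow(edges) && any(abs(edges$r) >= 1))
    stop("edge correlations must lie strictly inside (-1, 1)")
  bad <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(bad)) stop("edges reference unknown nodes: ",
                        paste(bad, collapse = ", "))
  spec <- structure(list(nodes = nodes, edges = edges, noise_sd = noise_sd,
                         global_sd = global_sd, signal_sd = signal_sd,
                         sampling_rate = sampling_rate, duration = duration),
                    class = "network_spec")
  ev <- eigen(target_corr_matrix(spec), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target correlation matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  spec
}

#' Target correlation matrix of a network specification
#'
#' @param network a `network_spec`.
#' @return symmetric unit-diagonal matrix ordered as `network$nodes$name`.
#' @export
target_corr_matrix <- function(network) {
  nm <- network$nodes$name
  C <- diag(length(nm)); dimnames(C) <- list(nm, nm)
  e <- network$edges
  if (nrow(e)) for (k in seq_len(nrow(e))) {
    C[e$from[k], e$to[k]] <- e$r[k]
    C[e$to[k], e$from[k]] <- e$r[k]
  }
  C
}

#' Focal lesion specification
#'
#' Models photothrombotic infarction as a spatial attenuation of evoked
#' activity: any node whose centre falls inside the lesion disc has its evoked
#' amplitude multiplied by `1 - attenuation`.  An optional remapped response
#' site switches on from `remap_onset_session` onward, emulating perilesional
#' remapping.
#'
#' @param center `c(row, col)` lesion centre in atlas pixels.
#' @param radius lesion radius in pixels.
#' @param attenuation fraction of the evoked amplitude removed, in [0, 1].
#' @param remap_center optional `c(row, col)` of the remapped site.
#' @param remap_onset_session session label (e.g. "week4") at which the
#'   remapped response first appears.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, attenuation,
                        remap_center = NULL, remap_onset_session = NULL) {
  stopifnot(length(center) == 2, radius > 0)
  if (attenuation < 0 || attenuation > 1)
    stop("attenuation must lie in [0, 1]")
  structure(list(center = center, radius = radius, attenuation = attenuation,
                 remap_center = remap_center,
                 remap_onset_session = remap_onset_session),
            class = "lesion_spec")
}

#' Block-design stimulus paradigm
#'
#' @param kind "electrical" (forepaw, 30 Hz hemodynamic sessions) or
#'   "optogenetic" (photostimulation, 10 Hz hemodynamic sessions).
#' @param pre_s rest before stimulus onset within each block, s.
#' @param stim_s stimulus duration, s.
#' @param post_s rest after stimulus offset, s.
#' @param n_blocks number of blocks.
#' @param pulse_rate stimulus pulse rate, Hz (metadata only).
#' @return object of class `stim_paradigm`; `block_s` gives the block length.
#' @details Defaults follow the two designs used throughout: electrical
#'   forepaw stimulation in 50-s blocks (5 s rest, 10 s stimulation at 3 Hz,
#'   35 s rest) repeated 18 times, and optogenetic stimulation in 60-s blocks
#'   (10 s on, 50 s rest) repeated 30 times.
#' @export
stim_paradigm <- function(kind = c("electrical", "optogenetic"),
                          pre_s = NULL, stim_s = NULL, post_s = NULL,
                          n_blocks = NULL, pulse_rate = NULL) {
  kind <- match.arg(kind)
  def <- if (kind == "electrical")
    list(pre_s = 5, stim_s = 10, post_s = 35, n_blocks = 18L, pulse_rate = 3)
  else
    list(pre_s = 5, stim_s = 10, post_s = 45, n_blocks = 30L, pulse_rate = 10)
  p <- list(kind = kind,
            pre_s = pre_s %||% def$pre_s,
            stim_s = stim_s %||% def$stim_s,
            post_s = post_s %||% def$post_s,
            n_blocks = as.integer(n_blocks %||% def$n_blocks),
            pulse_rate = pulse_rate %||% def$pulse_rate)
  if (any(unlist(p[c("pre_s", "stim_s", "post_s")]) <= 0))
    stop("all paradigm durations must be positive")
  if (p$n_blocks < 1L) stop("n_blocks must be >= 1")
  p$block_s <- p$pre_s + p$stim_s + p$post_s
  structure(p, class = "stim_paradigm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optical model for hemoglobin spectroscopy
#'
#' Bundles the quantities needed by the modified Beer-Lambert forward model
#' and its inversion: per-wavelength molar extinction coefficients of HbO and
#' HbR and differential pathlength factors.
#'
#' @param wavelengths LED centre wavelengths, nm; default the four channels
#'   478, 588, 610 and 625 nm.
#' @param extinction wavelength x 2 matrix, columns `HbO` and `HbR`, in
#'   1/(M cm); defaults to [extinction_table()] at `wavelengths`.
#' @param pathlength per-wavelength differential pathlength, cm; defaults to
#'   [pathlength_table()] at `wavelengths`.
#' @param baseline_hbo,baseline_hbr assumed resting concentrations, M
#'   (metadata; only concentration changes are analysed).
#' @return object of class `optics_model`.
#' @export
optics_model <- function(wavelengths = c(478, 588, 610, 625),
                         extinction = NULL, pathlength = NULL,
                         baseline_hbo = 60e-6, baseline_hbr = 40e-6) {
  if (length(wavelengths) < 2)
    stop("at least 2 wavelengths are required for a determined inversion")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (is.null(extinction)) extinction <- extinction_table(wavelengths)
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(length(wavelengths), 2)))
    stop("extinction must be a (n wavelengths) x 2 matrix")
  colnames(extinction) <- c("HbO", "HbR")
  if (any(extinction < 0)) stop("extinction coefficients must be non-negative")
  if (qr(extinction)$rank < 2)
    stop("extinction matrix must have full column rank")
  if (is.null(pathlength)) pathlength <- pathlength_table(wavelengths)
  if (any(pathlength <= 0)) stop("pathlengths must be positive")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 pathlength = pathlength, baseline_hbo = baseline_hbo,
                 baseline_hbr = baseline_hbr),
            class = "optics_model")
}
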