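#' Canonical 10-node demonstration network
#'
#' Five bilateral node pairs (motor, forepaw somatosensory, hindpaw
#' somatosensory, parietal, visual) with homotopic correlations of 0.7 and
#' motor-visual anticorrelations of -0.4 within each hemisphere, emulating
#' the anterior-posterior anticorrelation structure of mouse cortex.  The
#' target matrix is positive semidefinite.
#'
#' @param atlas an `atlas_spec`; node coordinates scale with the atlas.
#' @param ... passed to [network_spec()] (noise_sd, duration, ...).
#' @return a `network_spec` with 10 nodes.
#' @export
demo_network <- function(atlas, ...) {
  h <- atlas$height; w <- atlas$width
  rr <- function(f) round(f * h); cl <- function(f) round(f * w)
  nodes <- data.frame(
    name = c("motor_L", "motor_R", "forepaw_L", "forepaw_R",
             "hindpaw_L", "hindpaw_R", "parietal_L", "parietal_R",
             "visual_L", "visual_R"),
    # centres at least ~11 px apart (64-px grid) so that a 3-px ROI disc sees
    # a negligible tail (<1e-4) of any neighbouring footprint: unmixed ROI
    # traces are required for planted correlations to be recoverable
    row = c(rr(.22), rr(.22), rr(.36), rr(.36), rr(.50), rr(.50),
            rr(.64), rr(.64), rr(.80), rr(.80)),
    col = c(cl(.34), cl(.66), cl(.22), cl(.78), cl(.36), cl(.64),
            cl(.22), cl(.78), cl(.34), cl(.66)),
    sigma = rep(max(2, round(0.03 * w)), 10),
    hemisphere = rep(c("L", "R"), 5))
  # anticorrelation couples the bilateral motor network to the bilateral
  # visual network (all four pairings), which keeps the target matrix PSD
  edges <- data.frame(
    from = c("motor_L", "forepaw_L", "hindpaw_L", "parietal_L", "visual_L",
             "motor_L", "motor_R", "motor_L", "motor_R"),
    to   = c("motor_R", "forepaw_R", "hindpaw_R", "parietal_R", "visual_R",
             "visual_L", "visual_R", "visual_R", "visual_L"),
    r    = c(0.7, 0.7, 0.7, 0.7, 0.7, -0.4, -0.4, -0.4, -0.4))
  network_spec(nodes, edges, ...)
}

# evoked-session processing: truth hemo movie -> reflectance -> spectroscopic
# inversion -> block analysis; returns the recovered movie
.spectro_roundtrip <- function(movie, optics = optics_model()) {
  stack <- reflectance_forward(movie, optics = optics)
  invert_beer_lambert(stack, optics, quiet = TRUE)
}

#' Run a complete synthetic stroke study
#'
#' End-to-end pipeline on synthetic data emulating a 2-group
#' (contralesional-stimulation vs none), 3-session (baseline, week 1,
#' week 4) optical imaging study.  Per mouse and session it simulates an
#' electrical forepaw stimulation run and a resting-state run, renders them
#' to 4-wavelength reflectance, inverts the spectroscopy, and computes
#' evoked-response metrics (75%-of-baseline-max threshold), regional RSFC
#' matrices (after band-pass and global signal regression) and node degree;
#' plus cylinder-rearing behavior and qPCR fold-change tables.  All output
#' tables are written as CSV; the run is a pure function of `seed`.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param n_mice mice per group (default 3).
#' @param grid atlas size in pixels (default 48).
#' @param task_rate hemodynamic frame rate of task sessions, Hz (default 2).
#' @param rest_rate resting-session rate after downsampling, Hz (default 1).
#' @param n_blocks stimulation blocks per task run (default 18).
#' @param amplitude baseline evoked HbT amplitude, M.
#' @param attenuation named week-1/week-4 lesion attenuations per group.
#' @return invisibly, a list of the output tables.
#' @export
run_study_pipeline <- function(seed, out_dir = NULL, n_mice = 3, grid = 48,
                               task_rate = 2, rest_rate = 1,
                               n_blocks = 18, amplitude = 5e-6,
                               attenuation = list(
                                 minus_stim = c(week1 = 0.8, week4 = 0.6),
                                 plus_stim  = c(week1 = 0.8, week4 = 0.3))) {
  seed <- as.integer(seed)
  atlas <- make_atlas(grid, grid, pixel_size = 0.078 * 128 / grid)
  optics <- optics_model()
  paradigm <- stim_paradigm("electrical", n_blocks = n_blocks)
  groups <- names(attenuation)
  sessions <- c("baseline", "week1", "week4")
  fp_L <- c(row = round(0.42 * grid), col = round(0.25 * grid))
  lesion_of <- function(group, session) {
    if (session == "baseline") return(NULL)
    lesion_spec(center = fp_L, radius = round(0.08 * grid),
                attenuation = attenuation[[group]][[session]])
  }

  net_task <- demo_network(atlas, sampling_rate = task_rate,
                           noise_sd = 0.05e-6, signal_sd = 0.3e-6)
  net_rest <- demo_network(atlas, sampling_rate = rest_rate, duration = 300,
                           noise_sd = 0.05e-6, global_sd = 0.5e-6)

  rois <- list()
  for (k in seq_len(nrow(net_rest$nodes)))
    rois[[net_rest$nodes$name[k]]] <-
      disc_mask(atlas, c(net_rest$nodes$row[k], net_rest$nodes$col[k]), 3) &
      atlas$brain_mask

  evoked_rows <- NULL
  peak_maps <- list()
  rsfc_rows <- NULL
  degree_rows <- NULL
  mouse_id <- function(g, i) sprintf("%s_m%02d", g, i)

  for (g in groups) for (i in seq_len(n_mice)) for (ses in sessions) {
    mseed <- seed + 7919L * match(g, groups) + 101L * i +
      13L * match(ses, sessions)
    sim <- simulate_evoked(atlas, net_task, paradigm, "forepaw_L",
                           amplitude, seed = mseed,
                           lesion = lesion_of(g, ses), session = ses)
    rec <- .spectro_roundtrip(sim$movie, optics)
    avg <- block_average(extract_blocks(rec, paradigm))
    peak_maps[[paste(mouse_id(g, i), ses, sep = ".")]] <- peak_map(avg)

    rsim <- simulate_resting(atlas, net_rest, seed = mseed + 1L)
    rrec <- .spectro_roundtrip(rsim$movie, optics)
    rmov <- global_signal_regress(bandpass(rrec, 0.009, 0.08))
    cm <- corr_matrix(rmov, rois = rois)
    zvals <- cm$z[upper.tri(cm$z)]
    ut <- which(upper.tri(cm$z), arr.ind = TRUE)
    rsfc_rows <- rbind(rsfc_rows, data.frame(
      mouse = mouse_id(g, i), group = g, session = ses,
      roi_a = cm$index$unit[ut[, 1]], roi_b = cm$index$unit[ut[, 2]],
      z = zvals))
    pix <- corr_matrix(rmov, spatial_step = 4)
    degree_rows <- rbind(degree_rows, data.frame(
      mouse = mouse_id(g, i), group = g, session = ses,
      mean_degree = mean(node_degree(pix)$degree)))
  }

  # one shared 75% threshold from baseline maps of all mice
  base_maps <- peak_maps[grepl("\\.baseline$", names(peak_maps))]
  thr <- group_threshold(base_maps, mask = atlas$brain_mask)
  base_region <- Reduce(`+`, base_maps) / length(base_maps) >= thr
  base_metrics <- lapply(base_maps, response_metrics, threshold = thr,
                         mask = atlas$brain_mask)
  base_mag <- mean(vapply(base_metrics, `[[`, 0, "magnitude"), na.rm = TRUE)
  base_area <- mean(vapply(base_metrics, `[[`, 0, "area"))
  for (nm in names(peak_maps)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    em <- response_metrics(peak_maps[[nm]], thr,
                           baseline_magnitude = base_mag,
                           baseline_area = base_area,
                           mask = atlas$brain_mask,
                           fallback_region = base_region)
    evoked_rows <- rbind(evoked_rows, data.frame(
      mouse = parts[1], group = sub("_m[0-9]+$", "", parts[1]),
      session = parts[2], magnitude = em$magnitude, area = em$area,
      magnitude_norm = em$magnitude_norm, area_norm = em$area_norm))
  }

  behavior <- simulate_behavior(
    data.frame(group = rep(groups, each = 3),
               session = rep(sessions, 2),
               mean = c(0, 0.35, 0.25, 0, 0.35, 0.10),
               sd = 0.08),
    n_mice = n_mice, seed = seed + 5L)
  behavior$score <- asymmetry_score(behavior)

  eff <- cbind(minus_stim = rep(0, 8),
               plus_stim = c(1.5, 1.2, -1, 0, 0, 0.8, -0.6, 0))
  expr <- simulate_expression(8, eff, sd = 0.25, seed = seed + 6L)
  rel <- comparative_ct(expr, control_group = "minus_stim")
  fold <- fold_change_table(rel, treated = "plus_stim",
                            control = "minus_stim")

  out <- list(evoked_metrics = evoked_rows, rsfc = rsfc_rows,
              node_degree = degree_rows, behavior = behavior,
              expression_fold_change = fold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(out)
}
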