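#' Default pipeline configuration
#'
#' A flat named list of every tunable knob of the simulation and analysis
#' pipeline, writable/readable with [write_config_file()] /
#' [read_config_file()] and overridable per call. Optics keys mirror
#' [optical_config()]; carrier and filter keys drive [demodulate()];
#' `tau_rad`, `connectivity`, `min_volume_fl`, `min_px` drive segmentation;
#' the remaining keys parameterise the phantom generator.
#'
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(
    # optics
    wavelength_nm = 550, pixel_pitch_um = 0.16,
    n_medium = 1.337, n_water = 1.334, beta_dl_per_g = 0.00196,
    mchc_g_dl = 33, n_cell_override = NULL,
    # reconstruction
    carrier_auto = 0, carrier_u = 0.32, carrier_v = 0,
    filter_radius_frac = 0.5,
    # segmentation
    tau_rad = 0.3, connectivity = 8, min_volume_fl = 20, min_px = 1,
    # phantom scene
    grid_nrow = 512, grid_ncol = 512,
    n_cells = 30, mean_volume_fl = 90, rdw_percent = 15,
    platelet_fraction = 0.1,
    aberration_amplitude_rad = 0.5, n_dirt = 8,
    border_margin_px = 24, min_gap_um = 1.5, psf_sigma_um = 0.25,
    # camera
    fringe_contrast = 0.8, mean_intensity = 20000, noise_sd = 200,
    bit_depth = 16)
}

merge_config <- function(config, overrides) {
  for (k in names(overrides)) config[[k]] <- overrides[[k]]
  config
}

config_to_optics <- function(cfg) {
  ov <- cfg$n_cell_override
  if (!is.null(ov) && (is.na(ov) || ov <= 0)) ov <- NULL
  optical_config(
    wavelength_nm = cfg$wavelength_nm,
    pixel_pitch_um = cfg$pixel_pitch_um,
    n_medium = cfg$n_medium, n_water = cfg$n_water,
    beta_dl_per_g = cfg$beta_dl_per_g,
    mchc_g_dl = if (is.null(ov)) cfg$mchc_g_dl else NULL,
    n_cell_override = ov)
}

write_manifest <- function(entries, path) {
  write_config_file(entries, path)
}

#' Simulate a phantom acquisition to disk
#'
#' Draws a cell population, builds a ground-truthed scene and writes the
#' sample and background interferograms (16-bit TIFF), the ground-truth
#' table (CSV), the scene configuration and a run manifest into
#' `out_dir`. Fully deterministic given `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Pipeline configuration list; see
#'   [default_pipeline_config()].
#' @param seed Integer seed for population, placement and noise.
#' @param ... Individual configuration overrides, e.g. `n_cells = 10`.
#' @return Invisibly, a list with the scene, the file `paths` and the
#'   manifest.
#' @export
simulate_run <- function(out_dir, config = default_pipeline_config(),
                         seed = 1, ...) {
  config <- merge_config(config, list(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  optics <- config_to_optics(config)
  pf <- config$platelet_fraction
  mix <- if (pf > 0) c(biconcave = 1 - pf, platelet = pf)
         else c(biconcave = 1)
  t0 <- proc.time()[["elapsed"]]
  pop <- if (config$n_cells >= 1)
    sample_population(config$n_cells, config$mean_volume_fl,
                      config$rdw_percent, mix, seed = seed)
  else list()
  scene <- build_scene(pop, c(config$grid_nrow, config$grid_ncol),
                       optics, seed = seed + 1L,
                       aberration_amplitude_rad =
                         config$aberration_amplitude_rad,
                       n_dirt = config$n_dirt,
                       border_margin_px = config$border_margin_px,
                       min_gap_um = config$min_gap_um,
                       psf_sigma_um = config$psf_sigma_um)
  model <- interferogram_model(c(config$carrier_u, config$carrier_v),
                               fringe_contrast = config$fringe_contrast,
                               mean_intensity = config$mean_intensity,
                               noise_sd = config$noise_sd,
                               bit_depth = config$bit_depth)
  samp <- synthesize_interferogram(scene, model, seed = seed + 2L)
  bg <- make_background_frame(scene, model, seed = seed + 3L)
  paths <- list(
    sample = file.path(out_dir, "sample.tif"),
    background = file.path(out_dir, "background.tif"),
    truth = file.path(out_dir, "truth.csv"),
    config = file.path(out_dir, "scene_config.txt"),
    manifest = file.path(out_dir, "manifest_simulate.txt"))
  write_interferogram_tiff(samp, paths$sample)
  write_interferogram_tiff(bg, paths$background)
  write_truth_csv(scene, paths$truth)
  write_config_file(config, paths$config)
  manifest <- list(
    stage = "simulate", seed = seed,
    n_cells = length(scene$cells),
    grid = paste0(config$grid_nrow, "x", config$grid_ncol),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
    out_sample = paths$sample, out_background = paths$background,
    out_truth = paths$truth)
  write_manifest(manifest, paths$manifest)
  invisible(list(scene = scene, paths = paths, manifest = manifest))
}

#' Analyze interferogram frames end-to-end
#'
#' Runs the full measurement chain on one or more sample frames sharing
#' one background frame: demodulate, unwrap, subtract background,
#' threshold, label, filter (20 fL, border), per-cell morphology,
#' population statistics. Frames are analyzed independently and their cell
#' records concatenated. With `out_dir` set, writes the per-cell CSV, the
#' population summary, the corrected phase and label maps of the first
#' frame, and a manifest.
#'
#' @param sample Path(s) to sample TIFF(s), or a single [interferogram].
#' @param background Path to the background TIFF, an [interferogram], or
#'   `NULL` to analyze against a zero background (warns).
#' @param config Pipeline configuration; see [default_pipeline_config()].
#' @param out_dir Optional output directory.
#' @param ... Configuration overrides.
#' @return Invisibly, a list with `cells` (records data frame), `stats`
#'   (`population_stats` or `NULL` if no cells), `phase`, `labels` (first
#'   frame), `manifest`.
#' @export
analyze_run <- function(sample, background = NULL,
                        config = default_pipeline_config(),
                        out_dir = NULL, ...) {
  config <- merge_config(config, list(...))
  optics <- config_to_optics(config)
  t0 <- proc.time()[["elapsed"]]
  frames <- if (inherits(sample, "interferogram")) list(sample)
            else lapply(sample, read_interferogram_tiff,
                        pixel_pitch_um = optics$pixel_pitch_um)
  bg_ig <- if (is.null(background)) NULL
           else if (inherits(background, "interferogram")) background
           else read_interferogram_tiff(background,
                                        pixel_pitch_um = optics$pixel_pitch_um)
  carrier <- if (isTRUE(config$carrier_auto == 1))
    estimate_carrier(frames[[1]])
  else c(config$carrier_u, config$carrier_v)
  fr <- config$filter_radius_frac * sqrt(sum(carrier^2))

  bg_phase <- NULL
  if (!is.null(bg_ig))
    bg_phase <- unwrap_phase(demodulate(bg_ig, carrier, fr))

  all_records <- list()
  first <- NULL
  warn_residues <- 0L; clamped <- 0L
  n_before_filter <- 0L
  for (f in seq_along(frames)) {
    wrapped <- demodulate(frames[[f]], carrier, fr)
    un <- unwrap_phase(wrapped)
    warn_residues <- warn_residues + attr(un, "residues")
    corr <- if (is.null(bg_phase)) {
      warning("no background frame supplied; using zero background")
      suppressWarnings(subtract_background(un, NULL))
    } else subtract_background(un, bg_phase)
    labels <- segment_phase(corr, tau = config$tau_rad,
                            connectivity = config$connectivity)
    n_before_filter <- n_before_filter + labels$n_components
    hmap <- phase_to_height(phase_map(pmax(corr$values, 0),
                                      corr$pixel_pitch_um,
                                      background_subtracted = TRUE),
                            optics)
    cells <- extract_cells(labels, hmap, phase = corr,
                           min_volume_fl = config$min_volume_fl,
                           min_px = config$min_px)
    clamped <- clamped + sum(vapply(cells, `[[`, 0, "n_clamped"))
    rec <- analyze_cells(cells)
    rec$frame <- rep(f, nrow(rec))
    all_records[[f]] <- rec
    if (f == 1L) first <- list(phase = corr, labels = labels)
  }
  records <- do.call(rbind, all_records)
  if (nrow(records)) {
    records$id <- seq_len(nrow(records))
  }
  stats <- if (nrow(records)) population_stats(records) else NULL
  manifest <- list(
    stage = "analyze", n_frames = length(frames),
    carrier_u = carrier[1], carrier_v = carrier[2],
    filter_radius_cpp = fr, tau_rad = config$tau_rad,
    connectivity = config$connectivity,
    min_volume_fl = config$min_volume_fl,
    n_objects_labelled = n_before_filter,
    n_cells_kept = nrow(records),
    n_residues = warn_residues, n_clamped_px = clamped,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(cells = file.path(out_dir, "cells.csv"),
                  summary = file.path(out_dir, "summary.txt"),
                  phase = file.path(out_dir, "phase.tif"),
                  labels = file.path(out_dir, "labels.tif"),
                  manifest = file.path(out_dir, "manifest_analyze.txt"))
    write_cell_csv(records, paths$cells)
    if (!is.null(stats)) write_summary(stats, paths$summary)
    write_phase_tiff(first$phase, paths$phase)
    write_label_tiff(first$labels, paths$labels)
    manifest <- c(manifest, list(out_cells = paths$cells,
                                 out_summary = paths$summary))
    write_manifest(manifest, paths$manifest)
  }
  invisible(list(cells = records, stats = stats,
                 phase = first$phase, labels = first$labels,
                 manifest = manifest))
}

#' Write per-cell records as CSV with unit header comments
#'
#' @param records Cell-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_csv <- function(records, path) {
  con <- file(path, "w")
  writeLines(c(
    "# per-cell morphological records",
    "# units: areas um^2, volumes fL, lengths/diameters/thickness um,",
    "#        integrated density rad*px, centroids px (1-based)"), con)
  close(con)
  suppressWarnings(
    write.table(records, path, append = TRUE, sep = ",",
                row.names = FALSE, qmethod = "double"))
  invisible(path)
}

#' Read a per-cell CSV written by [write_cell_csv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_cell_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Compare pipeline output with phantom ground truth
#'
#' Matches measured cells to ground-truth cells by nearest centroid
#' (greedy, closest pairs first, gated at `match_radius_um`) and tabulates
#' per-cell volume and surface-area recovery errors.
#'
#' @param cells Cell-record data frame or path to a cells CSV.
#' @param truth Ground-truth data frame or path to a truth CSV.
#' @param pixel_pitch_um Pixel size used to convert measured centroids to
#'   micrometres.
#' @param match_radius_um Maximum centroid distance for a match (um).
#' @param out_path Optional CSV path for the per-cell error table.
#' @return An object of class `recovery_report`: `matches` data frame,
#'   counts, match rate and median absolute relative errors.
#' @export
recover_run <- function(cells, truth, pixel_pitch_um = 0.16,
                        match_radius_um = 3, out_path = NULL) {
  if (is.character(cells)) cells <- read_cell_csv(cells)
  if (is.character(truth)) truth <- read.csv(truth)
  truth <- truth[truth$true_volume_fl >= 20, , drop = FALSE]  # RBC truth only
  n_t <- nrow(truth); n_m <- nrow(cells)
  matches <- data.frame()
  if (n_t && n_m) {
    mx <- (cells$centroid_x_px - 1) * pixel_pitch_um
    my <- (cells$centroid_y_px - 1) * pixel_pitch_um
    D <- sqrt(outer(truth$center_x_um, mx, "-")^2 +
              outer(truth$center_y_um, my, "-")^2)
    repeat {
      k <- which.min(D)
      if (!length(k) || !is.finite(D[k]) || D[k] > match_radius_um) break
      ti <- ((k - 1) %% n_t) + 1
      mi <- ((k - 1) %/% n_t) + 1
      matches <- rbind(matches, data.frame(
        truth_id = truth$id[ti], cell_id = cells$id[mi],
        dist_um = D[k],
        true_volume_fl = truth$true_volume_fl[ti],
        volume_fl = cells$volume_fl[mi],
        volume_rel_err = (cells$volume_fl[mi] - truth$true_volume_fl[ti]) /
          truth$true_volume_fl[ti],
        true_surface_area_um2 = truth$true_surface_area_um2[ti],
        surface_area_um2 = cells$surface_area_um2[mi],
        sa_rel_err = (cells$surface_area_um2[mi] -
                        truth$true_surface_area_um2[ti]) /
          truth$true_surface_area_um2[ti]))
      D[ti, ] <- Inf
      D[, mi] <- Inf
    }
  }
  rep <- structure(list(
    matches = matches,
    n_truth = n_t, n_measured = n_m, n_matched = nrow(matches),
    match_rate = if (n_t) nrow(matches) / n_t else NA_real_,
    median_abs_volume_rel_err =
      if (nrow(matches)) median(abs(matches$volume_rel_err)) else NA_real_,
    median_abs_sa_rel_err =
      if (nrow(matches)) median(abs(matches$sa_rel_err)) else NA_real_),
    class = "recovery_report")
  if (!is.null(out_path)) write.csv(matches, out_path, row.names = FALSE)
  rep
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> %d/%d truth cells matched (%.1f%%), %d measured\n",
    x$n_matched, x$n_truth, 100 * x$match_rate, x$n_measured))
  if (x$n_matched)
    cat(sprintf(
      "  median |rel err|: volume %.2f%%, surface area %.2f%%\n",
      100 * x$median_abs_volume_rel_err, 100 * x$median_abs_sa_rel_err))
  invisible(x)
}
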