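#' Background ROI centres in cell-free areas
#'
#' Samples ROI centres that keep a clearance from every cell (cell ROI
#' radius plus the medium annulus) and from the field edge, mirroring the
#' empty-area background ROIs drawn around the experimental images.
#'
#' @param field a [generate_cell_field()] result.
#' @param n number of background ROIs.
#' @param diameter_um ROI diameter, um.
#' @param clearance_um minimum distance from any cell centre; default is
#'   the ROI radius plus three cell radii (the halo outer edge).
#' @param seed optional integer seed.
#' @return an `n x 2` matrix of centres (um).
#' @export
background_rois <- function(field, n, diameter_um = 90,
                            clearance_um = NULL, seed = NULL) {
  stopifnot(inherits(field, "cell_field"))
  set_seed_if(seed)
  r <- diameter_um / 2
  clear <- clearance_um %||%
    (r + 3 * max(c(field$cells$radius_um, 20)))
  xr <- c(-field$fov_um[1] / 2 + r, field$fov_um[1] / 2 - r)
  yr <- c(-field$fov_um[2] / 2 + r, field$fov_um[2] / 2 - r)
  out <- matrix(NA_real_, nrow = n, ncol = 2,
                dimnames = list(NULL, c("x_um", "y_um")))
  got <- 0L; tries <- 0L
  while (got < n) {
    if (tries > 20000L) {
      stop(errorCondition("could not place background ROIs clear of cells",
                          class = c("rlmsim_placement_failure", "error")))
    }
    tries <- tries + 1L
    px <- stats::runif(1, xr[1], xr[2])
    py <- stats::runif(1, yr[1], yr[2])
    ok <- nrow(field$cells) == 0 ||
      all((field$cells$x_um - px)^2 + (field$cells$y_um - py)^2 >= clear^2)
    if (ok && got > 0L) {
      ok <- all((out[seq_len(got), 1] - px)^2 +
                  (out[seq_len(got), 2] - py)^2 >= diameter_um^2)
    }
    if (ok) {
      got <- got + 1L
      out[got, ] <- c(px, py)
    }
  }
  out
}

#' Quantify a simulated single-vs-dual experiment
#'
#' Reconstructs every acquisition of a simulated experiment, counts events
#' in 90-um ROIs around the true cell centres (background-corrected with
#' equal-sized empty-area ROIs), regresses per-cell dual counts on single
#' counts, estimates the decay-corrected sensitivity ratio from the ROI
#' totals, and builds the efflux difference image.
#'
#' @param experiment an [simulate_experiment()] result containing one
#'   `"single"` and one `"double"` acquisition.
#' @param k_sigma,min_pixels reconstruction parameters.
#' @param roi_diameter_um per-cell ROI diameter, um.
#' @param n_background number of background ROIs (default: one per cell).
#' @param decay_correct logical; decay-correct the dual counts to the
#'   single acquisition time before the regression.
#' @param seed seed for background ROI placement.
#' @return list with `roi` (per-cell table), `regression`
#'   ([linear_regression()] of dual on single corrected counts),
#'   `sensitivity` ([sensitivity_ratio()] of the ROI totals), `difference`
#'   (efflux difference matrix), `images` (per-configuration
#'   [event_image()]s), `events` (reconstructed event tables) and
#'   `summary` (mean/sd per configuration).
#' @export
quantify_experiment <- function(experiment, k_sigma = 5, min_pixels = 2,
                                roi_diameter_um = 90, n_background = NULL,
                                decay_correct = TRUE, seed = 1) {
  stopifnot(inherits(experiment, "rlm_experiment"))
  cfgs <- vapply(experiment$acquisitions, `[[`, "", "configuration")
  if (!all(c("single", "double") %in% cfgs)) {
    stop_invalid("experiment must contain a single and a double acquisition")
  }
  i_s <- which(cfgs == "single")[1]
  i_d <- which(cfgs == "double")[1]
  bg <- estimate_background(experiment$dark)
  rec <- lapply(experiment$acquisitions[c(i_s, i_d)], function(a) {
    reconstruct(a$frames, bg, k_sigma = k_sigma, min_pixels = min_pixels)
  })
  names(rec) <- c("single", "double")
  field <- experiment$field_initial
  cells <- field$cells
  n_bg <- n_background %||% max(nrow(cells), 10L)
  bg_centers <- background_rois(field, n_bg, diameter_um = roi_diameter_um,
                                seed = derive_seed(seed, 7))
  centers <- cbind(cells$x_um, cells$y_um)
  roi_s <- roi_counts(rec$single$image, centers, roi_diameter_um, bg_centers)
  roi_d <- roi_counts(rec$double$image, centers, roi_diameter_um, bg_centers)
  cell_s <- roi_s[roi_s$label == "cell", ]
  cell_d <- roi_d[roi_d$label == "cell", ]
  delta_t <- experiment$acquisitions[[i_d]]$start_min -
    experiment$acquisitions[[i_s]]$start_min
  half_life <- experiment$params$half_life_min
  corr <- if (decay_correct) decay_correction_factor(delta_t, half_life) else 1
  roi <- data.frame(cell = cells$cell, x_um = cells$x_um, y_um = cells$y_um,
                    single = cell_s$corrected,
                    double = cell_d$corrected,
                    double_corrected = cell_d$corrected * corr)
  reg <- linear_regression(roi$single, roi$double_corrected)
  sens <- sensitivity_ratio(max(sum(cell_d$corrected), 0),
                            max(sum(cell_s$corrected), 1e-9),
                            delta_t_min = delta_t,
                            half_life_min = half_life)
  diff_img <- efflux_difference_image(rec$double$image, rec$single$image,
                                      delta_t_min = delta_t,
                                      half_life_min = half_life)
  list(roi = roi, regression = reg, sensitivity = sens,
       difference = diff_img,
       images = list(single = rec$single$image, double = rec$double$image),
       events = list(single = rec$single$events, double = rec$double$events),
       background_centers = bg_centers,
       summary = list(
         mean_single = mean(roi$single), sd_single = stats::sd(roi$single),
         mean_double = mean(roi$double_corrected),
         sd_double = stats::sd(roi$double_corrected),
         delta_t_min = delta_t, decay_correct = decay_correct))
}

#' Mean difference-image signal at cells and in their annuli
#'
#' Summarises an efflux difference image over the ground-truth geometry:
#' mean pixel value inside the cell footprints and inside the surrounding
#' medium annuli. With efflux between the acquisitions the cell mean is
#' negative (lost activity) and the annulus mean positive (received
#' activity).
#'
#' @param difference signed matrix from [efflux_difference_image()].
#' @param field the ground-truth [generate_cell_field()].
#' @param pixel_pitch pitch of the difference image, um.
#' @return list with `cell_mean` and `annulus_mean`.
#' @export
difference_signature <- function(difference, field, pixel_pitch) {
  stopifnot(is.matrix(difference), inherits(field, "cell_field"))
  ctr <- pixel_centers(nrow(difference), ncol(difference), pixel_pitch)
  xx <- rep(ctr$x, each = nrow(difference))
  yy <- rep(ctr$y, times = ncol(difference))
  in_cell <- rep(FALSE, length(xx))
  in_halo <- rep(FALSE, length(xx))
  for (i in seq_len(nrow(field$cells))) {
    d2 <- (xx - field$cells$x_um[i])^2 + (yy - field$cells$y_um[i])^2
    in_cell <- in_cell | d2 <= field$cells$radius_um[i]^2
    in_halo <- in_halo |
      (d2 > field$halos$inner_um[i]^2 & d2 <= field$halos$outer_um[i]^2)
  }
  list(cell_mean = mean(difference[in_cell]),
       annulus_mean = mean(difference[in_halo]))
}

#' Run the full synthetic pipeline
#'
#' End-to-end driver: generates a cell field from a scenario
#' ([rlm_scenario()] or an equivalent parameter list), simulates the
#' single-then-dual acquisition pair, reconstructs, quantifies, and
#' returns a report. With `outdir` set, the report (JSON), the per-cell
#' ROI table (CSV), reconstructed event lists (CSV) and event images
#' (TIFF) are also written to disk.
#'
#' @param scenario parameter list from [rlm_scenario()] (or a config read
#'   by [read_pipeline_config()]).
#' @param seed master seed; all stages derive sub-seeds from it.
#' @param outdir optional output directory.
#' @param decay_correct decay-correct dual counts in the regression.
#' @param keep_frames keep the raw frame arrays in the returned
#'   experiment (hundreds of MB for full-scale runs; default FALSE keeps
#'   only images, events and the truth ledger).
#' @return list with `report` (scalar summaries), `quant` (full
#'   [quantify_experiment()] output), `experiment` and `field`.
#' @export
run_pipeline <- function(scenario = rlm_scenario(), seed = 1,
                         outdir = NULL, decay_correct = TRUE,
                         keep_frames = FALSE) {
  sc <- scenario
  stack <- scintillator_stack(slab_thickness = sc$slab_thickness_um,
                              gap_bottom = sc$gap_um, gap_top = sc$gap_um,
                              light_yield = sc$light_yield %||% 0.3)
  optics <- optical_system(focal_plane_z = sc$focal_plane_z %||% 0)
  camera <- camera_model(exposure_s = sc$exposure_s)
  field <- generate_cell_field(
    n_cells = sc$n_cells, fov_um = sc$fov_um, mean_n0 = sc$mean_n0,
    dispersion = sc$dispersion, efflux_rate = sc$efflux_rate,
    cell_radius = sc$cell_radius, min_separation = sc$min_separation,
    seed = derive_seed(seed, 1))
  plan <- experiment_plan(configurations = c("single", "double"),
                          start_min = c(0, sc$delta_t_min),
                          n_frames = sc$n_frames,
                          exposure_s = sc$exposure_s,
                          dark_frames = sc$dark_frames)
  experiment <- simulate_experiment(field, plan, stack, optics, camera,
                                    seed = derive_seed(seed, 2),
                                    backscatter_prob =
                                      sc$backscatter_prob %||% BACKSCATTER_PROB)
  if (nrow(field$cells) == 0) {
    report <- list(scenario = sc$scenario, seed = seed, n_cells = 0,
                   empty_field = TRUE)
    if (!is.null(outdir)) write_report(report, file.path(outdir, "report.json"))
    return(list(report = report, quant = NULL, experiment = experiment,
                field = field))
  }
  quant <- quantify_experiment(experiment, k_sigma = sc$k_sigma,
                               min_pixels = sc$min_pixels,
                               roi_diameter_um = sc$roi_diameter_um,
                               decay_correct = decay_correct,
                               seed = derive_seed(seed, 3))
  if (!keep_frames) {
    for (k in seq_along(experiment$acquisitions)) {
      experiment$acquisitions[[k]]$frames$frames <- NULL
    }
    experiment$dark$frames <- NULL
  }
  sig <- difference_signature(quant$difference, field,
                              quant$images$single$pixel_pitch)
  ci <- stats::confint(quant$regression$fit)["x", ]
  report <- list(
    scenario = sc$scenario, seed = seed, n_cells = sc$n_cells,
    empty_field = FALSE,
    efflux_rate = sc$efflux_rate,
    mean_single = quant$summary$mean_single,
    sd_single = quant$summary$sd_single,
    mean_double_corrected = quant$summary$mean_double,
    sd_double_corrected = quant$summary$sd_double,
    slope = quant$regression$slope,
    slope_se = quant$regression$slope_se,
    slope_ci95 = unname(ci),
    intercept = quant$regression$intercept,
    r_squared = quant$regression$r_squared,
    sensitivity_ratio = quant$sensitivity$ratio,
    sensitivity_ci = c(quant$sensitivity$ci_low, quant$sensitivity$ci_high),
    decay_correction_factor = quant$sensitivity$correction_factor,
    difference_cell_mean = sig$cell_mean,
    difference_annulus_mean = sig$annulus_mean)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(outdir, "report.json"))
    utils::write.csv(quant$roi, file.path(outdir, "roi_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(quant$events$single,
                     file.path(outdir, "events_single.csv"), row.names = FALSE)
    utils::write.csv(quant$events$double,
                     file.path(outdir, "events_double.csv"), row.names = FALSE)
    write_event_image(quant$images$single,
                      file.path(outdir, "events_single.tif"))
    write_event_image(quant$images$double,
                      file.path(outdir, "events_double.tif"))
  }
  list(report = report, quant = quant, experiment = experiment,
       field = field)
}

#' Point-source spatial-resolution assay
#'
#' Simulates an 18F point source on the source plane, images the same
#' emission sample in the single (bottom-slab events only) and dual
#' (both slabs) configurations through the full optics + camera +
#' reconstruction chain, and fits a circularly symmetric 2-D Gaussian to
#' each reconstructed event image. Because the flash rate of a ~1 Bq
#' source is far below one per frame, each decay is rendered in its own
#' frame.
#'
#' @param n_decays decays per replicate.
#' @param seeds integer vector of replicate seeds.
#' @param stack dual [scintillator_stack()].
#' @param optics,camera optical and camera models.
#' @param fov_um field of view, um.
#' @param k_sigma,min_pixels reconstruction parameters.
#' @param dark_frames dark frames for the background model.
#' @return data frame with one row per seed: `seed`, `fwhm_single_um`,
#'   `fwhm_double_um`, `n_single`, `n_double`.
#' @export
resolution_assay <- function(n_decays = 2000, seeds = 1:10,
                             stack = scintillator_stack(),
                             optics = optical_system(),
                             camera = camera_model(),
                             fov_um = c(850, 850), k_sigma = 5,
                             min_pixels = 2, dark_frames = 200,
                             backscatter_prob = BACKSCATTER_PROB) {
  stopifnot(is_dual(stack))
  dof <- depth_of_field(optics, camera)
  out <- lapply(seeds, function(s) {
    set.seed(derive_seed(s, 41))
    dirs <- emit_direction(n_decays)
    energies <- sample_beta_spectrum(n_decays)
    ## paired transports: same decays and bounce draws through each
    ## detector geometry
    tr_seed <- derive_seed(s, 44)
    tr_d <- transport_batch(origins = matrix(0, n_decays, 3),
                            directions = dirs, energies = energies,
                            stack = stack, step_um = 4, focus_depth = dof,
                            seed = tr_seed,
                            backscatter_prob = backscatter_prob)
    tr_s <- transport_batch(origins = matrix(0, n_decays, 3),
                            directions = dirs, energies = energies,
                            stack = single_configuration(stack),
                            step_um = 4, focus_depth = dof, seed = tr_seed,
                            backscatter_prob = backscatter_prob)
    if (nrow(tr_d$deposits) == 0L) {
      return(data.frame(seed = s, fwhm_single_um = NA, fwhm_double_um = NA,
                        n_single = 0L, n_double = 0L))
    }
    dark <- make_dark_stack(camera, shape = round(fov_um /
                              pixel_pitch_object(camera, optics)),
                            n_frames = dark_frames,
                            seed = derive_seed(s, 42),
                            pixel_pitch = pixel_pitch_object(camera, optics))
    bg <- estimate_background(dark)
    render_events <- function(d, cfg) {
      ids <- unique(d$event_id)
      d$time_s <- (match(d$event_id, ids) - 0.5) * camera$exposure_s
      fr <- render_frames(d, stack, optics, camera, fov_um = fov_um,
                          n_frames = length(ids),
                          seed = derive_seed(s, 43L + cfg))
      reconstruct(fr, bg, k_sigma = k_sigma, min_pixels = min_pixels)
    }
    rec_d <- render_events(tr_d$deposits, 0L)
    rec_s <- render_events(tr_s$deposits, 1L)
    fit_s <- fit_gaussian2d(rec_s$image)
    fit_d <- fit_gaussian2d(rec_d$image)
    data.frame(seed = s, fwhm_single_um = fit_s$fwhm,
               fwhm_double_um = fit_d$fwhm,
               n_single = sum(rec_s$image$counts),
               n_double = sum(rec_d$image$counts))
  })
  do.call(rbind, out)
}
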