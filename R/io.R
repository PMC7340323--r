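#' Write / read a frame stack as multi-page TIFF
#'
#' Frames are stored as 16-bit unsigned grayscale pages; acquisition
#' metadata (pixel pitch, exposure, start time, camera/optics snapshot)
#' goes to a JSON sidecar `<path>.json`. The round trip is lossless for
#' values in `[0, 65535]`.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    stack$frames[, , i] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(pixel_pitch = stack$pixel_pitch,
               exposure_s = stack$exposure_s,
               t_start_s = stack$t_start_s,
               n_frames = n_frames(stack),
               metadata = stack$metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frame_stack
#' @param strict error (rather than warn) when the sidecar is missing.
#' @export
read_frame_stack <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("no such TIFF: ", path),
                        class = c("rlmsim_format_error", "error")))
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
      stop(errorCondition(paste0("malformed TIFF '", path, "': ",
                                 conditionMessage(e)),
                          class = c("rlmsim_format_error", "error")))
    })
  if (is.matrix(pages)) pages <- list(pages)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop(errorCondition(paste0("TIFF pages of '", path,
                               "' have inconsistent shapes"),
                        class = c("rlmsim_format_error", "error")))
  }
  a <- array(0L, dim = c(shapes[1, 1], shapes[2, 1], length(pages)))
  for (i in seq_along(pages)) a[, , i] <- as.integer(pages[[i]])
  side <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else if (strict) {
    stop(errorCondition(paste0("missing metadata sidecar: ", side),
                        class = c("rlmsim_format_error", "error")))
  }
  frame_stack(a,
              pixel_pitch = meta$pixel_pitch %||% 1,
              exposure_s = meta$exposure_s %||% 1,
              t_start_s = meta$t_start_s %||% 0,
              metadata = meta$metadata %||% list())
}

#' Write / read an event image as 16-bit TIFF
#'
#' @param image an [event_image()].
#' @param path output TIFF path (pitch stored in a JSON sidecar).
#' @return `path` (write) or an [event_image()] (read).
#' @export
write_event_image <- function(image, path) {
  stopifnot(inherits(image, "event_image"))
  tiff::writeTIFF(pmin(image$counts, 65535) / 65535, path,
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(pixel_pitch = image$pixel_pitch),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_image
#' @export
read_event_image <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  side <- paste0(path, ".json")
  pitch <- if (file.exists(side)) {
    jsonlite::read_json(side)$pixel_pitch
  } else 1
  event_image(matrix(as.integer(m), nrow = nrow(m)), pitch)
}

#' Write reconstructed events as CSV
#'
#' Stable column layout: `frame`, `x_um`, `y_um`, `signal`, `n_pixels`.
#'
#' @param events event data frame from [reconstruct()].
#' @param path output CSV path.
#' @export
write_event_csv <- function(events, path) {
  out <- data.frame(frame = events$frame_index, x_um = events$x_um,
                    y_um = events$y_um, signal = events$signal,
                    n_pixels = events$n_pixels)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

## allowed configuration schema: section -> known keys
config_schema <- function() {
  list(
    geometry = c("slab_thickness_um", "gap_um", "lateral_extent_um",
                 "light_yield"),
    optics = c("wavelength_nm", "refractive_index", "numerical_aperture",
               "magnification", "focal_plane_z"),
    camera = c("pixel_size_um", "binning", "em_gain", "exposure_s",
               "read_noise_e", "dark_rate_e_s", "quantum_efficiency",
               "sensitivity_e_adu"),
    reconstruction = c("k_sigma", "min_pixels"),
    quantification = c("roi_diameter_um", "decay_correct"),
    scenario = c("name", "n_cells", "fov_um", "n_frames", "dark_frames",
                 "mean_n0", "dispersion", "efflux_rate", "cell_radius",
                 "min_separation", "delta_t_min"),
    seed = NULL, version = NULL)
}

#' Read and validate a pipeline configuration (YAML)
#'
#' Configurations have sections `geometry`, `optics`, `camera`,
#' `reconstruction`, `quantification`, `scenario` plus scalar `seed` and
#' `version`; unknown sections or keys are rejected so that typos fail
#' loudly rather than silently falling back to defaults.
#'
#' @param path YAML file path.
#' @return validated named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config configuration list to validate.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stop_invalid("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in intersect(names(config), names(schema))) {
    keys <- schema[[sec]]
    if (is.null(keys)) next
    bad <- setdiff(names(config[[sec]]), keys)
    if (length(bad)) {
      stop_invalid("unknown key(s) in config section '", sec, "': ",
                   paste(bad, collapse = ", "))
    }
  }
  config
}

#' Merge a validated config onto a scenario parameter list
#'
#' @param config validated config list.
#' @return scenario list accepted by [run_pipeline()].
#' @export
config_to_scenario <- function(config) {
  sc <- rlm_scenario(config$scenario$name %||% "scaled")
  for (k in setdiff(names(config$scenario), "name")) {
    sc[[k]] <- config$scenario[[k]]
  }
  for (k in names(config$reconstruction %||% list())) {
    sc[[k]] <- config$reconstruction[[k]]
  }
  if (!is.null(config$quantification$roi_diameter_um)) {
    sc$roi_diameter_um <- config$quantification$roi_diameter_um
  }
  if (!is.null(config$geometry$gap_um)) sc$gap_um <- config$geometry$gap_um
  if (!is.null(config$geometry$slab_thickness_um)) {
    sc$slab_thickness_um <- config$geometry$slab_thickness_um
  }
  sc
}

#' Write a pipeline report as JSON
#'
#' @param report named list of results.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
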