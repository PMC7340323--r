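#' Frame stack container
#'
#' An ordered sequence of equally shaped camera frames with acquisition
#' metadata. Frames are stored as an integer array `[ny, nx, n_frames]` in
#' camera output units (ADU). Object-space coordinates are centred on the
#' optical axis: pixel `(i, j)` (row, column, 1-based) has its centre at
#' `x = -W/2 + (j - 0.5) * pitch`, `y = -H/2 + (i - 0.5) * pitch`, where
#' `W = nx * pitch`, `H = ny * pitch`.
#'
#' @param frames integer array `[ny, nx, n_frames]` (a matrix is treated as
#'   one frame).
#' @param pixel_pitch object-space pixel pitch, um.
#' @param exposure_s frame exposure, s.
#' @param t_start_s acquisition start time, s.
#' @param metadata list of camera/optics settings carried along for
#'   provenance.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_pitch, exposure_s, t_start_s = 0,
                        metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  check_number(pixel_pitch, "pixel_pitch", lower = 1e-12)
  check_number(exposure_s, "exposure_s", lower = 1e-12)
  if (any(frames < 0, na.rm = TRUE)) stop_invalid("frames must be non-negative")
  structure(
    list(frames = frames, pixel_pitch = pixel_pitch,
         exposure_s = exposure_s, t_start_s = t_start_s,
         timestamps = t_start_s + (seq_len(dim(frames)[3]) - 1) * exposure_s,
         metadata = metadata),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%.2f um/px), %g ms exposure\n",
              d[3], d[1], d[2], x$pixel_pitch, 1000 * x$exposure_s))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

## pixel-centre coordinate vectors of a ny x nx image with given pitch
pixel_centers <- function(ny, nx, pitch) {
  list(x = -nx * pitch / 2 + (seq_len(nx) - 0.5) * pitch,
       y = -ny * pitch / 2 + (seq_len(ny) - 0.5) * pitch)
}

## EMCCD output model: Poisson photoelectrons -> Gamma EM amplification ->
## Gaussian read noise -> ADU quantisation, clipped to 16 bits.
## Processed in chunks to bound transient memory on long stacks.
apply_camera_noise <- function(lam_pe, camera, seed = NULL) {
  set_seed_if(seed)
  dims <- dim(lam_pe)
  n <- length(lam_pe)
  adu <- integer(n)
  chunk <- 8L * 1024L * 1024L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    npe <- stats::rpois(length(idx), as.numeric(lam_pe[idx]))
    out <- numeric(length(idx))
    pos <- npe > 0L
    if (any(pos)) {
      out[pos] <- stats::rgamma(sum(pos), shape = npe[pos],
                                scale = camera$em_gain)
    }
    if (camera$read_noise_e > 0) {
      out <- out + stats::rnorm(length(idx), 0, camera$read_noise_e)
    }
    out <- round(out / camera$sensitivity_e_adu) + camera$bias_adu
    adu[idx] <- as.integer(pmin(pmax(out, 0), 65535))
  }
  dim(adu) <- dims
  adu
}

#' Render energy deposits into EMCCD frames
#'
#' Each energy deposit contributes `light_yield * energy_kev *
#' quantum_efficiency` expected photoelectrons, spread over pixels by a
#' circular Gaussian PSF whose width grows with the deposit's distance from
#' the focal plane ([psf_sigma()]); out-of-focus deposits are broadened but
#' not attenuated, so expected light is conserved. Per-pixel expected
#' photoelectrons (signal plus dark current) are then Poisson-sampled,
#' EM-amplified and digitised by [apply_camera_noise()]. A deposit is
#' assigned to the single frame whose exposure window contains its time
#' (no dead time); deposits outside `[t_start_s, t_start_s + n_frames *
#' exposure)` or laterally outside the field of view are dropped.
#'
#' @param deposits data frame with columns `x`, `y`, `z` (um),
#'   `energy_kev`, `time_s` (as produced by [transport_batch()]); may have
#'   zero rows.
#' @param stack a [scintillator_stack()] (for the light yield).
#' @param optics an [optical_system()].
#' @param camera a [camera_model()].
#' @param fov_um field of view `c(width, height)` in um; rounded to a whole
#'   number of pixels (must be >= 1 pixel).
#' @param n_frames number of frames to render (>= 1).
#' @param t_start_s acquisition start time, s.
#' @param seed optional integer seed.
#' @return a [frame_stack()].
#' @export
render_frames <- function(deposits, stack, optics, camera, fov_um,
                          n_frames, t_start_s = 0, seed = NULL) {
  stopifnot(inherits(stack, "scintillator_stack"),
            inherits(optics, "optical_system"),
            inherits(camera, "camera_model"))
  check_number(n_frames, "n_frames", lower = 1)
  n_frames <- as.integer(n_frames)
  pitch <- pixel_pitch_object(camera, optics)
  nx <- round(fov_um[1] / pitch)
  ny <- round(fov_um[2] / pitch)
  if (is.na(nx) || is.na(ny) || nx < 1 || ny < 1) {
    stop_invalid("field of view smaller than one pixel")
  }
  set_seed_if(seed)
  lam <- expected_signal_array(deposits, stack, optics, camera,
                               nx = nx, ny = ny, pitch = pitch,
                               n_frames = n_frames, t_start_s = t_start_s)
  lam <- lam + camera$dark_rate_e_s * camera$exposure_s
  frames <- apply_camera_noise(lam, camera)
  frame_stack(frames, pixel_pitch = pitch, exposure_s = camera$exposure_s,
              t_start_s = t_start_s,
              metadata = list(camera = unclass(camera),
                              optics = unclass(optics),
                              light_yield = stack$light_yield))
}

## expected photoelectron array [ny, nx, n_frames] from a deposit table
expected_signal_array <- function(deposits, stack, optics, camera,
                                  nx, ny, pitch, n_frames, t_start_s) {
  lam <- array(0, dim = c(ny, nx, n_frames))
  if (is.null(deposits) || nrow(deposits) == 0L) return(lam)
  fi <- floor((deposits$time_s - t_start_s) / camera$exposure_s) + 1
  keep <- fi >= 1 & fi <= n_frames & deposits$energy_kev > 0
  if (!any(keep)) return(lam)
  d <- deposits[keep, , drop = FALSE]
  fi <- as.integer(fi[keep])
  npe <- stack$light_yield * d$energy_kev * camera$quantum_efficiency
  sig_px <- psf_sigma(optics, d$z - optics$focal_plane_z) / pitch
  ## pixel-centre grids shifted so that pixel j spans [(j-1), j] * pitch
  ux <- (d$x + nx * pitch / 2) / pitch
  uy <- (d$y + ny * pitch / 2) / pitch
  half <- pmax(2L, as.integer(ceiling(4 * sig_px)))
  for (k in seq_len(nrow(d))) {
    jx0 <- max(1L, floor(ux[k]) - half[k]); jx1 <- min(nx, floor(ux[k]) + half[k] + 1L)
    jy0 <- max(1L, floor(uy[k]) - half[k]); jy1 <- min(ny, floor(uy[k]) + half[k] + 1L)
    if (jx0 > jx1 || jy0 > jy1) next
    px <- diff(stats::pnorm(jx0:(jx1 + 1L) - 1L, mean = ux[k], sd = sig_px[k]))
    py <- diff(stats::pnorm(jy0:(jy1 + 1L) - 1L, mean = uy[k], sd = sig_px[k]))
    lam[jy0:jy1, jx0:jx1, fi[k]] <- lam[jy0:jy1, jx0:jx1, fi[k]] +
      npe[k] * (py %o% px)
  }
  lam
}

#' Simulate a dark reference stack
#'
#' Frames containing only dark current and read noise passed through the
#' EM register, matching the separate dark sequence captured for
#' background subtraction.
#'
#' @param camera a [camera_model()].
#' @param shape frame shape `c(ny, nx)` in pixels.
#' @param n_frames number of dark frames (>= 1).
#' @param seed optional integer seed.
#' @param pixel_pitch object-space pitch recorded in the stack metadata,
#'   um.
#' @return a [frame_stack()].
#' @export
make_dark_stack <- function(camera, shape, n_frames, seed = NULL,
                            pixel_pitch = NULL) {
  stopifnot(inherits(camera, "camera_model"))
  check_number(n_frames, "n_frames", lower = 1)
  n_frames <- as.integer(n_frames)
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  stopifnot(ny >= 1, nx >= 1)
  set_seed_if(seed)
  lam <- array(camera$dark_rate_e_s * camera$exposure_s,
               dim = c(ny, nx, n_frames))
  frames <- apply_camera_noise(lam, camera)
  frame_stack(frames,
              pixel_pitch = pixel_pitch %||%
                (camera$pixel_size_um * camera$binning),
              exposure_s = camera$exposure_s,
              metadata = list(camera = unclass(camera), dark = TRUE))
}
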