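#' Microscope optical model
#'
#' The reference system is a 20x / 0.75 NA objective used with a short tube
#' lens giving an effective magnification of 3.6x, imaging the 475 nm
#' emission peak of CdWO4 scintillation.
#'
#' @param wavelength_nm emission wavelength, nm.
#' @param refractive_index refractive index of the imaging medium.
#' @param numerical_aperture objective numerical aperture; must satisfy
#'   `0 < NA < 1.52 * refractive_index`.
#' @param magnification effective magnification of the system.
#' @param focal_plane_z focal plane height in object space, um (source
#'   plane at z = 0). Default 0: the mid-height of the cells, which in the
#'   dual configuration is equidistant from both slab surfaces so that the
#'   ~24.5 um depth of field covers both symmetrically.
#' @return object of class `optical_system`.
#' @examples
#' depth_of_field(optical_system(), camera_model())
#' @export
optical_system <- function(wavelength_nm = 475, refractive_index = 1,
                           numerical_aperture = 0.75, magnification = 3.6,
                           focal_plane_z = 0) {
  check_number(wavelength_nm, "wavelength_nm", lower = 1e-9)
  check_number(refractive_index, "refractive_index", lower = 1e-9)
  check_number(numerical_aperture, "numerical_aperture", lower = 1e-12,
               upper = 1.52 * refractive_index - 1e-12)
  check_number(magnification, "magnification", lower = 1e-12)
  check_number(focal_plane_z, "focal_plane_z")
  structure(list(wavelength_nm = wavelength_nm,
                 refractive_index = refractive_index,
                 numerical_aperture = numerical_aperture,
                 magnification = magnification,
                 focal_plane_z = focal_plane_z),
            class = "optical_system")
}

#' EMCCD camera model
#'
#' Parameters of the electron-multiplying CCD. The rendered pixel value is
#' `round((Gamma(shape = n_pe, scale = em_gain) + read noise) /
#' sensitivity_e_adu)` clipped to the unsigned 16-bit range, where `n_pe`
#' is the Poisson photoelectron count (signal + dark). The Gamma
#' amplification reproduces the EM register's multiplicative excess noise
#' (factor ~sqrt(2)).
#'
#' @param pixel_size_um physical pixel size, um.
#' @param binning on-chip binning factor (integer >= 1).
#' @param em_gain electron-multiplication gain (>= 1).
#' @param exposure_s frame exposure time, s.
#' @param read_noise_e read noise, electrons RMS.
#' @param dark_rate_e_s dark current, electrons per (binned) pixel per
#'   second.
#' @param quantum_efficiency detector quantum efficiency in (0, 1].
#' @param sensitivity_e_adu analog-digital conversion factor, electrons per
#'   output count (ADU).
#' @param bias_adu constant baseline offset added to every pixel (ADU).
#'   Real EMCCDs sit the signal on a bias level of order 100 counts so
#'   that read noise is not clipped by the unsigned digitiser; without it
#'   the clipped noise becomes heavy-tailed relative to its standard
#'   deviation and k-sigma thresholds lose their Gaussian calibration.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_um = 16, binning = 4, em_gain = 1060,
                         exposure_s = 0.030, read_noise_e = 25,
                         dark_rate_e_s = 0.001, quantum_efficiency = 0.9,
                         sensitivity_e_adu = 12, bias_adu = 100) {
  check_number(pixel_size_um, "pixel_size_um", lower = 1e-9)
  check_number(binning, "binning", lower = 1)
  if (binning != round(binning)) stop_invalid("binning must be an integer")
  check_number(em_gain, "em_gain", lower = 1)
  check_number(exposure_s, "exposure_s", lower = 1e-12)
  check_number(read_noise_e, "read_noise_e", lower = 0)
  check_number(dark_rate_e_s, "dark_rate_e_s", lower = 0)
  check_number(quantum_efficiency, "quantum_efficiency", lower = 1e-12,
               upper = 1)
  check_number(sensitivity_e_adu, "sensitivity_e_adu", lower = 1e-12)
  check_number(bias_adu, "bias_adu", lower = 0)
  structure(list(pixel_size_um = pixel_size_um, binning = as.integer(binning),
                 em_gain = em_gain, exposure_s = exposure_s,
                 read_noise_e = read_noise_e, dark_rate_e_s = dark_rate_e_s,
                 quantum_efficiency = quantum_efficiency,
                 sensitivity_e_adu = sensitivity_e_adu,
                 bias_adu = bias_adu),
            class = "camera_model")
}

#' Depth of field of the low-light microscope
#'
#' `d = n * lambda / NA^2 + n * b * e / (M * NA)`: the wave-optics depth of
#' focus plus the geometric term from the finite (binned) pixel size
#' referred to object space. For the reference system (475 nm, NA 0.75,
#' 16 um pixels, 4x4 binning, M = 3.6) this is ~24.5 um, which is what
#' allows the near surfaces of both scintillators (10 um apart) to be in
#' acceptable focus simultaneously.
#'
#' @param optics an [optical_system()].
#' @param camera a [camera_model()].
#' @return depth of field in um.
#' @export
depth_of_field <- function(optics, camera) {
  stopifnot(inherits(optics, "optical_system"),
            inherits(camera, "camera_model"))
  na <- optics$numerical_aperture
  if (na == 0) stop_invalid("numerical aperture must be nonzero")
  n <- optics$refractive_index
  lambda_um <- optics$wavelength_nm / 1000
  n * lambda_um / na^2 +
    n * camera$binning * camera$pixel_size_um / (optics$magnification * na)
}

#' Object-space pixel pitch
#'
#' Size of one binned camera pixel referred to object space:
#' `pixel_size * binning / magnification` (17.78 um for the defaults).
#'
#' @inheritParams depth_of_field
#' @return pitch in um.
#' @export
pixel_pitch_object <- function(camera, optics) {
  stopifnot(inherits(optics, "optical_system"),
            inherits(camera, "camera_model"))
  camera$pixel_size_um * camera$binning / optics$magnification
}

#' Defocus-dependent Gaussian PSF width
#'
#' In-focus width `sigma0 = 0.21 * lambda / NA` (Gaussian approximation of
#' the Airy core, object space), broadened with defocus `dz` as
#' `sigma(dz) = sqrt(sigma0^2 + (c * dz)^2)` with `c = NA / (2 n)`, the
#' half-slope of the geometric defocus cone.
#'
#' @param optics an [optical_system()].
#' @param dz distance from the focal plane, um (vectorised).
#' @return Gaussian sigma in object-space um.
#' @export
psf_sigma <- function(optics, dz) {
  stopifnot(inherits(optics, "optical_system"))
  na <- optics$numerical_aperture
  sigma0 <- 0.21 * (optics$wavelength_nm / 1000) / na
  cc <- na / (2 * optics$refractive_index)
  sqrt(sigma0^2 + (cc * dz)^2)
}
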