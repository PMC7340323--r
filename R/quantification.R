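#' Expected decay counts from a labelled cell
#'
#' Number of decay events expected from a cell holding `n_molecules`
#' radiotracer molecules at the reference time, observed with detection
#' sensitivity `sensitivity` over an elapsed time `t`:
#' `D = S * Y * N0 * (1 - exp(-ln2 * t / half_life))`.
#'
#' @param n_molecules molecule count at the reference time (N0 >= 0).
#' @param sensitivity detection sensitivity S in \[0, 1\].
#' @param yield_beta positron yield per decay (0.97 for 18F).
#' @param elapsed_min elapsed time t, minutes.
#' @param half_life_min radionuclide half-life, minutes.
#' @return expected number of detected decays (vectorised over any
#'   argument).
#' @export
expected_counts <- function(n_molecules, sensitivity,
                            yield_beta = F18[["yield_beta"]],
                            elapsed_min, half_life_min = F18[["half_life_min"]]) {
  args <- list(n_molecules, sensitivity, yield_beta, elapsed_min,
               half_life_min)
  if (any(vapply(args, function(a) any(!is.finite(a)) || any(a < 0),
                 logical(1)))) {
    stop_invalid("all arguments must be finite and non-negative")
  }
  sensitivity * yield_beta * n_molecules *
    (1 - exp(-log(2) * elapsed_min / half_life_min))
}

#' Half-life decay correction factor
#'
#' Multiplicative correction `exp(ln2 * delta_t / half_life)` applied to a
#' measurement acquired `delta_t` minutes after the reference measurement,
#' rescaling it to the reference time (1.14 for a 21-minute delay with the
#' 110-minute 18F half-life).
#'
#' @param delta_t_min delay between the two measurements, minutes.
#' @param half_life_min radionuclide half-life, minutes (> 0).
#' @return dimensionless correction factor (vectorised).
#' @export
decay_correction_factor <- function(delta_t_min,
                                    half_life_min = F18[["half_life_min"]]) {
  if (any(half_life_min <= 0)) stop_invalid("half_life_min must be > 0")
  exp(log(2) * delta_t_min / half_life_min)
}

#' Dual/single sensitivity ratio with decay correction
#'
#' Ratio of detected decay counts in the dual- and single-scintillator
#' acquisitions, with the later (dual) measurement rescaled by the decay
#' correction factor. The confidence interval treats both totals as
#' Poisson counts and conditions on their sum, giving a Clopper-Pearson
#' binomial interval on the dual fraction that is transformed to the ratio
#' scale (equivalent to the F-distribution ratio-of-Poissons interval).
#'
#' @param d_double detected counts with two scintillators (>= 0).
#' @param d_single detected counts with one scintillator (> 0).
#' @param delta_t_min acquisition delay of the dual measurement, minutes.
#' @param half_life_min radionuclide half-life, minutes.
#' @param conf_level confidence level for the interval.
#' @return object of class `sensitivity_estimate`: list with `ratio`,
#'   `correction_factor`, `delta_t_min`, `ci_low`, `ci_high`,
#'   `conf_level`.
#' @export
sensitivity_ratio <- function(d_double, d_single, delta_t_min = 0,
                              half_life_min = F18[["half_life_min"]],
                              conf_level = 0.95) {
  check_number(d_double, "d_double", lower = 0)
  check_number(d_single, "d_single", lower = 0)
  if (d_single == 0) {
    stop(errorCondition("sensitivity ratio undefined for zero single-scintillator counts",
                        class = c("rlmsim_undefined_ratio", "error")))
  }
  corr <- decay_correction_factor(delta_t_min, half_life_min)
  ratio <- d_double * corr / d_single
  ## conditional binomial CI on p = d_double / (d_double + d_single)
  n <- d_double + d_single
  alpha <- 1 - conf_level
  p_lo <- if (d_double == 0) 0 else stats::qbeta(alpha / 2, d_double, d_single + 1)
  p_hi <- stats::qbeta(1 - alpha / 2, d_double + 1, d_single)
  structure(list(ratio = ratio, correction_factor = corr,
                 delta_t_min = delta_t_min,
                 ci_low = corr * p_lo / (1 - p_lo),
                 ci_high = corr * p_hi / (1 - p_hi),
                 conf_level = conf_level, d_double = d_double,
                 d_single = d_single),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("S_double/S_single = %.3f (%g%% CI %.3f-%.3f), decay correction %.3f\n",
              x$ratio, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$correction_factor))
  invisible(x)
}

#' Circular-ROI event counts with background correction
#'
#' Sums the event counts of all pixels whose centres lie within a circle
#' of the given diameter around each centre, and subtracts the mean raw
#' count over a set of equal-sized background ROIs placed in areas devoid
#' of cells.
#'
#' @param image an [event_image()].
#' @param centers two-column matrix (or data frame) of ROI centres, um.
#' @param diameter_um ROI diameter, um (default 90, the per-cell ROI
#'   used for uptake quantification).
#' @param background_rois optional two-column matrix of background ROI
#'   centres (same diameter); if supplied, `corrected` is
#'   `raw - mean(background raw)`.
#' @return data frame with one row per ROI: `x_um`, `y_um`,
#'   `diameter_um`, `raw`, `corrected`, `label`.
#' @export
roi_counts <- function(image, centers, diameter_um = 90,
                       background_rois = NULL) {
  stopifnot(inherits(image, "event_image"))
  centers <- as.matrix(centers)[, 1:2, drop = FALSE]
  check_number(diameter_um, "diameter_um", lower = 1e-9)
  raw <- roi_sums(image, centers, diameter_um)
  bg_mean <- 0
  bg <- NULL
  if (!is.null(background_rois) && nrow(as.matrix(background_rois)) > 0) {
    background_rois <- as.matrix(background_rois)[, 1:2, drop = FALSE]
    bg_raw <- roi_sums(image, background_rois, diameter_um)
    bg_mean <- mean(bg_raw)
    bg <- data.frame(x_um = background_rois[, 1], y_um = background_rois[, 2],
                     diameter_um = diameter_um, raw = bg_raw,
                     corrected = bg_raw - bg_mean, label = "background")
  }
  out <- data.frame(x_um = centers[, 1], y_um = centers[, 2],
                    diameter_um = diameter_um, raw = raw,
                    corrected = raw - bg_mean, label = "cell")
  rbind(out, bg)
}

## raw pixel-centre-in-circle sums for a set of ROI centres
roi_sums <- function(image, centers, diameter_um) {
  cts <- image$counts
  ctr <- pixel_centers(nrow(cts), ncol(cts), image$pixel_pitch)
  half_w <- ncol(cts) * image$pixel_pitch / 2
  half_h <- nrow(cts) * image$pixel_pitch / 2
  r <- diameter_um / 2
  if (any(centers[, 1] < -half_w + 0 | centers[, 1] > half_w |
          centers[, 2] < -half_h | centers[, 2] > half_h)) {
    stop_invalid("ROI centre outside the image")
  }
  vapply(seq_len(nrow(centers)), function(i) {
    dx2 <- (ctr$x - centers[i, 1])^2
    dy2 <- (ctr$y - centers[i, 2])^2
    inside <- outer(dy2, dx2, `+`) <= r^2
    sum(cts[inside])
  }, numeric(1))
}

#' Circularly symmetric 2-D Gaussian fit
#'
#' Least-squares fit of `amplitude * exp(-((x - x0)^2 + (y - y0)^2) /
#' (2 sigma^2)) + offset` to an event-count image, used to measure the
#' reconstructed point-spread function of the microscope. The fit is
#' initialised from the image centroid and second moments and solved with
#' the Levenberg-Marquardt algorithm.
#'
#' @param image an [event_image()] (or plain matrix with `pixel_pitch`)
#'   with at least `min_counts` total counts.
#' @param pixel_pitch pitch in um when `image` is a bare matrix.
#' @param min_counts minimum total counts required for a meaningful fit.
#' @return object of class `gaussian_fit2d`: list with `center` (um),
#'   `sigma` (um), `amplitude`, `offset`, `fwhm` (um, `2 sqrt(2 ln 2)
#'   sigma`) and `convergence` info.
#' @export
fit_gaussian2d <- function(image, pixel_pitch = NULL, min_counts = 50) {
  if (inherits(image, "event_image")) {
    cts <- image$counts
    pitch <- image$pixel_pitch
  } else {
    stopifnot(is.matrix(image), !is.null(pixel_pitch))
    cts <- image
    pitch <- pixel_pitch
  }
  if (sum(cts) < min_counts) {
    stop_invalid("image has fewer than ", min_counts, " counts")
  }
  ctr <- pixel_centers(nrow(cts), ncol(cts), pitch)
  xx <- rep(ctr$x, each = nrow(cts))
  yy <- rep(ctr$y, times = ncol(cts))
  z <- as.numeric(cts)
  off0 <- stats::median(z)
  w0 <- pmax(z - off0, 0)
  if (sum(w0) == 0) w0 <- rep(1, length(z))
  x0 <- sum(xx * w0) / sum(w0)
  y0 <- sum(yy * w0) / sum(w0)
  s0 <- sqrt(sum(((xx - x0)^2 + (yy - y0)^2) * w0) / (2 * sum(w0)))
  s0 <- min(max(s0, 0.5 * pitch), ncol(cts) * pitch / 2)
  a0 <- max(z) - off0
  resid_fn <- function(p) {
    mu <- p[3] * exp(-((xx - p[1])^2 + (yy - p[2])^2) / (2 * p[4]^2)) + p[5]
    z - mu
  }
  fit <- minpack.lm::nls.lm(
    par = c(x0, y0, max(a0, 1e-6), s0, off0), fn = resid_fn,
    lower = c(min(ctr$x), min(ctr$y), 0, 0.1 * pitch, -Inf),
    upper = c(max(ctr$x), max(ctr$y), Inf, ncol(cts) * pitch, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info < 1 || fit$info > 4) {
    stop(errorCondition(
      paste0("2-D Gaussian fit failed to converge: ", fit$message),
      class = c("rlmsim_fit_failure", "error")))
  }
  p <- fit$par
  structure(list(center = c(x = p[1], y = p[2]), sigma = p[4],
                 amplitude = p[3], offset = p[5],
                 fwhm = 2 * sqrt(2 * log(2)) * p[4],
                 deviance = fit$deviance, info = fit$info),
            class = "gaussian_fit2d")
}

#' @export
print.gaussian_fit2d <- function(x, ...) {
  cat(sprintf("<gaussian_fit2d> centre (%.1f, %.1f) um, sigma %.2f um, FWHM %.2f um\n",
              x$center[1], x$center[2], x$sigma, x$fwhm))
  invisible(x)
}

#' Line profile across an event image
#'
#' Integrates counts perpendicular to the segment `p0 -> p1` over a band
#' of the given width, sampled along the segment at one-pixel steps
#' (pixel-centre membership in the rotated rectangle slice).
#'
#' @param image an [event_image()].
#' @param p0,p1 segment endpoints `c(x, y)` in um (inside the image).
#' @param width_um integration width perpendicular to the segment, um.
#' @param normalize divide the profile by its maximum.
#' @return data frame with `distance_um` (position along the segment) and
#'   `value`.
#' @export
line_profile <- function(image, p0, p1, width_um = 50, normalize = FALSE) {
  stopifnot(inherits(image, "event_image"))
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  seg <- p1 - p0
  len <- sqrt(sum(seg^2))
  if (len <= 0) stop_invalid("zero-length profile segment")
  u <- seg / len
  v <- c(-u[2], u[1])
  cts <- image$counts
  ctr <- pixel_centers(nrow(cts), ncol(cts), image$pixel_pitch)
  xx <- rep(ctr$x, each = nrow(cts)) - p0[1]
  yy <- rep(ctr$y, times = ncol(cts)) - p0[2]
  along <- xx * u[1] + yy * u[2]
  perp <- xx * v[1] + yy * v[2]
  step <- image$pixel_pitch
  pos <- seq(0, len, by = step)
  val <- vapply(pos, function(s) {
    sel <- along >= s - step / 2 & along < s + step / 2 &
      abs(perp) <= width_um / 2
    sum(cts[sel])
  }, numeric(1))
  if (normalize) {
    m <- max(val)
    if (m > 0) val <- val / m
  }
  data.frame(distance_um = pos, value = val)
}

#' Efflux difference image
#'
#' Compares the (later) dual-scintillator event image with the single-
#' scintillator image: the dual image is decay-corrected to the single
#' acquisition time, divided by two to match the single sensitivity, and
#' subtracted by the single image. Cells that exported tracer between the
#' acquisitions appear negative; their surroundings, which received the
#' exported tracer, appear positive.
#'
#' @param double_img,single_img [event_image()]s of matching shape and
#'   pitch.
#' @param delta_t_min delay of the dual acquisition, minutes.
#' @param half_life_min radionuclide half-life, minutes.
#' @return signed numeric matrix `(corrected double)/2 - single`.
#' @export
efflux_difference_image <- function(double_img, single_img, delta_t_min = 0,
                                    half_life_min = F18[["half_life_min"]]) {
  stopifnot(inherits(double_img, "event_image"),
            inherits(single_img, "event_image"))
  if (!all(dim(double_img$counts) == dim(single_img$counts)) ||
      abs(double_img$pixel_pitch - single_img$pixel_pitch) > 1e-9) {
    stop_invalid("event images must have matching shape and pixel pitch")
  }
  corr <- decay_correction_factor(delta_t_min, half_life_min)
  double_img$counts * corr / 2 - single_img$counts
}

#' Ordinary least-squares regression
#'
#' Slope, intercept and coefficient of determination of `y ~ x`, as used
#' to compare per-cell dual- and single-scintillator counts.
#'
#' @param x,y numeric vectors of equal length (>= 3 points); `x` must not
#'   be constant.
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `slope_se`, `n` and the underlying `lm`
#'   fit.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_invalid("need at least 3 paired points")
  }
  if (stats::sd(x) == 0) stop_invalid("x is degenerate (zero variance)")
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  r2 <- s$r.squared
  # constant y: slope and explained variance are identically zero
  if (!is.finite(r2) || stats::sd(y) == 0) r2 <- 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 slope_se = s$coefficients[2, 2],
                 n = length(x), fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.3f x + %.3f (r^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
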