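#' Fluorine-18 physical constants
#'
#' Positron endpoint energy (keV), positron yield per decay and half-life
#' (minutes) of fluorine-18.
#' @format Named numeric vector with elements `endpoint_kev` (633.5),
#'   `yield_beta` (0.97) and `half_life_min` (110).
#' @export
F18 <- c(endpoint_kev = 633.5, yield_beta = 0.97, half_life_min = 110)

#' Radioactive point/extended source model
#'
#' @param activity_bq decay rate at the reference time, becquerel.
#' @param yield_beta fraction of decays emitting a positron (0.97 for 18F).
#' @param half_life_min radionuclide half-life in minutes (~110 for 18F).
#' @return object of class `source_model`.
#' @examples
#' src <- source_model(activity_bq = 1)
#' @export
source_model <- function(activity_bq = 1, yield_beta = F18[["yield_beta"]],
                         half_life_min = F18[["half_life_min"]]) {
  check_number(activity_bq, "activity_bq", lower = 0)
  check_number(yield_beta, "yield_beta", lower = 1e-12, upper = 1)
  check_number(half_life_min, "half_life_min", lower = 1e-12)
  structure(list(activity_bq = activity_bq, yield_beta = yield_beta,
                 half_life_min = half_life_min),
            class = "source_model")
}

#' Sample radioactive decay times
#'
#' Draws decay times from a Poisson process over `[0, duration_s)`. With
#' `decay_clock = FALSE` the process is homogeneous at rate `activity_bq`;
#' with `decay_clock = TRUE` the rate itself decays with the radionuclide
#' half-life (inhomogeneous process), as appropriate for acquisitions whose
#' duration is not negligible against the half-life.
#'
#' @param source a [source_model()].
#' @param duration_s acquisition duration in seconds (> 0).
#' @param decay_clock logical; apply radioactive decay of the rate within
#'   the window.
#' @param seed optional integer seed.
#' @return sorted numeric vector of decay times (s), possibly empty.
#' @export
sample_decay_times <- function(source, duration_s, decay_clock = FALSE,
                               seed = NULL) {
  stopifnot(inherits(source, "source_model"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      is.na(duration_s) || duration_s <= 0) {
    stop_invalid("duration_s must be a single positive number")
  }
  set_seed_if(seed)
  a <- source$activity_bq
  if (a == 0) return(numeric(0))
  if (!decay_clock) {
    n <- stats::rpois(1L, a * duration_s)
    return(sort(stats::runif(n, 0, duration_s)))
  }
  lambda <- log(2) / (source$half_life_min * 60) # per second
  total <- a / lambda * (1 - exp(-lambda * duration_s)) # integrated rate
  n <- stats::rpois(1L, total)
  u <- stats::runif(n)
  t <- -log(1 - u * (1 - exp(-lambda * duration_s))) / lambda
  sort(t)
}

#' Allowed-transition beta spectrum density of fluorine-18
#'
#' Unnormalised density of the positron kinetic energy for an allowed
#' beta-plus transition with endpoint 633.5 keV:
#' `p * W * (W0 - W)^2 * F(Z, W)`, with `W` the total positron energy and
#' `p` its momentum (electron-mass units), and `F` the nonrelativistic
#' Coulomb (Fermi) function for the daughter nucleus (oxygen-18, Z = 8),
#' which suppresses low energies for positrons.
#'
#' @param energy_kev positron kinetic energies, keV (vectorised).
#' @return unnormalised density values (0 outside `(0, 633.5]`).
#' @export
f18_beta_density <- function(energy_kev) {
  e0 <- F18[["endpoint_kev"]]
  mec2 <- 510.999 # keV
  w <- (energy_kev + mec2) / mec2
  w0 <- (e0 + mec2) / mec2
  p <- sqrt(pmax(w^2 - 1, 0))
  beta <- p / w
  alpha <- 1 / 137.036
  z <- 8 # daughter 18O
  eta <- -alpha * z / pmax(beta, 1e-12) # negative for positrons
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  d <- p * w * (w0 - w)^2 * fermi
  d[energy_kev <= 0 | energy_kev > e0] <- 0
  d[!is.finite(d)] <- 0
  d
}

## inverse-CDF lookup table for the beta spectrum, built once per session
.beta_tab <- new.env(parent = emptyenv())

beta_spectrum_table <- function() {
  if (is.null(.beta_tab$grid)) {
    e <- seq(0.25, F18[["endpoint_kev"]], by = 0.25)
    d <- f18_beta_density(e)
    cdf <- cumsum(d)
    cdf <- cdf / cdf[length(cdf)]
    keep <- !duplicated(cdf)
    .beta_tab$grid <- e[keep]
    .beta_tab$cdf <- cdf[keep]
  }
  .beta_tab
}

#' Sample positron kinetic energies from the 18F beta spectrum
#'
#' Inverse-CDF sampling of [f18_beta_density()] on a 0.25 keV grid with
#' linear interpolation.
#'
#' @param n number of energies to draw (>= 0).
#' @param seed optional integer seed.
#' @return numeric vector of energies in `(0, 633.5]` keV.
#' @export
sample_beta_spectrum <- function(n, seed = NULL) {
  check_number(n, "n", lower = 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  set_seed_if(seed)
  tab <- beta_spectrum_table()
  u <- stats::runif(n)
  e <- stats::approx(tab$cdf, tab$grid, xout = u, rule = 2)$y
  pmin(pmax(e, 1e-6), F18[["endpoint_kev"]])
}

#' Sample isotropic emission directions
#'
#' Directions uniform on the unit sphere (z-component uniform on
#' `[-1, 1]`, azimuth uniform).
#'
#' @param n number of directions (>= 0).
#' @param seed optional integer seed.
#' @return an `n x 3` matrix with columns `dx, dy, dz`; rows are unit
#'   vectors.
#' @export
emit_direction <- function(n, seed = NULL) {
  check_number(n, "n", lower = 0)
  n <- as.integer(n)
  out <- matrix(numeric(0), ncol = 3,
                dimnames = list(NULL, c("dx", "dy", "dz")))
  if (n == 0L) return(out)
  set_seed_if(seed)
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(dx = r * cos(phi), dy = r * sin(phi), dz = z)
}
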