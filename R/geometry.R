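#' Scintillator stack geometry
#'
#' Describes the detector geometry of a radioluminescence microscope: one
#' slab below the cell/source plane (single configuration) or one slab on
#' each side (dual "sandwich" configuration). Coordinates are right-handed
#' with z up and the source plane at z = 0; the bottom slab occupies
#' `z in [-gap_bottom - slab_thickness, -gap_bottom]` and the top slab (if
#' present) `z in [gap_top, gap_top + slab_thickness]`. All lengths in
#' micrometres.
#'
#' The default gaps of 5 um on each side correspond to a radiolabelled cell
#' of ~10 um height sitting between the slabs, with decays originating at
#' mid-height.
#'
#' @param slab_thickness slab thickness in um (per slab).
#' @param gap_bottom distance from the source plane down to the top surface
#'   of the bottom slab, um.
#' @param gap_top distance from the source plane up to the bottom surface of
#'   the top slab, um, or `NULL` for the single-slab configuration.
#' @param lateral_extent lateral slab size in um; must comfortably exceed
#'   the imaged field of view so edge losses are negligible.
#' @param light_yield effective collected scintillation photons per keV of
#'   deposited energy, folding together the intrinsic CdWO4 yield
#'   (~15 photons/keV), light trapping in the high-index crystal and the
#'   collection solid angle of the objective. The default 0.2 photons/keV
#'   puts typical flashes in the few-to-tens of photoelectrons regime that
#'   EMCCD single-photon counting operates in.
#' @return an object of class `scintillator_stack`.
#' @examples
#' single <- scintillator_stack(gap_top = NULL)
#' dual   <- scintillator_stack(gap_top = 5)
#' is_dual(dual)
#' @export
scintillator_stack <- function(slab_thickness = 100, gap_bottom = 5,
                               gap_top = 5, lateral_extent = 20000,
                               light_yield = 0.2) {
  check_number(slab_thickness, "slab_thickness", lower = 1e-9)
  check_number(gap_bottom, "gap_bottom", lower = 0)
  if (!is.null(gap_top)) check_number(gap_top, "gap_top", lower = 0)
  check_number(lateral_extent, "lateral_extent", lower = 1e-9)
  check_number(light_yield, "light_yield", lower = 1e-12)
  structure(
    list(slab_thickness = slab_thickness, gap_bottom = gap_bottom,
         gap_top = gap_top, lateral_extent = lateral_extent,
         light_yield = light_yield),
    class = "scintillator_stack")
}

#' @rdname scintillator_stack
#' @param stack a `scintillator_stack`.
#' @export
is_dual <- function(stack) {
  stopifnot(inherits(stack, "scintillator_stack"))
  !is.null(stack$gap_top)
}

#' @export
print.scintillator_stack <- function(x, ...) {
  cat(sprintf("<scintillator_stack> %s configuration\n",
              if (is_dual(x)) "dual" else "single"))
  cat(sprintf("  slab thickness: %g um, gap below: %g um%s\n",
              x$slab_thickness, x$gap_bottom,
              if (is_dual(x)) sprintf(", gap above: %g um", x$gap_top) else ""))
  cat(sprintf("  lateral extent: %g um, light yield: %g photons/keV\n",
              x$lateral_extent, x$light_yield))
  invisible(x)
}

## z ranges of the slabs: list(bottom = c(zlo, zhi), top = c(zlo, zhi) or NULL)
slab_z_ranges <- function(stack) {
  out <- list(bottom = c(-stack$gap_bottom - stack$slab_thickness,
                         -stack$gap_bottom))
  out$top <- if (is_dual(stack)) {
    c(stack$gap_top, stack$gap_top + stack$slab_thickness)
  } else NULL
  out
}

## drop the top slab, keeping everything else (used to image the same
## emission sample in the single configuration)
single_configuration <- function(stack) {
  s <- stack
  s$gap_top <- NULL
  s
}

#' Analytic ray-slab intersection
#'
#' Path-length interval `[t_entry, t_exit]` along a ray `origin + t*dir`
#' (t >= 0) inside a horizontal slab `z in [zlo, zhi]`. Vectorised over
#' rays. Rays parallel to the slab (dir z-component 0) never enter unless
#' started inside, which is disallowed by the transport preconditions.
#'
#' @param origin_z ray origin z coordinates (um), numeric vector.
#' @param dir_z ray direction z components (unit vectors assumed).
#' @param zlo,zhi slab bounds, um.
#' @return a two-column matrix `cbind(t_entry, t_exit)`, `NA` rows where the
#'   ray misses the slab.
#' @keywords internal
ray_slab_interval <- function(origin_z, dir_z, zlo, zhi) {
  n <- length(origin_z)
  t1 <- (zlo - origin_z) / dir_z
  t2 <- (zhi - origin_z) / dir_z
  lo <- pmin(t1, t2)
  hi <- pmax(t1, t2)
  lo <- pmax(lo, 0)
  miss <- !is.finite(lo) | !is.finite(hi) | (hi <= lo) | dir_z == 0
  lo[miss] <- NA_real_
  hi[miss] <- NA_real_
  cbind(t_entry = lo, t_exit = hi)
}
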