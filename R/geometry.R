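#' Specimen geometry: elliptic or circular cylinder
#'
#' Describes the idealised nerve specimen used by the reduced-order models: a
#' straight cylinder of elliptic (or circular) cross-section with a given gauge
#' length.  Semi-axes are stored; published full axes must be halved by the
#' caller (see [eccentricity()] examples).
#'
#' @param section `"ellipse"` or `"circle"`.
#' @param a,b Semi-major and semi-minor axes in mm (`a >= b > 0`).  For a
#'   circle give `r` instead (or `a = b`).
#' @param r Radius in mm (circle only).
#' @param length Gauge length in mm (distance between clamps).
#' @param name Optional label.
#' @return An object of class `"specimen_geometry"`.
#' @examples
#' pig <- specimen_geometry("ellipse", a = 3.57 / 2, b = 2.28 / 2, length = 69)
#' section_area(pig)
#' @export
specimen_geometry <- function(section = c("ellipse", "circle"),
                              a = NULL, b = NULL, r = NULL,
                              length, name = section) {
  section <- match.arg(section)
  if (section == "circle") {
    if (is.null(r)) {
      if (is.null(a) || is.null(b) || a != b)
        stop("circular section needs r (or a = b)")
      r <- a
    }
    a <- b <- r
  } else {
    if (is.null(a) || is.null(b)) stop("elliptical section needs both semi-axes a and b")
    if (b > a) stop("semi-axes must be ordered a >= b; swap the arguments")
    r <- NULL
  }
  if (min(a, b) <= 0) stop("semi-axes must be positive")
  if (length <= 0) stop("gauge length must be positive")
  structure(list(section = section, a = a, b = b, r = r,
                 length = length, name = name),
            class = "specimen_geometry")
}

#' @method print specimen_geometry
#' @export
print.specimen_geometry <- function(x, ...) {
  if (x$section == "circle")
    cat(sprintf("Circular cylinder '%s': r = %g mm, length = %g mm\n",
                x$name, x$a, x$length))
  else
    cat(sprintf("Elliptic cylinder '%s': a = %g mm, b = %g mm (e = %.3f), length = %g mm\n",
                x$name, x$a, x$b, eccentricity(x$a, x$b), x$length))
  cat(sprintf("  cross-sectional area %.4g mm^2\n", section_area(x)))
  invisible(x)
}

#' Eccentricity of an elliptical cross-section
#'
#' \eqn{e = \sqrt{1 - (b/a)^2}} for semi-axes `a >= b`.  Scale-invariant, so it
#' can equally be computed from the full axes.
#'
#' @param a,b Semi-major and semi-minor axes (mm), `a >= b > 0`.
#' @return Dimensionless eccentricity in `[0, 1)`.
#' @examples
#' eccentricity(3.57 / 2, 2.28 / 2)   # pig peroneal nerve, ~0.77
#' eccentricity(0.57, 0.44)           # Aplysia connective, ~0.64
#' @export
eccentricity <- function(a, b) {
  if (any(b <= 0)) stop("semi-axes must be positive")
  if (any(b > a)) stop("semi-axes must be ordered a >= b; swap the arguments")
  sqrt(1 - (b / a)^2)
}

#' Cross-sectional area of a specimen
#'
#' \eqn{\pi a b} for an ellipse, \eqn{\pi r^2} for a circle.
#'
#' @param geom A [specimen_geometry()].
#' @return Area in mm^2.
#' @export
section_area <- function(geom) {
  stopifnot(inherits(geom, "specimen_geometry"))
  pi * geom$a * geom$b
}

#' Rescale an elliptic cylinder to an area-equivalent circular cylinder
#'
#' Replaces the elliptical section by a circle of radius \eqn{r = \sqrt{ab}},
#' which preserves the cross-sectional area exactly and enables the
#' axisymmetric 2-D reduction.  Gauge length is unchanged.  Circular input is
#' returned as-is.
#'
#' @param geom A [specimen_geometry()].
#' @return A circular `specimen_geometry`.
#' @examples
#' rescale_to_circle(specimen_geometry("ellipse", a = 1.785, b = 1.14, length = 69))
#' @export
rescale_to_circle <- function(geom) {
  stopifnot(inherits(geom, "specimen_geometry"))
  if (geom$section == "circle") return(geom)
  specimen_geometry("circle", r = sqrt(geom$a * geom$b), length = geom$length,
                    name = paste0(geom$name, "_circ"))
}

#' Axial displacement equivalent to a target stretch
#'
#' The experiments impose stretch by moving the upper clamp; the displacement
#' corresponding to stretch \eqn{\lambda} of a gauge length `L` is
#' \eqn{(\lambda - 1) L}.
#'
#' @param lambda Target stretch ratio(s).
#' @param gauge_length Gauge length in mm.
#' @return Displacement in mm.
#' @examples
#' stretch_to_displacement(1.08, 69)
#' @export
stretch_to_displacement <- function(lambda, gauge_length) {
  if (any(lambda < 1))
    warning("lambda < 1 is outside the stretching protocol (compression)")
  (lambda - 1) * gauge_length
}

#' Mean half-width of a digitised specimen profile
#'
#' Helper for specimens whose lateral profile was traced as a polyline of
#' (axial position, half-width) coordinates: returns the length-weighted mean
#' half-width, usable as an effective semi-axis.  Digitisation itself (image
#' processing) is out of scope; this only averages supplied coordinates.
#'
#' @param z Axial positions (mm), increasing.
#' @param halfwidth Half-widths (mm) at those positions.
#' @return Mean half-width in mm (trapezoidal average over the profile).
#' @export
mean_profile_halfwidth <- function(z, halfwidth) {
  if (length(z) != length(halfwidth) || length(z) < 2)
    stop("z and halfwidth must be equal-length vectors (>= 2 points)")
  if (is.unsorted(z, strictly = TRUE)) stop("z must be strictly increasing")
  dz <- diff(z)
  sum(dz * (halfwidth[-1] + halfwidth[-length(halfwidth)]) / 2) / (max(z) - min(z))
}

#' Boundary conditions for a stretch simulation
#'
#' @param displacement Strictly increasing vector of imposed axial
#'   displacements (mm) of the moving end, starting above 0 (the reference
#'   state is implicit).
#' @param fixed_end `"bottom"` or `"top"` (fully clamped end).
#' @param moving_end_lateral `"blocked"` (clamped against lateral contraction,
#'   the experimental condition) or `"free"` (homogeneous-stretch patch
#'   configuration; the fixed end then only constrains the axial direction).
#' @param symmetry `"full"`, `"quarter"` (3-D) or `"axisymmetric"` (2-D).
#' @return An object of class `"boundary_conditions"`.
#' @export
boundary_conditions <- function(displacement,
                                fixed_end = c("bottom", "top"),
                                moving_end_lateral = c("blocked", "free"),
                                symmetry = c("full", "quarter", "axisymmetric")) {
  fixed_end <- match.arg(fixed_end)
  moving_end_lateral <- match.arg(moving_end_lateral)
  symmetry <- match.arg(symmetry)
  if (length(displacement) < 1 || any(diff(c(0, displacement)) <= 0))
    stop("displacement schedule must be strictly increasing from 0")
  structure(list(displacement = displacement, fixed_end = fixed_end,
                 moving_end_lateral = moving_end_lateral, symmetry = symmetry),
            class = "boundary_conditions")
}
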