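#' Equivalent-sphere radius of a target volume
#'
#' The effective radius \eqn{r_{PTV}} of a planning target volume (PTV) is the
#' radius of the sphere with the same volume,
#' \deqn{r_{PTV} = (3 V / 4\pi)^{1/3}.}
#' All quantities are in centimetres / cm^3; DICOM millimetre coordinates are
#' converted at the I/O boundary (see [read_rtstruct()]), never inside
#' computations.
#'
#' @param volume Target volume(s) in cm^3; must be strictly positive.
#' @return Effective radius in cm (vectorised).
#' @examples
#' effective_radius(4 * pi / 3)  # unit sphere -> 1
#' effective_diameter(27.394)    # ~3.74 cm
#' @seealso [effective_diameter()], [sphere_surface_area_from_volume()]
#' @export
effective_radius <- function(volume) {
  check_positive(volume, "volume")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' @rdname effective_radius
#' @export
effective_diameter <- function(volume) {
  2 * effective_radius(volume)
}

#' Sphere volume from radius
#'
#' Inverse of [effective_radius()]: \eqn{V = (4\pi/3) r^3}.
#'
#' @param radius Radius in cm; strictly positive.
#' @return Volume in cm^3.
#' @export
sphere_volume <- function(radius) {
  check_positive(radius, "radius")
  (4 * pi / 3) * radius^3
}

#' Surface area of the equivalent-volume sphere
#'
#' Returns \eqn{4\pi r^2} with \eqn{r} the equivalent-sphere radius of
#' `volume`.  Because the sphere is the minimal-surface solid of a given
#' volume, this is a hard lower bound on the surface area of any real target
#' of that volume; a mesh-derived surface area below it is non-physical (see
#' [mesh_surface_area()]).
#'
#' @inheritParams effective_radius
#' @return Surface area in cm^2.
#' @examples
#' sphere_surface_area_from_volume(0.011)  # ~0.24 cm^2
#' @export
sphere_surface_area_from_volume <- function(volume) {
  4 * pi * effective_radius(volume)^2
}

#' Geometric descriptors of one target
#'
#' Bundles the scalar geometry of a single PTV: volume, optional surface
#' area, equivalent-sphere radius and diameter.  When `surface_area` is
#' flagged physical it is checked against the sphere lower bound.
#'
#' @param volume Target volume, cm^3.
#' @param surface_area Optional measured surface area, cm^2 (`NA` when only
#'   the sphere approximation is wanted).
#' @param physical If `TRUE` (default), a supplied `surface_area` below the
#'   equal-volume sphere bound (beyond `tolerance`) is an error.
#' @param tolerance Slack on the sphere bound, cm^2.
#' @return An object of class `ptv_geometry`: a list with elements `volume`,
#'   `surface_area`, `r_ptv`, `d_ptv`.
#' @export
ptv_geometry <- function(volume, surface_area = NA_real_, physical = TRUE,
                         tolerance = 1e-9) {
  check_positive(volume, "volume")
  r <- effective_radius(volume)
  if (!is.na(surface_area)) {
    check_positive(surface_area, "surface_area")
    if (physical && surface_area < 4 * pi * r^2 - tolerance) {
      stop(sprintf(
        "surface_area %.4f cm^2 is below the equal-volume sphere bound %.4f cm^2 (non-physical)",
        surface_area, 4 * pi * r^2
      ), call. = FALSE)
    }
  }
  structure(
    list(volume = volume, surface_area = surface_area,
         r_ptv = r, d_ptv = 2 * r),
    class = "ptv_geometry"
  )
}

#' @export
print.ptv_geometry <- function(x, ...) {
  cat(sprintf("PTV geometry: V = %.3f cm^3, r = %.4f cm, d = %.4f cm\n",
              x$volume, x$r_ptv, x$d_ptv))
  if (!is.na(x$surface_area)) {
    cat(sprintf("  SA = %.3f cm^2 (sphere bound %.3f cm^2)\n",
                x$surface_area, 4 * pi * x$r_ptv^2))
  }
  invisible(x)
}

# shared argument guard: strictly positive, finite, numeric
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) ||
      any(!is.finite(x)) || any(x <= 0)) {
    bad <- if (is.numeric(x) && length(x) > 0) {
      paste(utils::head(x[!is.finite(x) | is.na(x) | x <= 0], 3), collapse = ", ")
    } else {
      deparse(substitute(x))
    }
    stop(sprintf("`%s` must be strictly positive and finite (got: %s)",
                 name, bad), call. = FALSE)
  }
  invisible(x)
}
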