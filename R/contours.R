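#' Planar contour stack of one ROI
#'
#' Container for the CLOSED_PLANAR contours of a structure: an ordered list
#' of axial slices, each holding one or more closed planar rings.  All
#' coordinates are in cm (DICOM millimetres are converted on ingest).  Rings
#' are stored counter-clockwise viewed from +z; clockwise input rings are
#' reversed, consecutive duplicate vertices are removed, and rings that
#' degenerate (< 3 distinct vertices or zero area) are rejected.
#'
#' @param slices List of `list(z = <cm>, polygons = list(<n x 2 matrix>))`,
#'   in any z order; slices are sorted and must have distinct z.
#' @param roi_name Structure name.
#' @param spacing Length-2 numeric `(pixel, slice)` spacing in cm, or `NA`.
#' @param degenerate Logical flag set for single-slice structures.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(slices, roi_name = "ROI", spacing = c(NA_real_, NA_real_),
                        degenerate = length(slices) < 2) {
  stopifnot(is.list(slices), length(slices) >= 1)
  z <- vapply(slices, function(s) s$z, numeric(1))
  if (anyDuplicated(z)) stop("duplicate slice z positions", call. = FALSE)
  slices <- slices[order(z)]
  slices <- lapply(slices, function(s) {
    polys <- lapply(s$polygons, clean_ring)
    polys <- polys[!vapply(polys, is.null, logical(1))]
    if (length(polys) == 0) return(NULL)
    list(z = s$z, polygons = polys)
  })
  slices <- slices[!vapply(slices, is.null, logical(1))]
  if (length(slices) == 0) {
    stop("no valid rings: every ring degenerated (< 3 distinct vertices or zero area)",
         call. = FALSE)
  }
  structure(
    list(roi_name = roi_name, slices = slices,
         source_spacing = spacing,
         degenerate = length(slices) < 2 || degenerate),
    class = "contour_set"
  )
}

# dedupe consecutive vertices, drop closing repeat, enforce CCW; NULL if degenerate
clean_ring <- function(ring, tol = 1e-12) {
  ring <- as.matrix(ring)
  stopifnot(ncol(ring) == 2)
  if (nrow(ring) > 1 &&
      all(abs(ring[1, ] - ring[nrow(ring), ]) < tol)) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  keep <- c(TRUE, rowSums(abs(diff(ring))) > tol)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3) return(NULL)
  a <- ring_signed_area(ring)
  if (abs(a) < tol) return(NULL)
  if (a < 0) ring <- ring[nrow(ring):1, , drop = FALSE]
  ring
}

# shoelace; positive for counter-clockwise
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:nrow(ring), 1)
  sum(x * y[j] - x[j] * y) / 2
}

ring_centroid <- function(ring) colMeans(ring)

#' @export
print.contour_set <- function(x, ...) {
  nr <- sum(vapply(x$slices, function(s) length(s$polygons), integer(1)))
  z <- vapply(x$slices, function(s) s$z, numeric(1))
  cat(sprintf("Contour set '%s': %d slice(s), %d ring(s), z in [%.3f, %.3f] cm%s\n",
              x$roi_name, length(x$slices), nr, min(z), max(z),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}
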