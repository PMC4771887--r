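#' Projection set
#'
#' An ordered stack of 2-D projection images over view angles, with the
#' acquisition geometry and the flat-field (unattenuated) intensity
#' `i0`.  Intensities are stored as a 3-D array
#' `[detector rows, detector columns, views]` in arbitrary detector units.
#'
#' @param intensity 3-D array of non-negative intensities.
#' @param geometry An [acquisition_geometry()].
#' @param i0 Flat-field intensity (scalar, > 0): the signal a detector
#'   pixel records with no object in the beam.
#' @param kind Free-form tag (`"measured"`, `"primary"`, `"corrected"`, ...).
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(intensity, geometry, i0, kind = "primary") {
  intensity <- as.array(intensity)
  if (length(dim(intensity)) == 2L) dim(intensity) <- c(dim(intensity), 1L)
  if (length(dim(intensity)) != 3L)
    stop("intensity must be a [rows, cols, views] array")
  if (!inherits(geometry, "acquisition_geometry"))
    stop("geometry must be an acquisition_geometry")
  d <- dim(intensity)
  if (d[1] != geometry$det_rows || d[2] != geometry$det_cols ||
      d[3] != length(geometry$angles_deg))
    stop("intensity dimensions do not match the geometry (",
         paste(d, collapse = " x "), " vs ", geometry$det_rows, " x ",
         geometry$det_cols, " x ", length(geometry$angles_deg), ")")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  if (!is.numeric(i0) || length(i0) != 1L || i0 <= 0)
    stop("flat-field intensity i0 must be a positive scalar")
  structure(list(intensity = intensity, geometry = geometry,
                 i0 = as.numeric(i0), kind = kind),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("Projection set (%s): %d x %d px, %d views, i0 = %g\n",
              x$kind, d[1], d[2], d[3], x$i0))
  invisible(x)
}

#' Number of views in a projection set
#' @param x A [projection_set()].
#' @export
n_views <- function(x) dim(x$intensity)[3]

#' Forward-project a phantom (monoenergetic Beer's law)
#'
#' Computes primary-beam projections of a voxel phantom: each detector
#' pixel records `i0 * exp(-l)` where `l` is the exact radiological path
#' (attenuation times intersection length, summed over voxels crossed) of
#' the ray from the source to that pixel.  Line integrals use an
#' incremental Siddon voxel traversal, so a ray crossing a voxel
#' contributes exactly `mu * chord length` with no interpolation.
#'
#' @param phantom A [digital_phantom()].
#' @param geometry An [acquisition_geometry()].
#' @param i0 Flat-field intensity.
#' @param check_fov If `TRUE` (default), error when the phantom's bounding
#'   cylinder is not fully covered by the fan at some angle, naming the
#'   first violating angle.
#' @return A [projection_set()] of primary intensities.
#' @export
forward_project <- function(phantom, geometry, i0 = 1e4, check_fov = TRUE) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(geometry, "acquisition_geometry"))
  d <- dim(phantom$mu)
  if (check_fov) {
    # Lateral radius of the attenuating support; the tangent rays to that
    # cylinder must land on the detector at every angle.
    occ <- apply(phantom$mu > 0, c(1, 2), any)
    if (!any(occ)) {
      r_obj <- 0
    } else {
      cx <- (row(occ) - (d[1] + 1) / 2) * phantom$voxel_mm
      cy <- (col(occ) - (d[2] + 1) / 2) * phantom$voxel_mm
      r_obj <- sqrt(max(cx[occ]^2 + cy[occ]^2)) +
        phantom$voxel_mm / sqrt(2)
    }
    if (r_obj >= geometry$dso)
      stop("phantom grid reaches the source orbit")
    proj_half <- if (r_obj > 0)
      geometry$dsd * tan(asin(pmin(1, r_obj / geometry$dso))) else 0
    if (proj_half > detector_half_width(geometry)) {
      stop(sprintf(
        "phantom exceeds the detector field of view at angle %.1f deg (needs half-width %.1f mm, detector %.1f mm)",
        geometry$angles_deg[1], proj_half, detector_half_width(geometry)))
    }
  }
  li <- cpp_forward_project(as.numeric(phantom$mu), as.integer(d),
                            phantom$voxel_mm, geometry$dso, geometry$dsd,
                            geometry$pitch, geometry$det_rows,
                            geometry$det_cols,
                            geometry$angles_deg * pi / 180)
  dim(li) <- c(geometry$det_rows, geometry$det_cols,
               length(geometry$angles_deg))
  projection_set(i0 * exp(-li), geometry, i0, kind = "primary")
}

#' Line integrals of a projection set
#'
#' Log-converts intensities to line integrals `log(i0 / I)`, clipping
#' intensities below `floor_frac * i0` to keep the logarithm finite.
#'
#' @param proj A [projection_set()].
#' @param floor_frac Intensity floor as a fraction of `i0`.
#' @return Array of line integrals, same shape as the intensities.
#' @export
line_integrals <- function(proj, floor_frac = 1e-6) {
  p <- pmax(proj$intensity, floor_frac * proj$i0)
  log(proj$i0 / p)
}
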