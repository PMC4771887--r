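#' Cone-beam acquisition geometry
#'
#' Describes a circular cone-beam scan with a flat-panel detector: the
#' source rotates at radius `dso` (source-to-object distance, mm) about the
#' isocenter, the detector sits at `dsd` (source-to-detector distance, mm)
#' perpendicular to the central ray, and projections are taken at equally
#' spaced angles over a full rotation.
#'
#' @param dso Source-to-object (isocenter) distance in mm. Default 500.
#' @param dsd Source-to-detector distance in mm. Default 786. Must exceed
#'   `dso`: the detector is behind the object as seen from the source.
#' @param pitch Detector pixel pitch in mm (square pixels).
#' @param det_rows,det_cols Detector dimensions in pixels.
#' @param n_views Number of equally spaced view angles over `[0, 360)`
#'   degrees. Ignored when `angles_deg` is given.
#' @param angles_deg Optional explicit view angles in degrees.
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(dso = 500, dsd = 786, pitch = 0.388,
                                 det_rows = 256L, det_cols = 256L,
                                 n_views = 360L, angles_deg = NULL) {
  if (!(dsd > dso && dso > 0))
    stop("geometry requires dsd > dso > 0 (got dsd = ", dsd,
         ", dso = ", dso, ")")
  if (pitch <= 0) stop("detector pixel pitch must be > 0")
  if (det_rows < 1 || det_cols < 1) stop("detector must have >= 1 pixel")
  if (is.null(angles_deg)) {
    if (n_views < 1) stop("n_views must be >= 1")
    angles_deg <- seq(0, 360, length.out = n_views + 1L)[seq_len(n_views)]
  }
  if (any(angles_deg < 0 | angles_deg >= 360))
    stop("view angles must lie in [0, 360)")
  structure(list(dso = dso, dsd = dsd, pitch = pitch,
                 det_rows = as.integer(det_rows),
                 det_cols = as.integer(det_cols),
                 angles_deg = as.numeric(angles_deg)),
            class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("Cone-beam acquisition geometry\n")
  cat(sprintf("  DSO %.1f mm, DSD %.1f mm (magnification %.3f)\n",
              x$dso, x$dsd, x$dsd / x$dso))
  cat(sprintf("  detector %d x %d px @ %.3f mm, %d views over [0, 360)\n",
              x$det_rows, x$det_cols, x$pitch, length(x$angles_deg)))
  invisible(x)
}

# Magnification of the isocenter plane onto the detector.
geometry_magnification <- function(geom) geom$dsd / geom$dso

# Half-width of the detector (mm) measured from the central ray.
detector_half_width <- function(geom) geom$pitch * geom$det_cols / 2
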