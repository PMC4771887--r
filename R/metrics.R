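#' ROI statistics on a reconstructed slice
#'
#' Mean and standard deviation over a circular region of interest.
#'
#' @param slice Matrix of reconstructed values (attenuation or HU); row
#'   index is x, column index is y, the isocenter at the array centre.
#' @param center_mm ROI centre `c(x, y)` in mm.
#' @param radius_mm ROI radius in mm.
#' @param voxel_mm Pixel size of the slice (mm).
#' @return List with `mean`, `sd`, `n` (pixel count), and the descriptor.
#' @export
roi_stats <- function(slice, center_mm, radius_mm, voxel_mm) {
  d <- dim(slice)
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * voxel_mm
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * voxel_mm
  m <- outer((cx - center_mm[1])^2, (cy - center_mm[2])^2, "+") <= radius_mm^2
  if (!any(m)) stop("empty ROI: radius smaller than a pixel?")
  v <- slice[m]
  list(mean = mean(v), sd = stats::sd(v), n = sum(m),
       center_mm = center_mm, radius_mm = radius_mm)
}

#' CT number (Hounsfield units)
#'
#' `CT# = 1000 * (m_x - m_water) / m_water`, with the water reference mean
#' taken from a low-scatter benchmark scan.  Water maps to 0 HU and zero
#' attenuation to -1000 HU.
#'
#' @param m_x Mean reconstructed value of the material of interest.
#' @param m_water Water (or water-surrogate) reference mean, `> 0`.
#' @return CT number(s) in HU.
#' @export
ct_number <- function(m_x, m_water) {
  if (any(m_water <= 0)) stop("water reference mean must be > 0")
  1000 * (m_x - m_water) / m_water
}

#' Contrast and contrast-to-noise ratio between two ROIs
#'
#' `Contrast = m_x - m_bg`;
#' `CNR = (m_x - m_bg) / sqrt(sd_x^2 + sd_bg^2)`.
#'
#' @param stats_x,stats_bg ROI statistics: lists with `mean` and `sd`
#'   (as returned by [roi_stats()]), or plain numbers for `mean` with
#'   `sd = 0`.
#' @return List with `contrast` and `cnr`.  When both standard deviations
#'   are zero and the contrast is nonzero, `cnr` is `Inf` with a warning;
#'   zero contrast gives `cnr = 0`.
#' @export
contrast_and_cnr <- function(stats_x, stats_bg) {
  as_stats <- function(s) if (is.numeric(s)) list(mean = s, sd = 0) else s
  sx <- as_stats(stats_x)
  sb <- as_stats(stats_bg)
  contrast <- sx$mean - sb$mean
  noise <- sqrt(sx$sd^2 + sb$sd^2)
  cnr <- if (noise == 0) {
    if (contrast == 0) 0
    else {
      warning("both ROI standard deviations are zero; CNR is infinite")
      Inf * sign(contrast)
    }
  } else contrast / noise
  list(contrast = contrast, cnr = cnr)
}

#' Percent cupping of a uniform region
#'
#' `% cupping = (CT#_edge - CT#_center) * 100 / (CT#_edge + 1000)`, where
#' `CT#_edge` is the average CT number of exactly four peripheral ROIs in
#' the uniform region and `CT#_center` the central ROI's CT number.
#' Positive values mean the centre is depressed relative to the
#' periphery — the classic scatter cupping artifact.
#'
#' @param edge_hu Numeric vector of exactly four peripheral CT numbers
#'   (HU).
#' @param center_hu Central CT number (HU).
#' @return Percent cupping (scalar).
#' @export
percent_cupping <- function(edge_hu, center_hu) {
  if (length(edge_hu) != 4L)
    stop("exactly four peripheral ROIs are required")
  edge <- mean(edge_hu)
  if (abs(edge + 1000) < .Machine$double.eps^0.5)
    stop("edge CT number of -1000 HU makes percent cupping undefined")
  (edge - center_hu) * 100 / (edge + 1000)
}

#' Extract a 1-D profile from a slice or projection
#'
#' Samples the image along a straight line between two points, using
#' nearest-neighbour lookup by default (each sample maps to the pixel it
#' falls in) or bilinear interpolation.
#'
#' @param img Matrix; row index is x, column index is y.
#' @param from,to Endpoints `c(x, y)` in pixel coordinates (1-based,
#'   fractional allowed).
#' @param n Number of samples (default: one per pixel of line length).
#' @param method `"nearest"` or `"bilinear"`.
#' @return Numeric vector of sampled values.
#' @export
extract_profile <- function(img, from, to, n = NULL,
                            method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  d <- dim(img)
  pts <- rbind(from, to)
  if (any(pts[, 1] < 1 | pts[, 1] > d[1] | pts[, 2] < 1 | pts[, 2] > d[2]))
    stop("profile line endpoint outside the image bounds")
  if (is.null(n))
    n <- max(2L, ceiling(sqrt(sum((to - from)^2))) + 1L)
  tt <- seq(0, 1, length.out = n)
  x <- from[1] + tt * (to[1] - from[1])
  y <- from[2] + tt * (to[2] - from[2])
  if (method == "nearest") {
    ix <- pmin(pmax(round(x), 1), d[1])
    iy <- pmin(pmax(round(y), 1), d[2])
    return(img[cbind(ix, iy)])
  }
  x0 <- pmin(pmax(floor(x), 1), d[1] - 1)
  y0 <- pmin(pmax(floor(y), 1), d[2] - 1)
  wx <- x - x0
  wy <- y - y0
  (1 - wx) * (1 - wy) * img[cbind(x0, y0)] +
    wx * (1 - wy) * img[cbind(x0 + 1, y0)] +
    (1 - wx) * wy * img[cbind(x0, y0 + 1)] +
    wx * wy * img[cbind(x0 + 1, y0 + 1)]
}

#' Absolute HU differences against a reference
#'
#' Elementwise `|corrected - reference|`, the error measure used to
#' benchmark corrected insert means against a low-scatter reference scan.
#'
#' @param corrected_means,reference_means Matched numeric vectors
#'   (optionally named by insert).
#' @return Numeric vector of absolute differences.
#' @export
hu_difference_table <- function(corrected_means, reference_means) {
  if (length(corrected_means) != length(reference_means))
    stop("insert lists must be matched")
  out <- abs(corrected_means - reference_means)
  names(out) <- names(corrected_means)
  out
}
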