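#' Reconstruction filter specification
#'
#' Ramp filter apodized by a window, specified by family and cutoff.
#' `cutoff` is the window truncation frequency as a fraction of the
#' detector Nyquist frequency: the frequency response is
#' `|f| * w(|f| / fc)` for `|f| <= fc = cutoff * f_Nyquist` and zero
#' above, with `w` = 1 (ramp), the half-period sinc (shepp-logan), or the
#' Hamming window (hamming).
#'
#' @param family One of `"ramp"`, `"shepp-logan"`, `"hamming"`.
#' @param cutoff Fraction of Nyquist in `(0, 1]`. Default 0.6.
#' @return An object of class `recon_filter`.
#' @export
recon_filter <- function(family = c("shepp-logan", "hamming", "ramp"),
                         cutoff = 0.6) {
  family <- match.arg(family)
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  structure(list(family = family, cutoff = cutoff), class = "recon_filter")
}

# Frequency response of the windowed ramp on an M-point circular grid
# with sample spacing ds.  The base ramp is the band-limited discrete
# ramp (its spatial samples are 1/(4 ds^2) at 0 and -1/(pi n ds)^2 at odd
# lags), which has the correct DC behaviour on sampled data.
ramp_response <- function(M, ds, filter) {
  n <- c(0:(M / 2), -(M / 2 - 1):-1)  # circular lags
  h <- numeric(M)
  h[1] <- 1 / (4 * ds^2)
  odd <- which(n %% 2 != 0)
  h[odd] <- -1 / (pi * n[odd] * ds)^2
  H <- Re(stats::fft(h))
  f <- abs(n) / (M * ds)              # frequency of each FFT bin
  fc <- filter$cutoff / (2 * ds)      # cutoff * Nyquist
  r <- pmin(f / fc, 1)
  w <- switch(filter$family,
              "ramp" = rep(1, M),
              "shepp-logan" = ifelse(r == 0, 1, sin(pi * r / 2) / (pi * r / 2)),
              "hamming" = 0.54 + 0.46 * cos(pi * r))
  w[f > fc] <- 0
  H * w
}

# Filter sinogram columns-wise: p is [ndet, nview] sampled at spacing ds.
filter_sinogram <- function(p, ds, filter) {
  ndet <- nrow(p)
  M <- 2L * stats::nextn(ndet, c(2, 3, 5))  # even, >= 2 * ndet
  H <- ramp_response(M, ds, filter)
  pad <- matrix(0, M, ncol(p))
  pad[seq_len(ndet), ] <- p
  q <- Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)) / M
  q[seq_len(ndet), , drop = FALSE] * ds
}

# Error when the view angles leave a gap larger than 1.5x the nominal
# spacing anywhere on the circle.
check_full_rotation <- function(angles_deg) {
  a <- sort(angles_deg %% 360)
  gaps <- diff(c(a, a[1] + 360))
  nominal <- 360 / length(a)
  if (max(gaps) > 1.5 * nominal + 1e-9)
    stop(sprintf(
      "incomplete angular coverage: %.1f deg gap after %.1f deg (nominal spacing %.1f deg)",
      max(gaps), a[which.max(gaps)], nominal))
  invisible(TRUE)
}

#' Reconstructed volume
#'
#' @param data 2-D matrix (single slice) or 3-D array of reconstructed
#'   attenuation values (per mm).
#' @param voxel_mm Isotropic voxel size (mm).
#' @param orientation Slice orientation tag.
#' @export
recon_volume <- function(data, voxel_mm, orientation = "axial") {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (voxel_mm <= 0) stop("voxel size must be > 0")
  if (any(!is.finite(data))) stop("reconstruction contains non-finite values")
  structure(list(data = data, voxel_mm = voxel_mm,
                 orientation = orientation), class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Reconstructed volume: %d x %d x %d voxels @ %.3g mm\n",
              d[1], d[2], d[3], x$voxel_mm))
  invisible(x)
}

#' Fan-beam FBP of a central-slice sinogram
#'
#' Reconstructs the rotation-plane slice from a sinogram of line
#' integrals using flat-detector (equally spaced) fan-beam filtered
#' backprojection: the detector is rescaled to a virtual detector line
#' through the isocenter, samples are cosine-weighted, convolved with the
#' windowed ramp, and backprojected with inverse-square distance
#' weighting.
#'
#' @param sino Matrix `[det_cols, n_views]` of line integrals
#'   `log(i0 / I)`.
#' @param geometry An [acquisition_geometry()].
#' @param filter A [recon_filter()].
#' @param npix Output image side (pixels).
#' @param voxel_mm Output pixel size (mm).
#' @return `npix x npix` matrix of attenuation values (per mm); x runs
#'   along rows, y along columns, the isocenter at the centre.
#' @export
fbp_central_slice <- function(sino, geometry,
                              filter = recon_filter("shepp-logan", 0.6),
                              npix = 256L, voxel_mm = 0.75) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            inherits(filter, "recon_filter"))
  if (nrow(sino) != geometry$det_cols ||
      ncol(sino) != length(geometry$angles_deg))
    stop("sinogram dimensions do not match the geometry")
  check_full_rotation(geometry$angles_deg)
  ds <- geometry$pitch * geometry$dso / geometry$dsd  # virtual pitch
  s <- (seq_len(geometry$det_cols) - (geometry$det_cols + 1) / 2) * ds
  wgt <- geometry$dso / sqrt(geometry$dso^2 + s^2)
  q <- filter_sinogram(sino * wgt, ds, filter)
  cpp_fan_backproject(q, ds, geometry$dso,
                      geometry$angles_deg * pi / 180, as.integer(npix),
                      voxel_mm)
}

#' Filtered backprojection reconstruction of a projection set
#'
#' Log-converts intensities to line integrals `log(i0 / I)` and
#' reconstructs.  The default path (`slices = "central"`) is fan-beam FBP
#' of the central detector row — the benchmarking configuration.  With
#' `slices = "fdk"` a full cone-beam volume is reconstructed with the
#' FDK weighting (cone-angle cosine weight, row-wise ramp filtering,
#' distance-weighted 3-D backprojection); intended for small grids.
#'
#' @param proj A [projection_set()].
#' @param filter A [recon_filter()].
#' @param npix In-plane output side (pixels).
#' @param voxel_mm Output voxel size (mm).
#' @param slices `"central"` or `"fdk"`.
#' @param nslice Number of axial slices for `slices = "fdk"`.
#' @return A [recon_volume()].
#' @export
fbp_reconstruct <- function(proj, filter = recon_filter("shepp-logan", 0.6),
                            npix = 256L, voxel_mm = 0.75,
                            slices = c("central", "fdk"), nslice = NULL) {
  stopifnot(inherits(proj, "projection_set"))
  slices <- match.arg(slices)
  geom <- proj$geometry
  li <- line_integrals(proj)
  if (slices == "central") {
    mid <- as.integer(round((geom$det_rows + 1) / 2))
    sino <- matrix(li[mid, , ], geom$det_cols, length(geom$angles_deg))
    img <- fbp_central_slice(sino, geom, filter, npix, voxel_mm)
    return(recon_volume(img, voxel_mm))
  }
  check_full_rotation(geom$angles_deg)
  if (is.null(nslice)) nslice <- max(1L, as.integer(npix / 8))
  ds <- geom$pitch * geom$dso / geom$dsd
  s <- (seq_len(geom$det_cols) - (geom$det_cols + 1) / 2) * ds
  v <- (seq_len(geom$det_rows) - (geom$det_rows + 1) / 2) *
    geom$pitch * geom$dso / geom$dsd
  cone_w <- geom$dso / sqrt(geom$dso^2 +
                            outer(v^2, s^2, "+"))  # [rows, cols]
  qf <- li
  for (a in seq_len(dim(li)[3])) {
    wrow <- li[, , a] * cone_w
    qf[, , a] <- t(filter_sinogram(t(wrow), ds, filter))
  }
  vol <- cpp_fdk_backproject(as.numeric(qf), dim(qf)[1:2], geom$pitch,
                             geom$dso, geom$dsd,
                             geom$angles_deg * pi / 180,
                             as.integer(npix), as.integer(nslice), voxel_mm)
  dim(vol) <- c(npix, npix, nslice)
  recon_volume(vol, voxel_mm)
}
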