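#' Digital voxel phantom
#'
#' A voxelized map of linear attenuation coefficients (per mm) on an
#' isotropic grid centred on the isocenter, plus descriptors for any
#' cylindrical inserts.  The convention follows the usual right-handed
#' scanner frame: x/y span the rotation plane, z the rotation axis.
#'
#' @param mu 3-D array of linear attenuation coefficients (per mm), all
#'   values `>= 0`.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param inserts Optional data frame describing inserts (see
#'   [generate_qrm_like_phantom()]).
#' @return An object of class `digital_phantom`.
#' @export
digital_phantom <- function(mu, voxel_mm, inserts = NULL) {
  mu <- as.array(mu)
  if (length(dim(mu)) == 2L) dim(mu) <- c(dim(mu), 1L)
  if (length(dim(mu)) != 3L) stop("mu must be a 2-D or 3-D array")
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("attenuation values must be finite and >= 0")
  if (voxel_mm <= 0) stop("voxel size must be > 0")
  structure(list(mu = mu, voxel_mm = voxel_mm, inserts = inserts),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  d <- dim(x$mu)
  cat(sprintf("Digital phantom: %d x %d x %d voxels @ %.3g mm (%s)\n",
              d[1], d[2], d[3], x$voxel_mm,
              if (is.null(x$inserts)) "no inserts"
              else paste(nrow(x$inserts), "inserts")))
  invisible(x)
}

# Nominal attenuation coefficients (per mm) at an effective energy of
# roughly 60 keV, the monoenergetic surrogate used throughout.
.material_mu <- c(water = 0.0206, soft_tissue = 0.0212,
                  bone = 0.0480, air = 0.0000, pmma = 0.0229)

#' Default insert layout for a QRM-style CT-number section
#'
#' Four cylindrical inserts (bone, air, water, soft tissue) placed on a
#' ring, mimicking the CT-number section of a cylindrical multi-insert
#' calibration phantom.
#'
#' @param ring_radius_mm Radius of the ring the insert centres sit on.
#' @param insert_radius_mm Radius of each insert.
#' @return Data frame with columns `label`, `cx`, `cy`, `radius`, `mu`.
#' @export
qrm_insert_spec <- function(ring_radius_mm = 50, insert_radius_mm = 9) {
  lab <- c("bone", "air", "water", "soft_tissue")
  ang <- (seq_along(lab) - 1) * pi / 2
  data.frame(label = lab,
             cx = ring_radius_mm * cos(ang),
             cy = ring_radius_mm * sin(ang),
             radius = insert_radius_mm,
             mu = unname(.material_mu[lab]))
}

#' Low-contrast insert layout
#'
#' Four inserts whose attenuation differs from background by small offsets,
#' emulating the numbered low-contrast pattern of a multi-insert phantom
#' section.
#'
#' @param background_mu Background attenuation (per mm).
#' @param offsets Attenuation offsets (per mm) for inserts 1 to 4.
#' @inheritParams qrm_insert_spec
#' @export
low_contrast_insert_spec <- function(background_mu = .material_mu[["soft_tissue"]],
                                     offsets = c(-8e-4, -4e-4, 4e-4, 8e-4),
                                     ring_radius_mm = 45,
                                     insert_radius_mm = 8) {
  ang <- (seq_along(offsets) - 1) * pi / 2 + pi / 4
  data.frame(label = paste0("lc", seq_along(offsets)),
             cx = ring_radius_mm * cos(ang),
             cy = ring_radius_mm * sin(ang),
             radius = insert_radius_mm,
             mu = background_mu + offsets)
}

#' Generate a cylindrical multi-insert phantom
#'
#' Voxelizes a water-equivalent cylinder (default diameter 160 mm) with
#' optional cylindrical inserts running parallel to the rotation axis, in
#' the style of a QRM cone-beam calibration phantom.
#'
#' @param diameter_mm Cylinder diameter in mm.
#' @param insert_spec `NULL` for a uniform cylinder, or a data frame with
#'   columns `label`, `cx`, `cy`, `radius`, `mu` (see [qrm_insert_spec()]).
#' @param height_mm Cylinder height in mm; defaults to the diameter.
#' @param voxel_mm Isotropic voxel size.
#' @param background_mu Attenuation of the cylinder body (per mm).
#' @param nz Number of voxel planes along z (defaults to cover
#'   `height_mm`); use a small value for thin test slabs.
#' @return A [digital_phantom()].
#' @export
generate_qrm_like_phantom <- function(diameter_mm = 160, insert_spec = NULL,
                                      height_mm = diameter_mm,
                                      voxel_mm = 1.25,
                                      background_mu = .material_mu[["soft_tissue"]],
                                      nz = NULL) {
  if (diameter_mm <= 0) stop("diameter must be > 0")
  R <- diameter_mm / 2
  if (!is.null(insert_spec)) {
    need <- c("label", "cx", "cy", "radius", "mu")
    if (!all(need %in% names(insert_spec)))
      stop("insert_spec needs columns: ", paste(need, collapse = ", "))
    r_out <- sqrt(insert_spec$cx^2 + insert_spec$cy^2) + insert_spec$radius
    bad <- which(r_out > R)
    if (length(bad))
      stop("insert(s) outside the phantom cylinder: ",
           paste(insert_spec$label[bad], collapse = ", "))
    if (nrow(insert_spec) > 1) {
      for (i in seq_len(nrow(insert_spec) - 1)) {
        for (j in seq(i + 1, nrow(insert_spec))) {
          d <- sqrt((insert_spec$cx[i] - insert_spec$cx[j])^2 +
                    (insert_spec$cy[i] - insert_spec$cy[j])^2)
          if (d < insert_spec$radius[i] + insert_spec$radius[j])
            stop("overlapping inserts: ", insert_spec$label[i], " and ",
                 insert_spec$label[j])
        }
      }
    }
  }
  nxy <- ceiling(diameter_mm / voxel_mm) + 2L
  if (is.null(nz)) nz <- max(1L, ceiling(height_mm / voxel_mm))
  cen <- (nxy + 1) / 2
  x <- (seq_len(nxy) - cen) * voxel_mm
  xm <- matrix(x, nxy, nxy)
  ym <- t(xm)
  slice <- matrix(0, nxy, nxy)
  slice[xm^2 + ym^2 <= R^2] <- background_mu
  if (!is.null(insert_spec)) {
    for (i in seq_len(nrow(insert_spec))) {
      m <- (xm - insert_spec$cx[i])^2 + (ym - insert_spec$cy[i])^2 <=
        insert_spec$radius[i]^2
      slice[m] <- insert_spec$mu[i]
    }
  }
  mu <- array(slice, dim = c(nxy, nxy, nz))
  digital_phantom(mu, voxel_mm, inserts = insert_spec)
}

#' Generate a uniform slab phantom
#'
#' A homogeneous slab of given thickness along the x axis (facing the
#' source at view angle 0), used for thickness-mapping calibration and
#' round-trip tests.
#'
#' @param thickness_mm Slab thickness along the beam direction (mm).
#' @param width_mm Lateral extent (y and z) of the slab.
#' @param voxel_mm Isotropic voxel size; the slab thickness is rounded to
#'   a whole number of voxels.
#' @param mu Slab attenuation (per mm); defaults to PMMA.
#' @return A [digital_phantom()].
#' @export
generate_slab_phantom <- function(thickness_mm, width_mm = 220,
                                  voxel_mm = 1, mu = .material_mu[["pmma"]]) {
  if (thickness_mm <= 0) stop("thickness must be > 0")
  nx <- max(1L, round(thickness_mm / voxel_mm))
  nyz <- ceiling(width_mm / voxel_mm)
  arr <- array(mu, dim = c(nx, nyz, nyz))
  digital_phantom(arr, voxel_mm)
}

#' Attenuation coefficients of the built-in materials
#'
#' @return Named numeric vector of linear attenuation coefficients
#'   (per mm) at the nominal effective energy.
#' @export
material_attenuation <- function() .material_mu
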