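#' Scatter fraction as a function of object thickness
#'
#' The scatter fraction (scatter-to-measured signal ratio) grows linearly
#' with the PMMA-equivalent thickness of the object:
#' `SF(t) = a1 * t + a2`.  The default coefficients are the calibrated
#' values `a1 = 0.0038` per mm and `a2 = 0.1`.  The linear model exceeds 1
#' for very thick objects (about 237 mm at the defaults), which is
#' unphysical; values are clamped to `clamp` with a warning.
#'
#' @param t Thickness in mm (vectorized, all `>= 0`).
#' @param a1 Slope (per mm).
#' @param a2 Intercept (dimensionless).
#' @param clamp Upper clamp applied before returning. Default 0.99.
#' @return Scatter fraction(s) in `[0, clamp]`.
#' @export
sf_of_thickness <- function(t, a1 = 0.0038, a2 = 0.1, clamp = 0.99) {
  if (any(t < 0)) stop("thickness must be >= 0")
  sf <- a1 * t + a2
  if (any(sf >= clamp)) {
    warning(sprintf(
      "scatter fraction clamped to %.2f for %d thickness value(s) (linear model exceeds 1)",
      clamp, sum(sf >= clamp)))
    sf <- pmin(sf, clamp)
  }
  sf
}

# Default amplitude table: piecewise-constant compensation factor over
# thickness ranges, upper edge inclusive, last range open-ended.
.default_amp_table <- function() {
  list(upper = c(40, 80, 120, 160), values = c(1.0, 1.0, 1.75, 1.75, 2.0))
}

#' Kernel amplitude as a function of thickness
#'
#' Piecewise-constant compensation amplitude `A(t)` looked up in a table of
#' thickness ranges.  Ranges are upper-edge inclusive (`0 < t <= 40` maps
#' to the first entry; `t` above the last finite edge maps to the final
#' open-ended entry); `t = 0` also maps to the first entry.
#'
#' @param t Thickness in mm (vectorized, `>= 0`).
#' @param table List with `upper` (finite upper edges, increasing) and
#'   `values` (one more element than `upper`).
#' @return Amplitude value(s).
#' @export
amplitude_of_thickness <- function(t, table = .default_amp_table()) {
  if (any(t < 0)) stop("thickness must be >= 0")
  stopifnot(length(table$values) == length(table$upper) + 1L,
            !is.unsorted(table$upper, strictly = TRUE))
  idx <- findInterval(t, table$upper, left.open = TRUE) + 1L
  table$values[idx]
}

#' Parametric scatter point-spread function
#'
#' Builds a radially symmetric, unit-sum PSF on an odd-sized square grid.
#' The shape is a two-component radial model — a narrow Gaussian core plus
#' a broad exponential tail — whose widths grow affinely with the slab
#' thickness `t`, reproducing the qualitative broad-tailed profiles of
#' pencil-beam scatter kernels:
#' \deqn{PSF(r) \propto (1 - w)\, e^{-r^2 / 2\sigma(t)^2} / (2\pi\sigma^2)
#'       + w\, e^{-r/\tau(t)} / (2\pi\tau^2)}
#' with `sigma(t) = sigma0 + sigma_slope * t` and
#' `tau(t) = tau0 + tau_slope * t` (all in mm).
#'
#' @param t Thickness in mm.
#' @param pitch Grid sample spacing in mm (detector pitch).
#' @param grid_size Odd number of samples per side.
#' @param params List of shape parameters `sigma0`, `sigma_slope`, `tau0`,
#'   `tau_slope` (mm / mm-per-mm) and `tail_frac` (weight of the
#'   exponential component, in `[0, 1]`).
#' @return A `grid_size x grid_size` matrix summing to 1, with attribute
#'   `truncated_mass`: the fraction of the continuous kernel mass falling
#'   outside the grid (reported, then renormalized away).
#' @export
make_parametric_psf <- function(t, pitch = 0.388, grid_size = 101L,
                                params = psf_shape_defaults()) {
  if (grid_size %% 2L == 0L)
    stop("PSF grid size must be odd so the centre pixel is defined")
  if (t < 0) stop("thickness must be >= 0")
  with(params, {
    if (sigma0 <= 0 || tau0 <= 0 || sigma_slope < 0 || tau_slope < 0)
      stop("PSF shape parameters must be positive")
  })
  sigma <- params$sigma0 + params$sigma_slope * t
  tau <- params$tau0 + params$tau_slope * t
  w <- params$tail_frac
  half <- (grid_size - 1L) / 2L
  r2 <- outer((-half:half)^2, (-half:half)^2, "+") * pitch^2
  g <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  e <- exp(-sqrt(r2) / tau) / (2 * pi * tau^2)
  psf <- (1 - w) * g + w * e
  mass_on_grid <- sum(psf) * pitch^2  # continuous total mass is 1
  psf <- psf / sum(psf)
  attr(psf, "truncated_mass") <- max(0, 1 - mass_on_grid)
  psf
}

#' Default PSF shape parameters
#'
#' Widths in mm; slopes per mm of thickness.  The exponential tail
#' dominates and reaches several cm for thick slabs (e.g. `tau = 60` mm
#' at 140 mm), as pencil-beam scatter kernels measured behind thick
#' slabs with an air gap do; the narrow Gaussian core carries the
#' small-angle peak.  Kernels this broad spread scatter from the bright
#' object rim across the whole field, which is what makes the
#' scatter-to-primary ratio peak behind the object centre and produces
#' the cupping artifact.
#' @export
psf_shape_defaults <- function() {
  list(sigma0 = 3, sigma_slope = 0.03,
       tau0 = 40, tau_slope = 0.5, tail_frac = 0.85)
}

#' Thickness-indexed scatter-kernel database
#'
#' Builds the kernel database `K_t = A_t * SF_t * PSF_t` on a contiguous
#' 1 mm thickness grid `1..t_max`.  PSFs are either evaluated directly
#' from the parametric model at every thickness (`method = "parametric"`)
#' or generated at coarse nodes spaced `coarse_step` mm apart and then
#' linearly interpolated per pixel to the 1 mm grid
#' (`method = "interpolated"`, mirroring a slab-ladder measurement
#' protocol).  `SF` and `A` always come from their own functions, never
#' from interpolation.
#'
#' @param t_max Largest thickness in the database (mm).
#' @param pitch Kernel sample spacing (mm).
#' @param grid_size Odd PSF grid side (pixels).
#' @param psf_params See [make_parametric_psf()].
#' @param a1,a2 Scatter-fraction coefficients, see [sf_of_thickness()].
#' @param amp_table Amplitude table, see [amplitude_of_thickness()].
#' @param method `"parametric"` or `"interpolated"`.
#' @param coarse_step Node spacing for `method = "interpolated"` (mm).
#' @return An object of class `kernel_database`.
#' @export
build_kernel_database <- function(t_max = 380L, pitch = 0.388,
                                  grid_size = 101L,
                                  psf_params = psf_shape_defaults(),
                                  a1 = 0.0038, a2 = 0.1,
                                  amp_table = .default_amp_table(),
                                  method = c("parametric", "interpolated"),
                                  coarse_step = 38L) {
  method <- match.arg(method)
  thick <- seq_len(t_max)
  if (method == "parametric") {
    psfs <- array(0, dim = c(grid_size, grid_size, t_max))
    trunc <- numeric(t_max)
    for (i in thick) {
      p <- make_parametric_psf(i, pitch, grid_size, psf_params)
      trunc[i] <- attr(p, "truncated_mass")
      psfs[, , i] <- p
    }
  } else {
    nodes <- seq(coarse_step, t_max + coarse_step - 1L, by = coarse_step)
    coarse <- lapply(nodes, make_parametric_psf, pitch = pitch,
                     grid_size = grid_size, params = psf_params)
    trunc <- vapply(coarse, attr, numeric(1), "truncated_mass")
    psfs <- interpolate_kernels(coarse, nodes, thick)
  }
  structure(list(thickness = thick, psf = psfs, pitch = pitch,
                 a1 = a1, a2 = a2, amp_table = amp_table,
                 psf_params = psf_params, provenance = method,
                 truncated_mass = max(trunc)),
            class = "kernel_database")
}

#' @export
print.kernel_database <- function(x, ...) {
  cat(sprintf(
    "Scatter-kernel database (%s): %d kernels @ 1 mm over [1, %d] mm\n",
    x$provenance, length(x$thickness), max(x$thickness)))
  cat(sprintf("  PSF grid %d x %d @ %.3f mm; SF = %.4f t + %.2f; max truncated mass %.3f\n",
              dim(x$psf)[1], dim(x$psf)[2], x$pitch, x$a1, x$a2,
              x$truncated_mass))
  invisible(x)
}

#' Interpolate coarse-node PSFs onto a fine thickness grid
#'
#' Per-pixel linear interpolation between the bracketing coarse kernels,
#' followed by renormalization of each interpolated PSF to unit sum.
#' Thicknesses below the first node reuse the first node's PSF (the shape
#' of very thin slabs is not measured by a slab ladder); thicknesses above
#' the last node are an error — no extrapolation.
#'
#' @param coarse List of unit-sum PSF matrices sharing one grid shape.
#' @param nodes Strictly increasing node thicknesses (mm), same length.
#' @param t_out Thicknesses (mm) to evaluate.
#' @return Array `[grid, grid, length(t_out)]` of unit-sum PSFs.
#' @export
interpolate_kernels <- function(coarse, nodes, t_out) {
  stopifnot(length(coarse) == length(nodes))
  if (is.unsorted(nodes, strictly = TRUE))
    stop("node thicknesses must be strictly increasing")
  shp <- dim(coarse[[1]])
  if (!all(vapply(coarse, function(k) identical(dim(k), shp), logical(1))))
    stop("coarse kernels must share one grid shape")
  if (any(t_out > max(nodes)))
    stop(sprintf("thickness %g mm beyond the last node (%g mm); no extrapolation",
                 max(t_out), max(nodes)))
  out <- array(0, dim = c(shp, length(t_out)))
  for (i in seq_along(t_out)) {
    t <- t_out[i]
    if (t <= nodes[1]) {
      k <- coarse[[1]]
    } else {
      hi <- findInterval(t, nodes, left.open = TRUE) + 1L
      lo <- hi - 1L
      if (t == nodes[hi]) {
        k <- coarse[[hi]]
      } else {
        w <- (t - nodes[lo]) / (nodes[hi] - nodes[lo])
        k <- (1 - w) * coarse[[lo]] + w * coarse[[hi]]
      }
    }
    out[, , i] <- k / sum(k)
  }
  out
}

#' Full kernel at a given thickness
#'
#' Looks up the database entry nearest to `t` on the 1 mm grid and scales
#' it to the full kernel `K_t = A(t) * SF(t) * PSF_t`, so the kernel's
#' grid sum equals `A(t) * SF(t)`.
#'
#' @param db A [build_kernel_database()] result.
#' @param t Thickness in mm.
#' @return Kernel matrix.
#' @export
kernel_at <- function(db, t) {
  stopifnot(inherits(db, "kernel_database"))
  if (t < 0) stop("thickness must be >= 0")
  tmax <- max(db$thickness)
  if (t > tmax)
    stop(sprintf("thickness %g mm exceeds the kernel database range (max %g mm)",
                 t, tmax))
  idx <- max(1L, round(t))
  amplitude_of_thickness(t, db$amp_table) *
    sf_of_thickness(t, db$a1, db$a2) * db$psf[, , idx]
}

#' Save / load a kernel database
#'
#' The database is persisted as a single R serialization file holding the
#' PSF stack and all metadata (thickness grid, pitch, SF coefficients,
#' amplitude table, provenance); the round trip is bit-exact.  `load`
#' validates the layout and re-checks PSF normalization, listing offending
#' thicknesses on failure.
#'
#' @param db A `kernel_database`.
#' @param path File path.
#' @return `load_kernels` returns the validated `kernel_database`.
#' @export
save_kernels <- function(db, path) {
  stopifnot(inherits(db, "kernel_database"))
  saveRDS(db, path)
  invisible(path)
}

#' @rdname save_kernels
#' @export
load_kernels <- function(path) {
  db <- readRDS(path)
  need <- c("thickness", "psf", "pitch", "a1", "a2", "amp_table")
  miss <- setdiff(need, names(db))
  if (!inherits(db, "kernel_database") || length(miss))
    stop("not a kernel database file; missing metadata: ",
         paste(miss, collapse = ", "))
  sums <- apply(db$psf, 3, sum)
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad))
    stop("non-normalized PSFs at thickness (mm): ",
         paste(db$thickness[bad], collapse = ", "))
  db
}
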