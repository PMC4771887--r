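#' Per-pixel PMMA-equivalent thickness
#'
#' Inverts the monoenergetic Beer's law: a pixel seeing primary intensity
#' `I_p` under flat field `i0` is assigned
#' `t = log(i0 / I_p) / mu_pmma` mm of PMMA-equivalent material.  Pixels
#' at or above the flat field map to 0; intensities below
#' `floor_frac * i0` are clipped before the log so the map stays finite.
#' When a log-signal lookup table is supplied the closed form is replaced
#' by table inversion (see [build_log_signal_lut()]).
#'
#' @param primary Matrix of primary intensities (one projection image) or
#'   a [projection_set()] (thickness is computed per view).
#' @param i0 Flat-field intensity (ignored when `primary` is a
#'   projection set).
#' @param mu_pmma Effective linear attenuation of PMMA (per mm, > 0).
#' @param lut Optional log-signal lookup table.
#' @param floor_frac Intensity floor as a fraction of `i0`.
#' @return Thickness map (matrix or array matching the input), mm.
#' @export
estimate_thickness <- function(primary, i0 = NULL,
                               mu_pmma = material_attenuation()[["pmma"]],
                               lut = NULL, floor_frac = 1e-6) {
  if (inherits(primary, "projection_set")) {
    i0 <- primary$i0
    primary <- primary$intensity
  }
  if (is.null(i0) || i0 <= 0) stop("flat-field intensity i0 must be > 0")
  if (mu_pmma <= 0) stop("mu_pmma must be > 0")
  p <- pmin(pmax(primary, floor_frac * i0), i0)
  logsig <- log(i0 / p)
  tmap <- if (is.null(lut)) logsig / mu_pmma else eval_log_signal_lut(lut, logsig)
  tmap[tmap < 0] <- 0
  tmap
}

#' Build a log-signal to thickness lookup table
#'
#' Calibration samples `(thickness, primary signal)` measured through pure
#' PMMA plates define a monotone transfer function from the log signal
#' `log(i0 / I_p)` to PMMA thickness.  The table always passes through
#' `(0, 0)` (zero thickness gives the flat field).
#'
#' @param thickness_mm Strictly increasing sample thicknesses (mm, > 0).
#' @param signal Strictly decreasing primary signals at those thicknesses.
#' @param i0 Flat-field intensity.
#' @return An object of class `log_signal_lut`.
#' @export
build_log_signal_lut <- function(thickness_mm, signal, i0) {
  if (length(thickness_mm) < 2L || length(signal) != length(thickness_mm))
    stop("need >= 2 (thickness, signal) pairs")
  if (any(thickness_mm <= 0)) stop("sample thicknesses must be > 0")
  up <- diff(thickness_mm) <= 0
  if (any(up))
    stop(sprintf("thicknesses not strictly increasing at pair %d -> %d",
                 which(up)[1], which(up)[1] + 1L))
  dn <- diff(signal) >= 0
  if (any(dn))
    stop(sprintf("signals not strictly decreasing at pair %d -> %d",
                 which(dn)[1], which(dn)[1] + 1L))
  if (any(signal <= 0) || any(signal >= i0))
    stop("signals must lie in (0, i0)")
  ls <- c(0, log(i0 / signal))
  structure(list(log_signal = ls, thickness = c(0, thickness_mm)),
            class = "log_signal_lut")
}

# Evaluate the LUT at log-signal values: linear interpolation inside the
# table, clamp to 0 below it, linear continuation of the last segment
# above it.
eval_log_signal_lut <- function(lut, logsig) {
  stopifnot(inherits(lut, "log_signal_lut"))
  n <- length(lut$log_signal)
  slope_end <- (lut$thickness[n] - lut$thickness[n - 1]) /
    (lut$log_signal[n] - lut$log_signal[n - 1])
  out <- stats::approx(lut$log_signal, lut$thickness, xout = pmin(
    as.numeric(logsig), lut$log_signal[n]), rule = 2)$y
  over <- as.numeric(logsig) > lut$log_signal[n]
  out[over] <- lut$thickness[n] +
    (as.numeric(logsig)[over] - lut$log_signal[n]) * slope_end
  out[out < 0] <- 0
  arr <- logsig
  arr[] <- out
  arr
}

#' Default thickness-group edges
#'
#' Five groups of 40 mm each with the last group open-ended:
#' `(0, 40], (40, 80], (80, 120], (120, 160], (160, Inf)`.
#'
#' @param n_groups Number of groups.
#' @param width_mm Group width (mm).
#' @return Numeric vector of finite lower edges `c(0, 40, 80, 120, 160)`.
#' @export
default_group_edges <- function(n_groups = 5L, width_mm = 40) {
  seq(0, by = width_mm, length.out = n_groups)
}

# Representative thickness of each group: the bin centre; the open-ended
# last group uses lower edge + half the nominal width.
group_centers <- function(edges) {
  w <- if (length(edges) > 1) diff(edges)[1] else 40
  edges + w / 2
}

#' Partition a projection image by thickness group
#'
#' Splits a primary image into subprojection images: pixel `(x, y)` with
#' thickness in group `g` keeps its value in subprojection `g` and is zero
#' in all others.  Groups are lower-open / upper-closed on the finite
#' edges, and the last group is open-ended, so every pixel with `t > 0`
#' belongs to exactly one group; the subprojections therefore sum back to
#' the primary image on the `t > 0` support.
#'
#' @param primary Projection image (matrix).
#' @param tmap Thickness map (matrix, same shape, mm).
#' @param edges Finite lower group edges, strictly increasing, starting
#'   at 0 (see [default_group_edges()]).
#' @param t_floor Minimum thickness (mm) for membership in the first
#'   group.  With the default 0 the subprojections partition the full
#'   `t > 0` support; a positive floor excludes near-air pixels from all
#'   groups (used by the scatter model, where sub-floor pixels are
#'   treated as non-emitting).
#' @return List of subprojection matrices, one per group, with attribute
#'   `masks` (logical membership masks) and `centers` (representative
#'   thickness per group, mm).
#' @export
partition_by_thickness <- function(primary, tmap,
                                   edges = default_group_edges(),
                                   t_floor = 0) {
  if (!identical(dim(primary), dim(tmap)))
    stop("primary and thickness map shapes differ")
  if (is.unsorted(edges, strictly = TRUE))
    stop("group edges must be strictly increasing")
  n_g <- length(edges)
  lower <- edges
  lower[1] <- max(edges[1], t_floor)
  upper <- c(edges[-1], Inf)
  subs <- vector("list", n_g)
  masks <- vector("list", n_g)
  for (g in seq_len(n_g)) {
    m <- tmap > lower[g] & tmap <= upper[g]
    sp <- matrix(0, nrow(primary), ncol(primary))
    sp[m] <- primary[m]
    subs[[g]] <- sp
    masks[[g]] <- m
  }
  attr(subs, "masks") <- masks
  attr(subs, "centers") <- group_centers(edges)
  subs
}
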