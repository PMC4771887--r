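#' Grouped-kernel scatter convolution
#'
#' Computes the scatter estimate `S = sum_g (I_{p,g} ** K_g)`: each
#' thickness-group subprojection is convolved ("same" output) with its
#' group kernel and the results are summed.  Convolution runs in the
#' frequency domain with zero padding to at least image + kernel extent
#' (rounded up to a fast composite FFT size), so no wrap-around occurs.
#' Tiny negative values from floating-point round-off are clamped to 0.
#'
#' @param subprojections List of equally shaped image matrices.
#' @param kernels List of kernel matrices, one per subprojection (odd
#'   sizes; the kernel centre pixel aligns with the image pixel).
#' @param plan Optional precomputed plan from [conv_plan()]; pass it when
#'   convolving many images with the same kernels.
#' @return Scatter image (matrix, same shape as the subprojections).
#' @export
scatter_convolve <- function(subprojections, kernels, plan = NULL) {
  if (length(subprojections) != length(kernels))
    stop("need one kernel per subprojection group")
  dimg <- dim(subprojections[[1]])
  for (s in subprojections)
    if (!identical(dim(s), dimg)) stop("subprojection shapes differ")
  if (is.null(plan)) plan <- conv_plan(dimg, kernels)
  acc <- NULL
  for (g in seq_along(subprojections)) {
    s <- subprojections[[g]]
    if (!any(s != 0)) next
    pad <- matrix(0, plan$P[1], plan$P[2])
    pad[seq_len(dimg[1]), seq_len(dimg[2])] <- s
    term <- stats::fft(pad) * plan$kft[[g]]
    acc <- if (is.null(acc)) term else acc + term
  }
  if (is.null(acc)) return(matrix(0, dimg[1], dimg[2]))
  full <- Re(stats::fft(acc, inverse = TRUE)) / prod(plan$P)
  out <- full[plan$off[1] + seq_len(dimg[1]), plan$off[2] + seq_len(dimg[2])]
  out[out < 0] <- 0
  out
}

#' Precompute the frequency-domain plan for [scatter_convolve()]
#'
#' @param dimg Image dimensions `c(rows, cols)`.
#' @param kernels List of kernel matrices.
#' @return List with padded size `P`, centre offsets `off`, and kernel
#'   FFTs `kft`.
#' @export
conv_plan <- function(dimg, kernels) {
  dk <- dim(kernels[[1]])
  for (k in kernels)
    if (!identical(dim(k), dk)) stop("kernel shapes differ")
  if (any(dk %% 2L == 0L)) stop("kernels must have odd dimensions")
  P <- c(stats::nextn(dimg[1] + dk[1] - 1L, c(2, 3, 5)),
         stats::nextn(dimg[2] + dk[2] - 1L, c(2, 3, 5)))
  kft <- lapply(kernels, function(k) {
    pad <- matrix(0, P[1], P[2])
    pad[seq_len(dk[1]), seq_len(dk[2])] <- k
    stats::fft(pad)
  })
  list(P = P, off = (dk - 1L) / 2L, kft = kft)
}

#' Poisson log-likelihood of a signal estimate
#'
#' `L = sum_xy [ I_m log(lambda) - lambda ]` over all pixels: the Poisson
#' log-likelihood of the measurement under mean `lambda`, with the
#' data-only constant terms dropped.  Pixels with zero measured signal
#' contribute only `-lambda`.  As the convergence monitor of the scatter
#' correction, `lambda` is the model-predicted total signal
#' `I_p^n + sum_g I_{p,g}^n ** K_g` — the quantity the MLEM update drives
#' toward the measurement — so the monitored sequence ascends toward its
#' maximum (attained when the prediction matches the measurement
#' exactly).  The likelihood of the bare primary estimate is maximized
#' trivially at `I_p = I_m` and is not a useful monitor.
#'
#' @param measured Measured image (matrix or array, `>= 0`).
#' @param estimate Predicted mean, `> 0` wherever `measured > 0`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(measured, estimate) {
  pos <- measured > 0
  if (any(estimate[pos] <= 0))
    stop("estimate must be > 0 wherever the measurement is > 0")
  sum(measured[pos] * log(estimate[pos])) - sum(estimate)
}

# Kernels representing each thickness group (at the group-centre
# thickness), with a range check against the database.
group_kernels <- function(db, edges) {
  centers <- group_centers(edges)
  if (max(centers) > max(db$thickness))
    stop(sprintf(
      "group centre %g mm exceeds the kernel database range (max %g mm)",
      max(centers), max(db$thickness)))
  lapply(centers, function(t) kernel_at(db, t))
}

#' One grouped-kernel MLEM update
#'
#' The multiplicative update
#' `I_p^{n+1} = I_p^n * I_m / (I_p^n + sum_g I_{p,g}^n ** K_g)`:
#' the current primary estimate is thickness-mapped, partitioned into
#' thickness-group subprojections, convolved with the group kernels to
#' predict the scatter, and the measurement is redistributed against the
#' predicted total signal.  The thickness map and grouping are refreshed
#' from the current estimate on every call.
#'
#' @param estimate Current primary estimate (matrix, `> 0` on the support
#'   of `measured`).
#' @param measured Measured image (matrix, `>= 0`).
#' @param i0 Flat-field intensity.
#' @param db Kernel database.
#' @param edges Thickness-group lower edges (mm).
#' @param mu_pmma Effective PMMA attenuation (per mm) for the thickness
#'   map.
#' @param t_emit_min Minimum emitting thickness (mm): pixels mapped below
#'   this are treated as unattenuated and generate no scatter.  The
#'   linear SF model is a fit over thick slabs; its positive intercept
#'   would otherwise assign finite scatter emission to bare flat-field
#'   pixels, which misstates the physics and destabilizes the
#'   multiplicative update around the flat-field level.
#' @param kernels,plan Optional precomputed [group_kernels()] /
#'   [conv_plan()] (computed from `db` and `edges` when omitted).
#' @return Updated estimate (matrix).
#' @export
mlem_update <- function(estimate, measured, i0, db,
                        edges = default_group_edges(),
                        mu_pmma = material_attenuation()[["pmma"]],
                        t_emit_min = 5,
                        kernels = NULL, plan = NULL) {
  if (!identical(dim(estimate), dim(measured)))
    stop("estimate and measured shapes differ")
  if (is.null(kernels)) kernels <- group_kernels(db, edges)
  if (is.null(plan)) plan <- conv_plan(dim(estimate), kernels)
  tmap <- estimate_thickness(estimate, i0, mu_pmma)
  subs <- partition_by_thickness(estimate, tmap, edges, t_floor = t_emit_min)
  scatter <- scatter_convolve(subs, kernels, plan)
  den <- estimate + scatter
  upd <- estimate * (measured / den)
  upd[!is.finite(upd)] <- 0  # 0/0 where measurement and estimate vanish
  upd
}

#' Run the scatter correction on a projection set
#'
#' Per view: initialize the primary estimate at the measurement, then
#' iterate [mlem_update()] until the relative change of the
#' log-likelihood falls below `tol` or `max_iter` iterations are reached
#' (whichever first).  Views are independent; nothing is shared between
#' them.  Non-convergence at `max_iter` raises a warning and is flagged
#' in the diagnostics, never an error.
#'
#' @param measured A [projection_set()] of measured intensities.
#' @param db Kernel database covering the observed thickness range.
#' @param edges Thickness-group lower edges (mm).
#' @param max_iter Maximum MLEM iterations per view (default 5).
#' @param tol Relative log-likelihood tolerance (default 1e-4).
#' @param mu_pmma Effective PMMA attenuation (per mm).
#' @param t_emit_min Minimum emitting thickness (mm); see [mlem_update()].
#' @param snapshot_rows Optional integer vector of detector rows whose
#'   estimates are recorded after every iteration (iteration 0 = the
#'   initial estimate), e.g. the central row for slice reconstruction of
#'   intermediate iterates.
#' @param warn_nonconverged Emit a warning when some view hits `max_iter`
#'   without meeting `tol`.
#' @return List with `corrected` (a [projection_set()]),
#'   `loglik` (matrix `[max_iter + 1, n_views]`, NA-padded),
#'   `iterations` (per view), `converged` (per view), and — when
#'   `snapshot_rows` is given — `snapshots`: a list over iterations
#'   0..`max_iter` of arrays `[length(snapshot_rows), cols, views]`.
#' @export
run_scatter_correction <- function(measured, db,
                                   edges = default_group_edges(),
                                   max_iter = 5L, tol = 1e-4,
                                   mu_pmma = material_attenuation()[["pmma"]],
                                   t_emit_min = 5,
                                   snapshot_rows = NULL,
                                   warn_nonconverged = TRUE) {
  stopifnot(inherits(measured, "projection_set"), max_iter >= 0, tol > 0)
  kernels <- group_kernels(db, edges)
  nv <- n_views(measured)
  d <- dim(measured$intensity)
  plan <- conv_plan(d[1:2], kernels)
  out <- measured$intensity
  loglik <- matrix(NA_real_, max_iter + 1L, nv)
  iters <- integer(nv)
  conv <- logical(nv)
  snaps <- NULL
  if (!is.null(snapshot_rows)) {
    snapshot_rows <- as.integer(snapshot_rows)
    snaps <- lapply(seq_len(max_iter + 1L), function(i)
      array(NA_real_, dim = c(length(snapshot_rows), d[2], nv)))
  }
  i0 <- measured$i0
  for (v in seq_len(nv)) {
    im <- measured$intensity[, , v]
    est <- im  # initialization: I_p^0 = I_m
    ll_prev <- NA_real_
    n <- 0L
    repeat {
      # scatter prediction for the current iterate: shared between the
      # likelihood monitor and the multiplicative update
      tmap <- estimate_thickness(est, i0, mu_pmma)
      subs <- partition_by_thickness(est, tmap, edges, t_floor = t_emit_min)
      den <- est + scatter_convolve(subs, kernels, plan)
      ll <- log_likelihood(im, pmax(den, 1e-12 * i0))
      loglik[n + 1L, v] <- ll
      if (!is.null(snaps)) snaps[[n + 1L]][, , v] <- est[snapshot_rows, ]
      if (!is.na(ll_prev) &&
          abs(ll - ll_prev) < tol * max(abs(ll), .Machine$double.eps)) {
        conv[v] <- TRUE
        break
      }
      ll_prev <- ll
      if (n >= max_iter) break
      upd <- est * (im / den)
      upd[!is.finite(upd)] <- 0  # 0/0 where measurement and estimate vanish
      est <- upd
      n <- n + 1L
    }
    iters[v] <- n
    if (!is.null(snaps) && n < max_iter) {
      # converged early: later iterates equal the converged estimate
      for (k in seq(n + 2L, max_iter + 1L)) snaps[[k]][, , v] <- est[snapshot_rows, ]
    }
    out[, , v] <- est
  }
  if (warn_nonconverged && any(!conv) && max_iter > 0)
    warning(sum(!conv), " of ", nv,
            " views hit max_iter without meeting the likelihood tolerance")
  res <- list(corrected = projection_set(out, measured$geometry,
                                         measured$i0, kind = "corrected"),
              loglik = loglik, iterations = iters, converged = conv)
  if (!is.null(snaps)) {
    res$snapshots <- snaps
    res$snapshot_rows <- snapshot_rows
  }
  res
}
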