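#' Add kernel-model scatter to primary projections
#'
#' Generates the measured signal `I_m = I_p + sum_g (I_{p,g} ** K_g)`
#' using exactly the grouped-convolution forward model the correction
#' assumes: the true primary is thickness-mapped, partitioned into
#' thickness groups, convolved with the group kernels, and the summed
#' scatter is added.  This deliberately shares the forward model with the
#' correction (an "inverse crime") so that recovery of the known primary
#' is a well-posed test of the deconvolution.
#'
#' @param primary A [projection_set()] of primary intensities.
#' @param db Kernel database; must cover the thickness range present in
#'   the projections.
#' @param edges Thickness-group lower edges (mm).
#' @param mu_pmma Effective PMMA attenuation (per mm).
#' @param t_emit_min Minimum emitting thickness (mm); pixels thinner than
#'   this generate no scatter, matching the correction's forward model
#'   (see [mlem_update()]).
#' @return A [projection_set()] of measured intensities (`kind =
#'   "measured"`), never below the input primary anywhere.
#' @export
add_scatter <- function(primary, db, edges = default_group_edges(),
                        mu_pmma = material_attenuation()[["pmma"]],
                        t_emit_min = 5) {
  stopifnot(inherits(primary, "projection_set"),
            inherits(db, "kernel_database"))
  kernels <- group_kernels(db, edges)
  plan <- conv_plan(dim(primary$intensity)[1:2], kernels)
  out <- primary$intensity
  tmax_db <- max(db$thickness)
  for (v in seq_len(n_views(primary))) {
    ip <- primary$intensity[, , v]
    tmap <- estimate_thickness(ip, primary$i0, mu_pmma)
    if (max(tmap) > tmax_db)
      stop(sprintf(
        "projection thickness %.1f mm exceeds the kernel database range (max supported thickness %g mm)",
        max(tmap), tmax_db))
    subs <- partition_by_thickness(ip, tmap, edges, t_floor = t_emit_min)
    out[, , v] <- ip + scatter_convolve(subs, kernels, plan)
  }
  projection_set(out, primary$geometry, primary$i0, kind = "measured")
}

#' Apply Poisson counting noise to a projection set
#'
#' Replaces each pixel intensity by a Poisson draw with that mean.  The
#' Poisson assumption is the statistical model underlying the MLEM
#' deconvolution, so noisy simulations exercise the estimator under its
#' own noise model.  Off by default everywhere in the package.
#'
#' @param proj A [projection_set()].
#' @param seed Optional integer seed for reproducibility.
#' @return A [projection_set()] with noisy intensities.
#' @export
add_poisson_noise <- function(proj, seed = NULL) {
  stopifnot(inherits(proj, "projection_set"))
  if (!is.null(seed)) set.seed(seed)
  noisy <- proj$intensity
  noisy[] <- stats::rpois(length(noisy), lambda = as.numeric(noisy))
  projection_set(noisy, proj$geometry, proj$i0,
                 kind = paste0(proj$kind, "+noise"))
}

#' Simulate a cone-beam scan of a phantom
#'
#' Convenience wrapper: forward-projects the phantom (Beer's law), then
#' optionally adds kernel-model scatter and Poisson noise.
#'
#' @inheritParams forward_project
#' @param db Kernel database for scatter generation; `NULL` for a
#'   scatter-free scan.
#' @param edges Thickness-group lower edges (mm).
#' @param mu_pmma Effective PMMA attenuation (per mm).
#' @param noise Add Poisson noise to the measured intensities.
#' @param seed Seed used when `noise = TRUE`.
#' @return List with `primary` and `measured` [projection_set()]s
#'   (identical objects when `db` is `NULL` and `noise = FALSE`).
#' @export
simulate_projections <- function(phantom, geometry, i0 = 1e4, db = NULL,
                                 edges = default_group_edges(),
                                 mu_pmma = material_attenuation()[["pmma"]],
                                 noise = FALSE, seed = NULL) {
  primary <- forward_project(phantom, geometry, i0)
  measured <- if (is.null(db)) primary
              else add_scatter(primary, db, edges, mu_pmma)
  if (noise) measured <- add_poisson_noise(measured, seed)
  list(primary = primary, measured = measured)
}
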