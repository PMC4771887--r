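# Shared test fixtures.  The recovery fixture (160 mm soft-tissue
# cylinder, 256 x 256 detector at 1.2 mm pitch, 180 views, scatter from
# the default broad-tailed kernel database) is expensive, so it is built
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture_geometry <- function(n_views = 180L, det_rows = 256L) {
  acquisition_geometry(dso = 500, dsd = 786, pitch = 1.2,
                       det_rows = det_rows, det_cols = 256L,
                       n_views = n_views)
}

fixture_kernel_db <- function() {
  if (is.null(.fixture_cache$db))
    .fixture_cache$db <- build_kernel_database(t_max = 200L, pitch = 1.2,
                                               grid_size = 201L)
  .fixture_cache$db
}

# Full recovery fixture: simulation plus a 10-iteration correction with
# central-row snapshots.  Everything downstream (recovery error,
# likelihood ascent, cupping trend) reads from this one run.
recovery_fixture <- function() {
  if (!is.null(.fixture_cache$fix)) return(.fixture_cache$fix)
  geom <- fixture_geometry()
  phantom <- generate_qrm_like_phantom(160, NULL, voxel_mm = 1.25)
  db <- fixture_kernel_db()
  sim <- simulate_projections(phantom, geom, i0 = 1e4, db = db)
  corr <- run_scatter_correction(sim$measured, db, max_iter = 10L,
                                 tol = 1e-9, snapshot_rows = 128L,
                                 warn_nonconverged = FALSE)
  .fixture_cache$fix <- list(geom = geom, phantom = phantom, db = db,
                             i0 = 1e4, primary = sim$primary,
                             measured = sim$measured, corr = corr)
  .fixture_cache$fix
}

# Small geometry for cheap unit tests: wide pixels so the 160 mm
# phantom fits on a 64-column detector.
tiny_geometry <- function(n_views = 8L, det_rows = 32L, det_cols = 64L,
                          pitch = 4.8) {
  acquisition_geometry(dso = 500, dsd = 786, pitch = pitch,
                       det_rows = det_rows, det_cols = det_cols,
                       n_views = n_views)
}

tiny_kernel_db <- function(grid_size = 51L, pitch = 4.8) {
  build_kernel_database(t_max = 200L, pitch = pitch, grid_size = grid_size)
}

# Percent cupping of a reconstructed central slice, HU-calibrated
# against a reference background mean.
slice_cupping <- function(slice, m_ref, voxel_mm = 0.75, ring_mm = 55,
                          roi_mm = 8) {
  pts <- list(c(ring_mm, 0), c(-ring_mm, 0), c(0, ring_mm), c(0, -ring_mm))
  hu_edge <- vapply(pts, function(p)
    ct_number(roi_stats(slice, p, roi_mm, voxel_mm)$mean, m_ref), numeric(1))
  hu_cen <- ct_number(roi_stats(slice, c(0, 0), roi_mm, voxel_mm)$mean, m_ref)
  percent_cupping(hu_edge, hu_cen)
}
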