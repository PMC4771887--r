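test_that("filter specification validates family and cutoff", {
  expect_s3_class(recon_filter("hamming", 0.6), "recon_filter")
  expect_error(recon_filter("shepp-logan", 0), "cutoff")
  expect_error(recon_filter("shepp-logan", 1.2), "cutoff")
  expect_error(recon_filter("boxcar"), "arg")
})

test_that("zero projections reconstruct to a zero volume", {
  geom <- tiny_geometry(n_views = 12L)
  pr <- projection_set(array(5e3, c(32, 64, 12)), geom, 5e3)
  vol <- fbp_reconstruct(pr, npix = 64L, voxel_mm = 3)
  expect_equal(max(abs(vol$data)), 0)
})

test_that("reconstruction is linear in the sinogram", {
  set.seed(11)
  geom <- tiny_geometry(n_views = 24L, det_cols = 64L)
  filt <- recon_filter("shepp-logan", 0.6)
  s1 <- matrix(runif(64 * 24), 64, 24)
  s2 <- matrix(runif(64 * 24), 64, 24)
  r12 <- fbp_central_slice(s1 + s2, geom, filt, npix = 48L, voxel_mm = 3)
  r1 <- fbp_central_slice(s1, geom, filt, npix = 48L, voxel_mm = 3)
  r2 <- fbp_central_slice(s2, geom, filt, npix = 48L, voxel_mm = 3)
  expect_lt(max(abs(r12 - (r1 + r2))), 1e-8)
})

test_that("uniform cylinder reconstructs flat and at the true attenuation", {
  geom <- acquisition_geometry(dso = 500, dsd = 786, pitch = 1.2,
                               det_rows = 4L, det_cols = 256L,
                               n_views = 360L)
  mu <- 0.02
  ph <- generate_qrm_like_phantom(160, NULL, voxel_mm = 1.25, nz = 40L,
                                  background_mu = mu)
  pr <- forward_project(ph, geom)
  vol <- fbp_reconstruct(pr, recon_filter("shepp-logan", 0.6),
                         npix = 256L, voxel_mm = 0.75)
  sl <- vol$data[, , 1]
  interior <- roi_stats(sl, c(0, 0), 60, 0.75)
  expect_lt(abs(interior$mean - mu) / mu, 0.03)
  prof <- extract_profile(sl, c(128.5 - 55 / 0.75, 128.5),
                          c(128.5 + 55 / 0.75, 128.5))
  expect_lt((max(prof) - min(prof)) / mu, 0.02)
})

test_that("a small insert reconstructs at its true position", {
  spec <- data.frame(label = "dot", cx = 30, cy = -20, radius = 5,
                     mu = 0.06)
  geom <- acquisition_geometry(dso = 500, dsd = 786, pitch = 2.4,
                               det_rows = 4L, det_cols = 128L,
                               n_views = 180L)
  ph <- generate_qrm_like_phantom(160, spec, voxel_mm = 2, nz = 20L,
                                  background_mu = 0.02)
  vol <- fbp_reconstruct(forward_project(ph, geom), npix = 128L,
                         voxel_mm = 1.5)
  sl <- vol$data[, , 1]
  hot <- sl > 0.5 * (0.06 + 0.02)
  cx <- (mean(row(sl)[hot]) - 64.5) * 1.5
  cy <- (mean(col(sl)[hot]) - 64.5) * 1.5
  expect_lt(abs(cx - 30), 1.5)
  expect_lt(abs(cy - (-20)), 1.5)
})

test_that("incomplete angular coverage is rejected, stating the gap", {
  geom <- acquisition_geometry(dso = 500, dsd = 786, pitch = 4.8,
                               det_rows = 8L, det_cols = 64L,
                               angles_deg = seq(0, 179, by = 1))
  pr <- projection_set(array(1e3, c(8, 64, 180)), geom, 1e3)
  expect_error(fbp_reconstruct(pr), "incomplete angular coverage")
})

test_that("FDK central slice agrees with the fan-beam path on a small grid", {
  geom <- acquisition_geometry(dso = 500, dsd = 786, pitch = 4.8,
                               det_rows = 33L, det_cols = 64L,
                               n_views = 90L)
  ph <- generate_qrm_like_phantom(120, NULL, voxel_mm = 2.5, nz = 48L,
                                  background_mu = 0.02)
  pr <- forward_project(ph, geom)
  fan <- fbp_reconstruct(pr, npix = 64L, voxel_mm = 2.5)$data[, , 1]
  fdk <- fbp_reconstruct(pr, npix = 64L, voxel_mm = 2.5, slices = "fdk",
                         nslice = 5L)
  mid <- fdk$data[, , 3]
  # compare over the interior (the cone edge differs by design)
  cen <- 32.5
  d2 <- outer((seq_len(64) - cen)^2, (seq_len(64) - cen)^2, "+") * 2.5^2
  in50 <- d2 <= 50^2
  expect_lt(max(abs(mid[in50] - fan[in50])), 0.002)
  # shepp-logan vs hamming: both near the truth, hamming smoother
  ham <- fbp_reconstruct(pr, recon_filter("hamming", 0.6), npix = 64L,
                         voxel_mm = 2.5)$data[, , 1]
  expect_equal(mean(ham[in50]), mean(fan[in50]), tolerance = 0.02)
  expect_lt(sd(ham[in50]), sd(fan[in50]) + 1e-12)
})

test_that("scatter produces cupping and correction reduces it (small fixture)", {
  geom <- acquisition_geometry(dso = 500, dsd = 786, pitch = 2.4,
                               det_rows = 128L, det_cols = 128L,
                               n_views = 90L)
  ph <- generate_qrm_like_phantom(160, NULL, voxel_mm = 2.5)
  db <- build_kernel_database(t_max = 200L, pitch = 2.4, grid_size = 101L)
  sim <- simulate_projections(ph, geom, i0 = 1e4, db = db)
  corr <- run_scatter_correction(sim$measured, db, max_iter = 5L,
                                 warn_nonconverged = FALSE)
  filt <- recon_filter("shepp-logan", 0.6)
  bench <- fbp_reconstruct(sim$primary, filt, npix = 128L,
                           voxel_mm = 1.5)$data[, , 1]
  m_ref <- roi_stats(bench, c(0, 0), 8, 1.5)$mean
  cup_un <- slice_cupping(fbp_reconstruct(sim$measured, filt, npix = 128L,
                                          voxel_mm = 1.5)$data[, , 1],
                          m_ref, voxel_mm = 1.5)
  cup_co <- slice_cupping(fbp_reconstruct(corr$corrected, filt,
                                          npix = 128L,
                                          voxel_mm = 1.5)$data[, , 1],
                          m_ref, voxel_mm = 1.5)
  expect_gt(cup_un, 1)            # scatter depresses the centre
  expect_lt(cup_co, cup_un / 4)   # correction removes most of the cupping
})
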